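#' Indicator schema for third-molar extraction records
#'
#' The difficulty scale underlying the workflow scores each extraction on 14
#' primary indicators (crown condition of the second molar, looseness,
#' relationship of the third molar to the inferior alveolar nerve, Winter
#' angulation, Pell & Gregory depth, crown condition, root number/morphology/
#' width, crown resistance, age, mouth opening, BMI, gender), each with an
#' ordered set of secondary levels. `ddss_schema()` loads the packaged
#' default schema, including the baseline level proportions used by the
#' synthetic generator; pass a path to load a custom JSON or YAML schema
#' with the same structure.
#'
#' @param path Optional path to a JSON or YAML schema document with a single
#'   top-level `indicators` array, each entry carrying `name`,
#'   `abbreviation`, `levels` and optionally `proportions`.
#' @return A tibble of class `ddss_schema` with one row per indicator and
#'   columns `name`, `abbreviation`, `levels` (list of character vectors)
#'   and `proportions` (list of numeric vectors, renormalized to sum to 1).
#' @examples
#' sch <- ddss_schema()
#' nrow(sch)        # 14 indicators
#' sch$abbreviation
#' @export
ddss_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "indicator_schema.json", package = "ddss")
  }
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  ind <- raw$indicators
  sch <- tibble::tibble(
    name = purrr::map_chr(ind, "name"),
    abbreviation = purrr::map_chr(ind, "abbreviation"),
    levels = purrr::map(ind, ~ as.character(unlist(.x$levels))),
    # raw published proportions; rows need not sum exactly to 1 (rounding in
    # the source table) - the generator renormalizes within indicator
    proportions = purrr::map(ind, function(x) {
      if (is.null(x$proportions)) return(NULL)
      as.numeric(unlist(x$proportions))
    })
  )
  validate_schema(sch)
  class(sch) <- c("ddss_schema", class(sch))
  sch
}

validate_schema <- function(sch) {
  if (nrow(sch) != 14L) {
    stop("schema must define exactly 14 indicators, got ", nrow(sch))
  }
  if (anyDuplicated(sch$abbreviation)) {
    stop("indicator abbreviations must be unique")
  }
  purrr::pwalk(sch, function(name, abbreviation, levels, proportions) {
    if (length(levels) < 2L) {
      stop("indicator '", abbreviation, "' must have at least 2 levels")
    }
    if (anyDuplicated(levels)) {
      stop("duplicate level names within indicator '", abbreviation, "'")
    }
    if (!is.null(proportions)) {
      if (length(proportions) != length(levels)) {
        stop("proportions length mismatch for indicator '", abbreviation, "'")
      }
      if (any(proportions < 0) || abs(sum(proportions) - 1) > 0.05) {
        stop("proportions for '", abbreviation,
             "' must be non-negative and sum to ~1")
      }
    }
  })
  invisible(sch)
}

#' @export
print.ddss_schema <- function(x, ...) {
  cat("<ddss_schema> 14 indicators,",
      sum(lengths(x$levels)), "secondary levels\n")
  NextMethod()
}

schema_abbrevs <- function(schema) schema$abbreviation

schema_n_levels <- function(schema) {
  stats::setNames(lengths(schema$levels), schema$abbreviation)
}
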