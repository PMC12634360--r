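#' Read surgical extraction records from CSV
#'
#' Records are stored one row per extraction with columns `record_id`
#' (optional; generated when absent), `surgeon_id`, `month_index` (months
#' since the surgeon joined the department, starting at 1), `duration_s`
#' (operative time in seconds), and one column per indicator abbreviation
#' holding the observed secondary-level name exactly as spelled in the
#' schema. Empty cells are treated as missing values. In memory each
#' indicator is held as a 0-based ordinal code (`NA` = missing) following
#' the schema's level order, so that one Lasso coefficient corresponds to
#' one indicator trajectory.
#'
#' @param path Path to a CSV file.
#' @param schema An indicator schema from [ddss_schema()].
#' @return A tibble of class `ddss_records` with columns `record_id`,
#'   `surgeon_id`, `month_index`, `duration_s` and one integer code column
#'   per indicator abbreviation.
#' @seealso [write_records()], [impute_missing()], [label_class()]
#' @export
read_records <- function(path, schema = ddss_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("", "NA"))
  abbrevs <- schema_abbrevs(schema)
  needed <- c("surgeon_id", "month_index", "duration_s", abbrevs)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::tibble(
    record_id = if ("record_id" %in% names(df)) as.character(df$record_id)
                else sprintf("r%04d", seq_len(nrow(df))),
    surgeon_id = as.character(df$surgeon_id),
    month_index = as.integer(df$month_index),
    duration_s = as.numeric(df$duration_s)
  )
  for (i in seq_along(abbrevs)) {
    ab <- abbrevs[i]
    lv <- schema$levels[[i]]
    val <- df[[ab]]
    code <- match(val, lv) - 1L
    bad <- which(!is.na(val) & is.na(code))
    if (length(bad)) {
      stop("unknown level \"", val[bad[1]], "\" for indicator '", ab,
           "' at data row ", bad[1])
    }
    out[[ab]] <- code
  }
  validate_records(out, schema)
  new_ddss_records(out)
}

#' Write surgical records to CSV
#'
#' Inverse of [read_records()]: ordinal codes are expanded back to their
#' level names so the file round-trips losslessly.
#'
#' @param records A `ddss_records` tibble.
#' @param path Output CSV path.
#' @param schema An indicator schema from [ddss_schema()].
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, schema = ddss_schema()) {
  abbrevs <- schema_abbrevs(schema)
  df <- as.data.frame(records[c("record_id", "surgeon_id", "month_index",
                                "duration_s")])
  for (i in seq_along(abbrevs)) {
    df[[abbrevs[i]]] <- schema$levels[[i]][records[[abbrevs[i]]] + 1L]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

new_ddss_records <- function(df) {
  class(df) <- unique(c("ddss_records", class(df)))
  df
}

validate_records <- function(records, schema) {
  if (anyDuplicated(records$record_id)) stop("record_ids must be unique")
  if (any(is.na(records$duration_s)) || any(records$duration_s <= 0)) {
    stop("duration_s must be positive for every record")
  }
  if (any(is.na(records$month_index)) || any(records$month_index < 1L)) {
    stop("month_index must be an integer >= 1")
  }
  n_lev <- schema_n_levels(schema)
  for (ab in names(n_lev)) {
    code <- records[[ab]]
    bad <- !is.na(code) & (code < 0L | code >= n_lev[[ab]])
    if (any(bad)) {
      stop("out-of-range level code for indicator '", ab, "' in record ",
           records$record_id[which(bad)[1]])
    }
  }
  invisible(records)
}

#' Impute missing indicator levels by surgeon-wise means
#'
#' Missing ordinal codes are replaced by the mean code observed for the same
#' indicator within the same surgeon's records, rounded half-up to the
#' nearest valid level. Non-missing values are never altered. When a surgeon
#' has no observed value at all for an indicator, the function stops unless
#' `global_fallback = TRUE`, in which case the dataset-wide mean code is
#' used instead.
#'
#' @param records A `ddss_records` tibble.
#' @param schema An indicator schema.
#' @param global_fallback Fall back to the global mean when a whole
#'   (surgeon, indicator) group is missing. Default `FALSE`.
#' @return The records tibble with all indicator codes filled in.
#' @export
impute_missing <- function(records, schema = ddss_schema(),
                           global_fallback = FALSE) {
  abbrevs <- schema_abbrevs(schema)
  out <- records
  for (ab in abbrevs) {
    code <- out[[ab]]
    if (!anyNA(code)) next
    filled <- code
    for (s in unique(out$surgeon_id[is.na(code)])) {
      idx <- which(out$surgeon_id == s)
      obs <- code[idx]
      if (all(is.na(obs))) {
        if (!global_fallback) {
          stop("all values of '", ab, "' missing for surgeon ", s,
               "; rerun with global_fallback = TRUE to use the global mean")
        }
        m <- mean(code, na.rm = TRUE)
        if (is.nan(m)) stop("indicator '", ab, "' is missing everywhere")
      } else {
        m <- mean(obs, na.rm = TRUE)
      }
      filled[idx][is.na(obs)] <- round_half_up(m)
    }
    out[[ab]] <- as.integer(filled)
  }
  validate_records(out, schema)
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Per-surgeon z-scores of operative duration
#'
#' Normalizes operative durations within each surgeon so that Lasso fits
#' compare records on a common scale regardless of the surgeon's own speed:
#' for each surgeon the returned values have mean 0 and population standard
#' deviation 1 (divisor `n`, not `n - 1`). Class labels, by contrast, always
#' use raw seconds (see [label_class()]).
#'
#' @param records A `ddss_records` tibble.
#' @return A tibble with columns `record_id` and `duration_z`, in the input
#'   record order.
#' @export
normalize_durations <- function(records) {
  out <- records |>
    dplyr::group_by(.data$surgeon_id) |>
    dplyr::mutate(.n = dplyr::n(),
                  .sd = pop_sd(.data$duration_s),
                  duration_z = (.data$duration_s - mean(.data$duration_s)) /
                    .data$.sd) |>
    dplyr::ungroup()
  if (any(out$.n < 2L)) {
    stop("every surgeon needs at least 2 records to normalize durations")
  }
  if (any(out$.sd == 0)) {
    s <- unique(out$surgeon_id[out$.sd == 0])
    stop("surgeon ", s[1], " has constant durations (zero variance)")
  }
  out[c("record_id", "duration_z")]
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Three-class difficulty label from operative duration
#'
#' Extractions are graded by operative time: Class 1 under 10 minutes,
#' Class 2 from 10 to 20 minutes, Class 3 over 20 minutes. Both boundary
#' points (600 s and 1200 s exactly) fall in the middle class.
#'
#' @param duration_s Vector of positive operative durations in seconds.
#' @return An integer vector of class labels in `{1, 2, 3}`.
#' @examples
#' label_class(c(540, 600, 900, 1200, 1500))
#' @export
label_class <- function(duration_s) {
  if (any(is.na(duration_s)) || any(duration_s <= 0)) {
    stop("duration_s must be positive")
  }
  ifelse(duration_s < 600, 1L, ifelse(duration_s <= 1200, 2L, 3L))
}

record_matrix <- function(records, schema = ddss_schema()) {
  abbrevs <- schema_abbrevs(schema)
  m <- as.matrix(as.data.frame(records[abbrevs]))
  storage.mode(m) <- "double"
  rownames(m) <- records$record_id
  m
}
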