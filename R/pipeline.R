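#' Assemble a workflow configuration
#'
#' Collects every tunable of the end-to-end workflow with its default.
#' Input is either a records CSV (`records_csv`) or, when that is `NULL`,
#' a synthetic dataset from [default_config()] (optionally overridden via
#' the `generator` list, e.g. `generator = list(noise_sd = 0.1)`).
#'
#' @param records_csv Optional path to a records CSV.
#' @param generator Named list of overrides passed to [default_config()].
#' @param lambda0,tau Retention rule parameters.
#' @param grid_size Lasso penalty grid size.
#' @param linkage,k Clustering controls.
#' @param model_kind Classifier family: `"svm"`, `"rf"` or `"xgb"`.
#' @param test_fraction,cv_folds Split and cross-validation controls.
#' @param routing Test-time routing (`"surgeon"` or `"centroid"`).
#' @param months Span of the learning-curve analysis.
#' @param seed Master seed for the run.
#' @return A list of class `ddss_run_config`.
#' @export
ddss_run_config <- function(records_csv = NULL, generator = list(),
                            lambda0 = 0.01, tau = 0.05, grid_size = 200L,
                            linkage = "average", k = 2L,
                            model_kind = "svm", test_fraction = 0.2,
                            cv_folds = 5L, routing = "surgeon",
                            months = 10L, seed = 1L) {
  structure(
    list(records_csv = records_csv, generator = generator,
         lambda0 = lambda0, tau = tau, grid_size = as.integer(grid_size),
         linkage = linkage, k = as.integer(k), model_kind = model_kind,
         test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
         routing = routing, months = as.integer(months),
         seed = as.integer(seed)),
    class = "ddss_run_config"
  )
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    raw <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
    config <- raw
  }
  if (inherits(config, "ddss_run_config")) return(config)
  if (!is.list(config)) stop("config must be a list, path or ddss_run_config")
  do.call(ddss_run_config, config)
}

config_records <- function(cfg) {
  if (!is.null(cfg$records_csv)) {
    if (!file.exists(cfg$records_csv)) {
      stop("records CSV not found: ", cfg$records_csv)
    }
    impute_missing(read_records(cfg$records_csv), global_fallback = TRUE)
  } else {
    gen_args <- cfg$generator
    if (is.null(gen_args$seed)) gen_args$seed <- cfg$seed
    generate_dataset(do.call(default_config, gen_args))
  }
}

#' Run the full decoupling-prediction workflow
#'
#' Executes records -> per-surgeon Lasso trajectories -> Levenshtein
#' decoupling -> per-group classifier training -> test-set evaluation, and
#' (when `out_dir` is given) writes the sequences, distance matrix,
#' partition, per-cell metrics, predictions and a JSON run manifest.
#'
#' @param config A `ddss_run_config`, a plain list of its fields, or a
#'   path to a YAML/JSON file holding them.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return Invisibly, a list with `records`, `sequences`, `partition`,
#'   `duration_test`, `bundle`, `predictions`, `metrics` and (if written)
#'   `artifacts`.
#' @export
run_ddss <- function(config = ddss_run_config(), out_dir = NULL) {
  cfg <- load_run_config(config)
  records <- config_records(cfg)
  if (length(unique(records$surgeon_id)) < 2L) {
    stop("decoupler stage: need >= 2 surgeons")
  }
  schema <- ddss_schema()

  partition <- decouple_surgeons(records, schema, k = cfg$k,
                                 linkage = cfg$linkage,
                                 grid_size = cfg$grid_size)
  seqs <- attr(partition, "sequences")
  dtest <- group_duration_test(records, partition)

  sp <- split_dataset(records, test_fraction = cfg$test_fraction,
                      seed = cfg$seed)
  bundle <- train_models(sp$train, partition, schema,
                         model_kind = cfg$model_kind,
                         cv_folds = cfg$cv_folds, seed = cfg$seed)
  pred <- predict(bundle, sp$test, method = cfg$routing)
  metrics <- evaluate_predictions(
    label_class(sp$test$duration_s), pred$.pred_class,
    as.matrix(pred[c(".pred_1", ".pred_2", ".pred_3")])
  )

  res <- list(records = records, sequences = seqs, partition = partition,
              duration_test = dtest, bundle = bundle, predictions = pred,
              metrics = metrics)
  if (!is.null(out_dir)) {
    res$artifacts <- write_run_artifacts(res, cfg, out_dir)
  }
  invisible(res)
}

write_run_artifacts <- function(res, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    p
  }
  paths$sequences <- w(res$sequences[c("surgeon_id", "n_records",
                                       "sequence")], "sequences.csv")
  paths$partition <- w(as.data.frame(res$partition), "partition.csv")
  D <- attr(res$partition, "distances")
  paths$distances <- w(cbind(surgeon_id = rownames(D), as.data.frame(D)),
                       "distances.csv")
  paths$duration_test <- w(res$duration_test, "duration_test.csv")
  paths$metrics <- w(glance(res$metrics), "metrics.csv")
  paths$model <- w(glance(res$bundle), "model_selection.csv")
  paths$predictions <- w(res$predictions, "predictions.csv")

  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_json, auto_unbox = TRUE,
                       null = "null", digits = NA)
  manifest <- list(
    package = "ddss",
    version = as.character(utils::packageVersion("ddss")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    artifacts = lapply(paths, basename)
  )
  paths$config <- cfg_json
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  paths
}

#' Run the monthly learning-curve analysis
#'
#' Pools records by month since joining and traces the retained difficulty
#' factors over the first `months` months (see [monthly_trajectories()]).
#' With `out_dir` set, writes a per-month coefficient table and a retained
#' -factor timeline CSV.
#'
#' @inheritParams run_ddss
#' @return Invisibly, a list with the `ddss_learning_curve` tibble
#'   (`curve`), the input `records`, and written `artifacts` if any.
#' @export
run_learning_curve <- function(config = ddss_run_config(),
                               out_dir = NULL) {
  cfg <- load_run_config(config)
  records <- config_records(cfg)
  if (!any(records$month_index >= 1L)) stop("records carry no month data")
  schema <- ddss_schema()
  curve <- monthly_trajectories(records, schema, months = cfg$months,
                                lambda0 = cfg$lambda0, tau = cfg$tau,
                                grid_size = cfg$grid_size)
  res <- list(curve = curve, records = records)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    coef_tbl <- curve |>
      dplyr::filter(!purrr::map_lgl(.data$coefs, is.null)) |>
      dplyr::mutate(coefs = purrr::map(.data$coefs, ~ tibble::tibble(
        indicator = names(.x), coefficient = unname(.x)))) |>
      dplyr::select("month", "coefs") |>
      tidyr::unnest("coefs")
    p1 <- file.path(out_dir, "monthly_coefficients.csv")
    utils::write.csv(as.data.frame(coef_tbl), p1, row.names = FALSE)
    timeline <- curve |>
      dplyr::mutate(retained = purrr::map_chr(
        .data$retained, ~ paste(.x$indicator, collapse = ">"))) |>
      dplyr::select("month", "n_records", "n_surgeons", "n_retained",
                    "retained")
    p2 <- file.path(out_dir, "retained_timeline.csv")
    utils::write.csv(as.data.frame(timeline), p2, row.names = FALSE)
    res$artifacts <- list(coefficients = p1, timeline = p2)
  }
  invisible(res)
}
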