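#' Per-surgeon train/test split
#'
#' Splits each surgeon's records 4:1 by default (test count =
#' `round(test_fraction * n)`, minimum 1) and pools the per-surgeon
#' training sets into the overall training set. With
#' `stratify_by_class = TRUE` the test quota is allocated within each
#' difficulty class as `round(test_fraction * n_class)`.
#'
#' @param records A `ddss_records` tibble.
#' @param test_fraction Fraction of each surgeon's records held out
#'   (default 0.2).
#' @param stratify_by_class Stratify the split by difficulty class within
#'   surgeon (default TRUE).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with elements `train` and `test`, both `ddss_records`
#'   tibbles; disjoint, with union equal to the input.
#' @export
split_dataset <- function(records, test_fraction = 0.2,
                          stratify_by_class = TRUE, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  cls <- label_class(records$duration_s)
  test_ids <- withr::with_seed(seed, {
    unlist(lapply(sort(unique(records$surgeon_id)), function(s) {
      idx <- which(records$surgeon_id == s)
      n <- length(idx)
      if (n < 2L) {
        stop("surgeon ", s, " has only ", n,
             " record(s); need >= 2 to split")
      }
      n_test <- max(1L, round(test_fraction * n))
      if (stratify_by_class) {
        picked <- unlist(lapply(sort(unique(cls[idx])), function(k) {
          pool <- idx[cls[idx] == k]
          n_k <- round(test_fraction * length(pool))
          if (n_k > 0) sample(pool, n_k) else integer(0)
        }))
        # stratified rounding can miss the per-surgeon minimum of 1
        if (!length(picked)) picked <- sample(idx, 1L)
        picked
      } else {
        sample(idx, n_test)
      }
    }))
  })
  is_test <- seq_len(nrow(records)) %in% test_ids
  list(train = new_ddss_records(records[!is_test, , drop = FALSE]),
       test = new_ddss_records(records[is_test, , drop = FALSE]))
}

# hyperparameter grids; svm bandwidths are 4 log-spaced values plus the
# variance-scaled default 1/p (features are standardized, so var = 1)
model_grid <- function(model_kind, p) {
  switch(model_kind,
    svm = expand.grid(cost = c(0.1, 1, 10, 100, 1000),
                      gamma = sort(unique(c(10^seq(-3, 0, length.out = 4),
                                            1 / p)))),
    rf = expand.grid(num_trees = c(100L, 300L), max_depth = c(0L, 5L, 10L)),
    xgb = expand.grid(max_depth = c(3L, 6L), eta = c(0.1, 0.3)),
    stop("unknown model_kind: ", model_kind)
  )
}

fit_clf <- function(model_kind, x, y, params, seed) {
  # y: factor over the classes present in this cluster's training data
  switch(model_kind,
    svm = withr::with_seed(seed, {
      e1071::svm(x, y, kernel = "radial", cost = params$cost,
                 gamma = params$gamma, probability = TRUE, scale = FALSE)
    }),
    rf = ranger::ranger(
      x = x, y = y, num.trees = params$num_trees,
      max.depth = params$max_depth, probability = TRUE,
      seed = seed, num.threads = 1
    ),
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      withr::with_seed(seed, xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = nlevels(y),
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = 200L, verbose = 0
      ))
    }
  )
}

predict_clf <- function(model_kind, fit, x, train_levels) {
  prob <- switch(model_kind,
    svm = {
      pr <- stats::predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")[, train_levels, drop = FALSE]
    },
    rf = {
      pr <- stats::predict(fit, data = x, num.threads = 1)$predictions
      pr[, train_levels, drop = FALSE]
    },
    xgb = {
      pr <- stats::predict(fit, xgboost::xgb.DMatrix(x))
      m <- matrix(pr, ncol = length(train_levels), byrow = TRUE)
      colnames(m) <- train_levels
      m / rowSums(m) # booster emits float32 softmax; renormalize in double
    }
  )
  # expand to the full 3-class simplex; absent training classes score 0
  out <- matrix(0, nrow = nrow(x), ncol = 3,
                dimnames = list(NULL, c("1", "2", "3")))
  out[, train_levels] <- prob
  out
}

macro_auc_score <- function(y_true, scores, warn = FALSE) {
  aucs <- vapply(c("1", "2", "3"), function(k) {
    pos <- y_true == as.integer(k)
    if (!any(pos) || all(pos)) return(NA_real_)
    r <- rank(scores[, k])
    n_pos <- sum(pos)
    (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * (length(pos) - n_pos))
  }, numeric(1))
  if (anyNA(aucs) && warn) {
    warning("one-vs-rest AUC undefined for class(es) ",
            paste(c("1", "2", "3")[is.na(aucs)], collapse = ", "),
            " (absent from y_true); macro average taken over the rest")
  }
  mean(aucs, na.rm = TRUE)
}

#' Train per-cluster difficulty classifiers
#'
#' For each experience group in the partition: standardize that group's
#' training features, select hyperparameters by seeded `cv_folds`-fold
#' cross-validated grid search maximizing out-of-fold macro-average AUC
#' (SVM-RBF: cost x bandwidth; random forest: trees x depth; XGBoost:
#' depth x learning rate at 200 rounds), and refit the winning
#' configuration on the full group with probability outputs.
#'
#' @param train Training records (`ddss_records`).
#' @param partition A `ddss_partition` assigning surgeons to groups.
#' @param schema Indicator schema.
#' @param model_kind `"svm"`, `"rf"` or `"xgb"`.
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Integer seed governing folds and stochastic fits.
#' @return A `ddss_bundle`: per-cluster fitted model, standardization
#'   statistics, selected hyperparameters and CV score, plus the partition
#'   and training records for routing at prediction time.
#' @export
train_models <- function(train, partition, schema = ddss_schema(),
                         model_kind = c("svm", "rf", "xgb"),
                         cv_folds = 5L, seed = 1L) {
  model_kind <- match.arg(model_kind)
  df <- dplyr::inner_join(train, partition, by = "surgeon_id")
  if (!nrow(df)) stop("no training records match the partition")
  clusters <- sort(unique(df$cluster))
  fits <- lapply(clusters, function(cl) {
    sub <- df[df$cluster == cl, , drop = FALSE]
    y_all <- label_class(sub$duration_s)
    lv <- as.character(sort(unique(y_all)))
    if (length(lv) < 2L) {
      stop("cluster ", cl, " has a single difficulty class; cannot train")
    }
    y <- factor(as.character(y_all), levels = lv)
    stats_ <- train_feature_stats(sub, schema)
    x <- standardize_features(sub, schema, stats_)
    grid <- model_grid(model_kind, ncol(x))
    folds <- withr::with_seed(seed, sample(rep_len(seq_len(cv_folds),
                                                   nrow(sub))))
    cv_scores <- vapply(seq_len(nrow(grid)), function(g) {
      oof <- matrix(NA_real_, nrow = nrow(sub), ncol = 3)
      colnames(oof) <- c("1", "2", "3")
      for (f in seq_len(cv_folds)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2L) next
        lv_f <- levels(droplevels(y[tr]))
        fit <- fit_clf(model_kind, x[tr, , drop = FALSE],
                       droplevels(y[tr]), grid[g, , drop = FALSE],
                       seed = seed + f)
        oof[!tr, ] <- predict_clf(model_kind, fit, x[!tr, , drop = FALSE],
                                  lv_f)
      }
      ok <- !is.na(oof[, 1])
      if (!any(ok)) return(NA_real_)
      macro_auc_score(y_all[ok], oof[ok, , drop = FALSE])
    }, numeric(1))
    best <- which.max(cv_scores) # first maximum: deterministic tie-break
    fit <- fit_clf(model_kind, x, y, grid[best, , drop = FALSE], seed = seed)
    list(cluster = cl, fit = fit, stats = stats_, classes = lv,
         best_params = as.list(grid[best, , drop = FALSE]),
         cv_macro_auc = cv_scores[best])
  })
  structure(
    list(model_kind = model_kind, clusters = stats::setNames(
           fits, paste0("cluster", clusters)),
         cluster_ids = clusters, partition = partition, train = train,
         schema = schema, seed = seed),
    class = "ddss_bundle"
  )
}

#' @export
print.ddss_bundle <- function(x, ...) {
  cat("<ddss_bundle> ", x$model_kind, " models for ",
      length(x$cluster_ids), " cluster(s)\n", sep = "")
  for (cl in x$clusters) {
    cat("  cluster ", cl$cluster, ": params ",
        paste(names(cl$best_params), unlist(cl$best_params),
              sep = "=", collapse = ", "),
        ", CV macro-AUC ", round(cl$cv_macro_auc, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Glance at a trained bundle
#'
#' @param x A `ddss_bundle`.
#' @param ... Unused.
#' @return One row per cluster: selected hyperparameters and CV score.
#' @export
glance.ddss_bundle <- function(x, ...) {
  dplyr::bind_rows(lapply(x$clusters, function(cl) {
    tibble::tibble(model_kind = x$model_kind, cluster = cl$cluster,
                   cv_macro_auc = cl$cv_macro_auc,
                   params = paste(names(cl$best_params),
                                  unlist(cl$best_params),
                                  sep = "=", collapse = ", "))
  }))
}

#' Predict difficulty classes for test records
#'
#' Each test record is routed to an experience group (see
#' [assign_samples()]) and scored by that group's classifier. Scores form
#' a probability simplex over the three classes.
#'
#' @param object A `ddss_bundle` from [train_models()].
#' @param newdata Test records (`ddss_records`).
#' @param method Routing method passed to [assign_samples()].
#' @param ... Unused.
#' @return A tibble with columns `record_id`, `cluster`, `.pred_class`
#'   (integer 1-3) and `.pred_1`, `.pred_2`, `.pred_3`.
#' @export
predict.ddss_bundle <- function(object, newdata,
                                method = c("surgeon", "centroid"), ...) {
  method <- match.arg(method)
  routed <- assign_samples(newdata, object$partition, object$train,
                           object$schema, method = method)
  out <- tibble::tibble(record_id = newdata$record_id, cluster = routed,
                        .pred_class = NA_integer_,
                        .pred_1 = NA_real_, .pred_2 = NA_real_,
                        .pred_3 = NA_real_)
  for (cl in object$cluster_ids) {
    rows <- which(routed == cl)
    if (!length(rows)) next
    m <- object$clusters[[paste0("cluster", cl)]]
    if (is.null(m)) stop("no trained model for cluster ", cl)
    x <- standardize_features(newdata[rows, , drop = FALSE], object$schema,
                              m$stats)
    prob <- predict_clf(object$model_kind, m$fit, x, m$classes)
    out$.pred_class[rows] <- as.integer(colnames(prob)[max.col(prob,
                                                               "first")])
    out$.pred_1[rows] <- prob[, "1"]
    out$.pred_2[rows] <- prob[, "2"]
    out$.pred_3[rows] <- prob[, "3"]
  }
  if (anyNA(out$.pred_class)) {
    stop("some records were routed to clusters without a trained model")
  }
  out
}

#' Evaluate difficulty predictions
#'
#' Confusion-matrix metrics for the three difficulty classes: overall
#' accuracy, one-vs-rest sensitivity, specificity and F1 per class,
#' macro-F1, and macro-average AUC (unweighted mean of the three
#' one-vs-rest ROC areas; rank/trapezoidal with tied scores averaged).
#'
#' @param y_true Integer vector of true classes (1-3).
#' @param y_pred Integer vector of predicted classes.
#' @param scores Optional n x 3 score matrix (rows on the probability
#'   simplex) for the AUC; columns in class order.
#' @return A `ddss_metrics` object; see [tidy.ddss_metrics()] and
#'   [glance.ddss_metrics()].
#' @export
evaluate_predictions <- function(y_true, y_pred, scores = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  conf <- table(factor(y_true, levels = 1:3),
                factor(y_pred, levels = 1:3), dnn = c("true", "pred"))
  conf <- unclass(conf)
  n <- sum(conf)
  per_class <- dplyr::bind_rows(lapply(1:3, function(k) {
    tp <- conf[k, k]
    fn <- sum(conf[k, ]) - tp
    fp <- sum(conf[, k]) - tp
    tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
      2 * prec * sens / (prec + sens)
    } else NA_real_
    tibble::tibble(class = k, n = tp + fn, sensitivity = sens,
                   specificity = spec, precision = prec, f1 = f1)
  }))
  macro_auc <- if (!is.null(scores)) {
    scores <- as.matrix(scores)
    colnames(scores) <- c("1", "2", "3")
    macro_auc_score(y_true, scores, warn = TRUE)
  } else NA_real_
  structure(
    list(confusion = conf, accuracy = sum(diag(conf)) / n,
         per_class = per_class,
         macro_f1 = mean(per_class$f1, na.rm = TRUE),
         macro_auc = macro_auc, n = n),
    class = "ddss_metrics"
  )
}

#' @export
print.ddss_metrics <- function(x, ...) {
  cat("<ddss_metrics> n = ", x$n,
      ", accuracy = ", round(x$accuracy, 3),
      ", macro-F1 = ", round(x$macro_f1, 3),
      ", macro-AUC = ", round(x$macro_auc, 3), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Per-class metrics of an evaluation
#'
#' @param x A `ddss_metrics` object.
#' @param ... Unused.
#' @return Tibble with one row per difficulty class.
#' @export
tidy.ddss_metrics <- function(x, ...) x$per_class

#' One-row summary of an evaluation
#'
#' @param x A `ddss_metrics` object.
#' @param ... Unused.
#' @return One-row tibble: `accuracy`, `macro_f1`, `macro_auc`, `n`.
#' @export
glance.ddss_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_f1 = x$macro_f1,
                 macro_auc = x$macro_auc, n = x$n)
}

single_cluster_partition <- function(records) {
  out <- tibble::tibble(surgeon_id = sort(unique(records$surgeon_id)),
                        cluster = 1L)
  class(out) <- c("ddss_partition", class(out))
  out
}

#' Compare decoupling strategies across classifiers
#'
#' Runs the full workflow on one seeded per-surgeon split under each
#' combination of partitioner (sequence-based decoupling, the
#' Gaussian-mixture baseline, and no clustering = one pooled model) and
#' classifier, reporting test accuracy and macro-average AUC per cell.
#'
#' @param records A `ddss_records` tibble (planted or real).
#' @param schema Indicator schema.
#' @param seed Integer seed for split, CV folds and stochastic fits.
#' @param model_kinds Subset of `c("svm", "rf", "xgb")`.
#' @param partitioners Subset of `c("lasso", "gmm", "none")`.
#' @param test_fraction,cv_folds Split and CV controls.
#' @param method Test-time routing method (see [assign_samples()]).
#' @return A tibble with columns `partitioner`, `model`, `accuracy`,
#'   `macro_auc`, `n_test`.
#' @export
compare_pipelines <- function(records, schema = ddss_schema(), seed = 1L,
                              model_kinds = c("svm", "rf", "xgb"),
                              partitioners = c("lasso", "gmm", "none"),
                              test_fraction = 0.2, cv_folds = 5L,
                              method = "surgeon") {
  sp <- split_dataset(records, test_fraction = test_fraction, seed = seed)
  y_true <- label_class(sp$test$duration_s)
  parts <- list()
  for (p in partitioners) {
    parts[[p]] <- switch(p,
      lasso = decouple_surgeons(sp$train, schema),
      gmm = gmm_partition(sp$train, schema, seed = seed),
      none = single_cluster_partition(records),
      stop("unknown partitioner: ", p)
    )
  }
  grid <- expand.grid(partitioner = partitioners, model = model_kinds,
                      stringsAsFactors = FALSE)
  dplyr::bind_rows(purrr::pmap(grid, function(partitioner, model) {
    bundle <- train_models(sp$train, parts[[partitioner]], schema,
                           model_kind = model, cv_folds = cv_folds,
                           seed = seed)
    pred <- predict(bundle, sp$test, method = method)
    met <- evaluate_predictions(
      y_true, pred$.pred_class,
      as.matrix(pred[c(".pred_1", ".pred_2", ".pred_3")])
    )
    tibble::tibble(partitioner = partitioner, model = model,
                   accuracy = met$accuracy, macro_auc = met$macro_auc,
                   n_test = met$n)
  }))
}
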