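#' Low-level Lasso regularization path on a numeric design
#'
#' Solves the Lasso objective
#' \deqn{\frac{1}{2n}\|y - \beta_0 - X\beta\|_2^2 + \lambda \|\beta\|_1}
#' by cyclic coordinate descent with covariance (Gram) updates and warm
#' starts along a geometric grid of `grid_size` penalties from
#' \eqn{\lambda_{max}} (the smallest penalty at which all coefficients are
#' zero) down to `lambda_min_ratio` \eqn{\cdot \lambda_{max}}. Predictors
#' are standardized to mean 0 and population standard deviation 1 before
#' fitting; constant columns are dropped from standardization and their
#' coefficients pinned to 0. Coefficients are reported on the standardized
#' scale, which is the scale on which activation order and retention
#' thresholds are defined.
#'
#' @param x Numeric matrix (records in rows, indicators in columns).
#' @param y Numeric response vector (normalized operative duration).
#' @param grid_size Number of penalty grid points (default 200).
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty on
#'   the geometric grid (default 1e-4).
#' @param lambdas Optional explicit, strictly decreasing penalty grid
#'   overriding `grid_size`/`lambda_min_ratio`.
#' @param standardize Standardize columns of `x` internally (default TRUE).
#'   Set to FALSE only when `x` is already standardized.
#' @param tol Coordinate-descent convergence tolerance on the maximum
#'   absolute coefficient change per sweep (default 1e-10).
#' @param max_iter Maximum sweeps per grid point (default 100000).
#' @return An object of class `ddss_lasso_path`: a list with `lambdas`,
#'   `coefs` (grid points x columns), `intercepts`, `n_obs` and
#'   `feature_order`.
#' @seealso [fit_lasso_path()] for the records-level interface.
#' @export
lasso_path_xy <- function(x, y, grid_size = 200L, lambda_min_ratio = 1e-4,
                          lambdas = NULL, standardize = TRUE,
                          tol = 1e-10, max_iter = 100000L) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("need at least 2 records to fit a Lasso path")
  if (length(y) != n) stop("length(y) must match nrow(x)")
  if (pop_sd(y) == 0) stop("response is constant; no path can be fit")

  if (standardize) {
    mu <- colMeans(x)
    sd_ <- apply(x, 2, pop_sd)
    keep <- sd_ > 0
    xs <- sweep(x, 2, mu, "-")
    xs[, keep] <- sweep(xs[, keep, drop = FALSE], 2, sd_[keep], "/")
    xs[, !keep] <- 0
  } else {
    xs <- x
    keep <- apply(x, 2, pop_sd) > 0
  }
  b0 <- mean(y)
  yc <- y - b0

  cvec <- drop(crossprod(xs, yc)) / n
  G <- crossprod(xs) / n
  lambda_max <- max(abs(cvec))
  if (lambda_max == 0) {
    # response uncorrelated with every predictor: flat all-zero path
    lambda_max <- 1
  }
  if (is.null(lambdas)) {
    lambdas <- lambda_max *
      exp(seq(0, log(lambda_min_ratio), length.out = grid_size))
  } else {
    if (any(diff(lambdas) >= 0)) stop("lambdas must be strictly decreasing")
  }

  coefs <- matrix(0, nrow = length(lambdas), ncol = p,
                  dimnames = list(NULL, colnames(x)))
  beta <- numeric(p)
  gdiag <- diag(G)
  active_cols <- which(keep & gdiag > 0)
  for (g in seq_along(lambdas)) {
    lam <- lambdas[g]
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (j in active_cols) {
        rho <- cvec[j] - sum(G[j, ] * beta) + gdiag[j] * beta[j]
        bj_new <- soft_threshold(rho, lam) / gdiag[j]
        d <- abs(bj_new - beta[j])
        if (d > delta) delta <- d
        beta[j] <- bj_new
      }
      if (delta < tol) break
    }
    coefs[g, ] <- beta
  }
  structure(
    list(lambdas = lambdas, coefs = coefs,
         intercepts = rep(b0, length(lambdas)),
         n_obs = n, feature_order = colnames(x)),
    class = "ddss_lasso_path"
  )
}

soft_threshold <- function(z, lam) sign(z) * max(abs(z) - lam, 0)

#' Fit the Lasso trajectory of normalized duration on surgical indicators
#'
#' Records-level interface to [lasso_path_xy()]: the response is the
#' per-surgeon z-scored operative duration and the predictors are the 14
#' ordinal indicator codes, standardized over the fitted subset. Passing a
#' precomputed `response` (e.g. z-scores computed on a larger dataset)
#' allows pooled fits - per-group or per-month - to reuse stable
#' per-surgeon normalization.
#'
#' @param records A `ddss_records` tibble (a subset of a dataset: one
#'   surgeon, one group, or one month).
#' @param schema An indicator schema.
#' @param grid_size,lambda_min_ratio Penalty grid controls; see
#'   [lasso_path_xy()].
#' @param response Optional numeric response aligned with `records` rows;
#'   defaults to `normalize_durations(records)$duration_z`.
#' @return A `ddss_lasso_path` object whose `feature_order` follows the
#'   schema's indicator order.
#' @examples
#' cfg <- default_config(n_surgeons = 2)
#' ds <- generate_dataset(cfg)
#' path <- fit_lasso_path(dplyr::filter(ds, surgeon_id == "s1"))
#' activation_sequence(path)
#' @export
fit_lasso_path <- function(records, schema = ddss_schema(),
                           grid_size = 200L, lambda_min_ratio = 1e-4,
                           response = NULL) {
  if (nrow(records) < 2L) stop("need at least 2 records to fit a Lasso path")
  if (is.null(response)) {
    response <- normalize_durations(records)$duration_z
  }
  if (anyNA(record_matrix(records, schema))) {
    stop("records contain missing indicator codes; run impute_missing() first")
  }
  lasso_path_xy(record_matrix(records, schema), response,
                grid_size = grid_size, lambda_min_ratio = lambda_min_ratio)
}

#' @export
print.ddss_lasso_path <- function(x, ...) {
  cat("<ddss_lasso_path> ", length(x$lambdas), " lambda grid points, ",
      ncol(x$coefs), " indicators, n = ", x$n_obs, "\n", sep = "")
  cat("lambda range: [", format(min(x$lambdas), digits = 4), ", ",
      format(max(x$lambdas), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Lasso path into long format
#'
#' @param x A `ddss_lasso_path`.
#' @param ... Unused.
#' @return A tibble with columns `lambda`, `term` and `estimate`, one row
#'   per (grid point, indicator).
#' @export
tidy.ddss_lasso_path <- function(x, ...) {
  tibble::tibble(
    lambda = rep(x$lambdas, times = ncol(x$coefs)),
    term = rep(x$feature_order, each = length(x$lambdas)),
    estimate = as.vector(x$coefs)
  )
}

#' Feature-activation preference sequence of a Lasso path
#'
#' A surgeon's preference sequence is the order in which indicator
#' coefficients first move away from zero as the penalty decreases along
#' the path: the earlier an indicator activates, the more strongly it
#' drives that surgeon's operative time. Indicators that never activate are
#' omitted. Ties at the same grid point are broken by the larger
#' coefficient magnitude at that point, then by schema order.
#'
#' @param path A `ddss_lasso_path`.
#' @param tol Activation tolerance on `|coefficient|` (default 1e-8).
#' @return Character vector of indicator names in activation order (empty
#'   when no coefficient ever activates).
#' @export
activation_sequence <- function(path, tol = 1e-8) {
  act <- abs(path$coefs) > tol
  first_idx <- apply(act, 2, function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_integer_
  })
  activated <- which(!is.na(first_idx))
  if (!length(activated)) return(character(0))
  mag_at_entry <- vapply(activated, function(j) {
    abs(path$coefs[first_idx[j], j])
  }, numeric(1))
  ord <- order(first_idx[activated], -mag_at_entry, activated)
  path$feature_order[activated][ord]
}

#' Zero-to-nonzero transition counts along a Lasso path
#'
#' Diagnostic companion to [activation_sequence()]: counts how many times
#' each coefficient leaves zero along the grid (re-activations after
#' returning to zero included). The preference sequence uses only the first
#' activation; this vector exposes the re-entry behaviour for inspection.
#'
#' @inheritParams activation_sequence
#' @return Named integer vector, one count per indicator.
#' @export
activation_counts <- function(path, tol = 1e-8) {
  act <- abs(path$coefs) > tol
  counts <- apply(act, 2, function(col) {
    sum(diff(c(FALSE, col)) == 1L)
  })
  stats::setNames(as.integer(counts), path$feature_order)
}

#' Coefficients of a Lasso path at an arbitrary penalty
#'
#' Linear interpolation in log-lambda between the two bracketing grid
#' points.
#'
#' @param object A `ddss_lasso_path`.
#' @param lambda0 Penalty at which to evaluate (must lie within the grid).
#' @param ... Unused.
#' @return Named numeric vector of coefficients on the standardized scale.
#' @export
coef.ddss_lasso_path <- function(object, lambda0 = 0.01, ...) {
  lams <- object$lambdas
  if (lambda0 > max(lams) || lambda0 < min(lams)) {
    stop("lambda0 = ", lambda0, " lies outside the fitted grid [",
         format(min(lams), digits = 4), ", ",
         format(max(lams), digits = 4), "]")
  }
  # grid is decreasing; interpolate each coefficient in log-lambda
  lx <- log(lams)
  out <- apply(object$coefs, 2, function(b) {
    stats::approx(lx, b, xout = log(lambda0), rule = 1)$y
  })
  stats::setNames(out, object$feature_order)
}

#' Retained difficulty factors at a truncation penalty
#'
#' Implements the retention rule: evaluate the path at the truncation
#' penalty `lambda0` and keep the indicators whose coefficient magnitude is
#' at least `tau`. The retained set names the factors that significantly
#' affect operative difficulty for the fitted records.
#'
#' @param path A `ddss_lasso_path`.
#' @param lambda0 Truncation penalty (default 0.01).
#' @param tau Magnitude threshold (default 0.05).
#' @return A tibble with columns `indicator` and `coefficient`, ordered by
#'   descending magnitude.
#' @seealso [retain_coefficients()] for applying the rule to a plain
#'   coefficient vector.
#' @export
retained_features <- function(path, lambda0 = 0.01, tau = 0.05) {
  retain_coefficients(coef(path, lambda0 = lambda0), tau = tau)
}

#' Apply the magnitude retention rule to a coefficient vector
#'
#' @param coefs Named numeric vector of coefficients.
#' @param tau Magnitude threshold (default 0.05).
#' @return A tibble with columns `indicator` and `coefficient` for entries
#'   with `|coefficient| >= tau`, ordered by descending magnitude.
#' @examples
#' retain_coefficients(c(Angle = 0.17, Resistance = 0.10, Age = 0.01))
#' @export
retain_coefficients <- function(coefs, tau = 0.05) {
  keep <- which(abs(coefs) >= tau)
  out <- tibble::tibble(
    indicator = names(coefs)[keep],
    coefficient = unname(coefs[keep])
  )
  dplyr::arrange(out, dplyr::desc(abs(.data$coefficient)))
}

#' Per-surgeon preference sequences
#'
#' Fits one Lasso path per surgeon (response: that surgeon's z-scored
#' durations) and extracts each activation-order preference sequence.
#'
#' @param records A `ddss_records` tibble covering one or more surgeons,
#'   each with at least 2 records and non-constant durations.
#' @param schema An indicator schema.
#' @param grid_size,lambda_min_ratio Passed to [fit_lasso_path()].
#' @return A tibble with one row per surgeon: `surgeon_id`, `n_records`,
#'   `tokens` (list of character vectors) and `sequence` (tokens joined
#'   with `">"`), ordered by surgeon id.
#' @export
preference_sequences <- function(records, schema = ddss_schema(),
                                 grid_size = 200L, lambda_min_ratio = 1e-4) {
  ids <- sort(unique(records$surgeon_id))
  purrr::map(ids, function(s) {
    df <- records[records$surgeon_id == s, , drop = FALSE]
    path <- fit_lasso_path(df, schema, grid_size = grid_size,
                           lambda_min_ratio = lambda_min_ratio)
    toks <- activation_sequence(path)
    tibble::tibble(surgeon_id = s, n_records = nrow(df),
                   tokens = list(toks),
                   sequence = paste(toks, collapse = ">"))
  }) |>
    dplyr::bind_rows()
}

#' Monthly learning-curve trajectories
#'
#' Pools the records of all surgeons month by month (month 1 = each
#' surgeon's first month in the department) and fits one Lasso path per
#' month, recording the full coefficient vector at the truncation penalty
#' and the retained difficulty factors. The shrinking retained set over
#' months traces how novice surgeons converge onto the core factors.
#'
#' @param records A `ddss_records` tibble.
#' @param schema An indicator schema.
#' @param months Number of months to span, from 1 (default 10). Months with
#'   fewer than 2 records are reported empty, not errors.
#' @param lambda0,tau Retention rule parameters (defaults 0.01, 0.05).
#' @param grid_size Penalty grid size per month.
#' @return A tibble of class `ddss_learning_curve` with one row per month:
#'   `month`, `n_records`, `n_surgeons`, `coefs` (list of named vectors or
#'   NULL when empty), `retained` (list of tibbles) and `n_retained`.
#' @export
monthly_trajectories <- function(records, schema = ddss_schema(),
                                 months = 10L, lambda0 = 0.01, tau = 0.05,
                                 grid_size = 200L) {
  z <- normalize_durations(records)
  zmap <- stats::setNames(z$duration_z, z$record_id)
  rows <- purrr::map(seq_len(months), function(m) {
    sub <- records[records$month_index == m, , drop = FALSE]
    empty <- tibble::tibble(
      month = m, n_records = nrow(sub),
      n_surgeons = length(unique(sub$surgeon_id)),
      coefs = list(NULL), retained = list(tibble::tibble(
        indicator = character(0), coefficient = numeric(0))),
      n_retained = NA_integer_
    )
    if (nrow(sub) < 2L) return(empty)
    path <- tryCatch(
      fit_lasso_path(sub, schema, grid_size = grid_size,
                     response = unname(zmap[sub$record_id])),
      error = function(e) NULL
    )
    if (is.null(path) || lambda0 > max(path$lambdas)) return(empty)
    cf <- coef(path, lambda0 = lambda0)
    ret <- retain_coefficients(cf, tau = tau)
    empty$coefs <- list(cf)
    empty$retained <- list(ret)
    empty$n_retained <- nrow(ret)
    empty
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ddss_learning_curve", class(out))
  out
}
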