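# orthonormal (in the population sense) 3-column design on 4 points:
# X'X/n = I, so the Lasso has the soft-threshold closed form
ortho_design <- function() {
  cbind(f1 = c(1, 1, -1, -1), f2 = c(1, -1, 1, -1), f3 = c(1, -1, -1, 1))
}

test_that("all coefficients are zero at the top of the penalty grid", {
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  path <- lasso_path_xy(x, y)
  expect_true(all(path$coefs[1, ] == 0))
  expect_true(all(diff(path$lambdas) < 0))
  expect_true(all(is.finite(path$coefs)))
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  x <- ortho_design()
  set.seed(2)
  y <- rnorm(4)
  path <- lasso_path_xy(x, y, grid_size = 50, standardize = FALSE)
  cvec <- drop(crossprod(x, y - mean(y))) / 4
  for (g in c(1, 10, 25, 50)) {
    lam <- path$lambdas[g]
    expect_equal(path$coefs[g, ],
                 sign(cvec) * pmax(abs(cvec) - lam, 0),
                 tolerance = 1e-8)
  }
})

test_that("path coefficients match glmnet on random instances", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  for (i in 1:5) {
    x <- matrix(rnorm(50 * 6), 50, 6)
    y <- drop(x %*% c(2, -1, 0.5, 0, 0, 0)) + rnorm(50)
    xs <- scale(x, scale = apply(x, 2, ddss:::pop_sd))
    path <- lasso_path_xy(xs, y, grid_size = 200, standardize = FALSE)
    g <- glmnet::glmnet(xs, y, lambda = path$lambdas, standardize = FALSE,
                        thresh = 1e-14, maxit = 1e7)
    cf <- t(as.matrix(stats::coef(g)))[, -1]
    expect_lt(max(abs(cf - path$coefs)), 1e-6)
  }
})

test_that("activation order on orthonormal designs follows |correlation|", {
  x <- ortho_design()
  y <- 3 * x[, 1] + 1 * x[, 2] # x3 orthogonal to y
  path <- lasso_path_xy(x, y, standardize = FALSE)
  expect_identical(activation_sequence(path), c("f1", "f2"))

  # response uncorrelated with every feature: empty sequence
  y0 <- c(1, -1, -1, 1) * 0 + c(0.5, -0.5, -0.5, 0.5)
  x2 <- ortho_design()[, 1:2]
  expect_identical(activation_sequence(lasso_path_xy(x2, y0,
                                                     standardize = FALSE)),
                   character(0))
})

test_that("default-grid activation order agrees with a dense-grid oracle", {
  set.seed(4)
  agree <- logical(100)
  for (i in 1:100) {
    x <- matrix(rnorm(30 * 5), 30, 5)
    b <- rnorm(5) * rbinom(5, 1, 0.6)
    y <- drop(x %*% b) + rnorm(30, sd = 0.5)
    colnames(x) <- paste0("f", 1:5)
    p200 <- lasso_path_xy(x, y, grid_size = 200)
    p2000 <- lasso_path_xy(x, y, grid_size = 2000)
    agree[i] <- identical(activation_sequence(p200),
                          activation_sequence(p2000))
  }
  expect_gte(mean(agree), 0.95)
})

test_that("paths are scale-equivariant and sequences scale-invariant", {
  set.seed(5)
  x <- matrix(rnorm(40 * 4), 40, 4)
  colnames(x) <- paste0("f", 1:4)
  y <- drop(x %*% c(1, -0.5, 0, 0.2)) + rnorm(40, sd = 0.3)
  p1 <- lasso_path_xy(x, y)
  p2 <- lasso_path_xy(x, 3 * y)
  expect_equal(p2$lambdas, 3 * p1$lambdas)
  expect_equal(p2$coefs, 3 * p1$coefs, tolerance = 1e-7)
  expect_identical(activation_sequence(p1), activation_sequence(p2))
})

test_that("coefficient interpolation and retention behave as specified", {
  set.seed(6)
  x <- matrix(rnorm(200 * 4), 200, 4)
  colnames(x) <- paste0("f", 1:4)
  y <- drop(x %*% c(0.8, 0.3, 0, 0)) + rnorm(200, sd = 0.1)
  path <- lasso_path_xy(x, y)
  expect_error(coef(path, lambda0 = 2 * max(path$lambdas)), "outside")

  # interpolated coefficients at a grid point equal the stored row
  g <- 57
  expect_equal(unname(coef(path, lambda0 = path$lambdas[g])),
               unname(path$coefs[g, ]), tolerance = 1e-9)

  # monotone in tau: raising the threshold never adds entries
  r_lo <- retained_features(path, tau = 0.02)
  r_hi <- retained_features(path, tau = 0.25)
  expect_true(all(r_hi$indicator %in% r_lo$indicator))

  # all-zero coefficient vector: empty retention
  expect_identical(nrow(retain_coefficients(c(a = 0, b = 0))), 0L)
})

test_that("a planted coefficient is recovered from synthetic records", {
  # single dominant indicator, low noise: retention finds exactly it
  sg <- surgeon_specs_default()[1, ]
  sg$tenure_months <- 1L
  sg$records_per_month <- 1000L
  sch <- ddss_schema()
  beta <- stats::setNames(numeric(14), sch$abbreviation)
  beta["Depth"] <- 0.8
  cfg <- default_config(surgeons = sg, beta_experienced = beta,
                        noise_sd = 0.1, seed = 8)
  ds <- generate_dataset(cfg)
  path <- fit_lasso_path(ds)
  ret <- retained_features(path)
  expect_identical(ret$indicator, "Depth")
  expect_identical(activation_sequence(path)[1], "Depth")
})

test_that("activation counts flag re-entries without changing the sequence", {
  set.seed(9)
  x <- matrix(rnorm(40 * 4), 40, 4)
  colnames(x) <- paste0("f", 1:4)
  y <- drop(x %*% c(1, 0.4, -0.2, 0)) + rnorm(40, sd = 0.2)
  path <- lasso_path_xy(x, y)
  counts <- activation_counts(path)
  seqs <- activation_sequence(path)
  expect_true(all(counts[seqs] >= 1L))
  expect_true(all(counts[setdiff(names(counts), seqs)] == 0L))
})

test_that("monthly trajectories span all months and flag empty ones", {
  cfg <- small_clinic_cfg(13)
  ds <- generate_dataset(cfg)
  ds7 <- ds[ds$month_index != 2L, , drop = FALSE] # knock out month 2
  lc <- monthly_trajectories(ds7, months = 4)
  expect_identical(lc$month, 1:4)
  expect_identical(lc$n_records[2], 0L)
  expect_true(is.na(lc$n_retained[2]))
  expect_identical(lc$n_records[4], 0L) # beyond every tenure
  expect_gt(lc$n_retained[1], 0L)
})

test_that("experienced-only cohorts retain only core factors at adequate n", {
  # month-level retention needs a few hundred records per month before the
  # finite-sample noise floor drops safely below the 0.05 threshold
  sg <- surgeon_specs_default()[1:3, ]
  sg$tenure_months <- 3L
  sg$records_per_month <- 100L # 300 records per month across the cohort
  cfg <- default_config(surgeons = sg, seed = 21)
  ds <- generate_dataset(cfg)
  lc <- monthly_trajectories(ds, months = 3)
  for (m in 1:3) {
    expect_true(all(lc$retained[[m]]$indicator %in% cfg$core),
                info = paste("month", m))
  }
})
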