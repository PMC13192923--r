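test_that("median imputation fills holes with the training median", {
  p <- data.frame(subject_id = "A", t = 0:2, env__a = c(1, NA, 3))
  st <- fit_impute(p)
  expect_equal(apply_impute(p, st)$env__a, c(1, 2, 3))
  # untouched when nothing is missing
  p2 <- data.frame(subject_id = "A", t = 0:2, env__a = c(4, 5, 6))
  expect_identical(apply_impute(p2, fit_impute(p2)), p2)
})

test_that("imputation matches a sort-and-middle oracle under MCAR holes", {
  set.seed(21)
  p <- as.data.frame(matrix(rnorm(100), 20, 5))
  names(p) <- paste0("dom__f", 1:5)
  p[matrix(runif(100) < 0.3, 20, 5)] <- NA
  st <- fit_impute(p, names(p))
  out <- apply_impute(p, st)
  for (cl in names(p)) {
    v <- sort(p[[cl]][!is.na(p[[cl]])])
    m <- length(v)
    oracle <- if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
    expect_equal(unname(st$medians[[cl]]), oracle)
    expect_equal(out[[cl]][is.na(p[[cl]])],
                 rep(oracle, sum(is.na(p[[cl]]))))
  }
})

test_that("an all-missing training column is rejected by name", {
  p <- data.frame(env__a = c(NA_real_, NA_real_), env__b = c(1, 2))
  expect_error(fit_impute(p, c("env__a", "env__b")), "env__a")
})

test_that("standardization uses the population convention and train parameters", {
  p <- data.frame(env__a = c(2, 4, 6))
  st <- fit_standardize(p, "env__a")
  expect_equal(apply_standardize(p, st)$env__a,
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # held-out rows transformed with train mu/sigma, no refit
  test <- data.frame(env__a = c(10, 0))
  expect_equal(apply_standardize(test, st)$env__a,
               (c(10, 0) - st$mu[["env__a"]]) / st$sigma[["env__a"]])
})

test_that("zero-variance features are dropped with a warning", {
  p <- data.frame(env__a = c(1, 1, 1), env__b = c(1, 2, 3))
  expect_warning(st <- fit_standardize(p, c("env__a", "env__b")),
                 "env__a")
  expect_equal(st$feature_cols, "env__b")
  expect_false("env__a" %in% names(apply_standardize(p, st)))
})

test_that("residualization with intercept only is column centering", {
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(residualize(X), scale(X, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a covariate used as predictor residualizes to zero", {
  C <- cbind(rnorm(20), rbinom(20, 1, .5))
  expect_lt(max(abs(residualize(C, C))), 1e-10)
})

test_that("residuals are orthogonal to covariates and match least squares", {
  set.seed(31)
  for (k in 1:50) {
    X <- matrix(rnorm(50 * 8), 50, 8)
    C <- cbind(1, matrix(rnorm(50 * 3), 50, 3))
    Xr <- residualize(X, C)
    expect_lt(max(abs(crossprod(C, Xr))), 1e-8)
    # independent normal-equations oracle per column
    P <- C %*% solve(crossprod(C)) %*% t(C)
    expect_equal(Xr, X - P %*% X, tolerance = 1e-9, ignore_attr = TRUE)
    # idempotence
    expect_equal(residualize(Xr, C), Xr, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("rank-deficient covariates are rejected with names", {
  C <- cbind(a = rnorm(10), b = 1:10)
  C <- cbind(C, c = C[, "a"] + C[, "b"])
  expect_error(residualize(matrix(rnorm(10)), C), "collinear")
  p <- data.frame(cov_x = 1:5, cov_y = 2 * (1:5))
  expect_error(covariate_design(p), "cov_y")
})

test_that("out-of-sample residualization reuses the training projection", {
  set.seed(32)
  Xtr <- matrix(rnorm(40 * 4), 40, 4); Ctr <- cbind(1, rnorm(40))
  Xte <- matrix(rnorm(10 * 4), 10, 4); Cte <- cbind(1, rnorm(10))
  st <- fit_residualize(Xtr, Ctr)
  out <- apply_residualize(Xte, Cte, st)
  # oracle: per-column lm coefficients from training rows
  for (j in 1:4) {
    beta <- qr.coef(qr(Ctr), Xtr[, j])
    expect_equal(out[, j], Xte[, j] - as.numeric(Cte %*% beta),
                 tolerance = 1e-10)
  }
})

test_that("site factors are one-hot encoded with a reference level", {
  p <- data.frame(cov_sex = c(0, 1, 0, 1),
                  cov_site = c("s1", "s2", "s3", "s1"))
  C <- covariate_design(p)
  expect_equal(colnames(C), c("(Intercept)", "cov_sex", "cov_sites2",
                              "cov_sites3"))
  expect_equal(unname(C[, "cov_sites2"]), c(0, 1, 0, 0))
})

test_that("the fitted chain applies to held-out subjects without refit", {
  d <- small_model_data(n = 50, seed = 51)
  pp_test <- d$pp[d$pp$subject_id %in% d$split$test, ]
  # training medians/means differ from test ones: recompute with oracle
  raw_test <- d$panel[d$panel$subject_id %in% d$split$test, ]
  imp <- apply_impute(raw_test, d$prep$impute)
  std <- apply_standardize(imp, d$prep$standardize)
  fcol <- d$prep$standardize$feature_cols[1]
  med <- d$prep$impute$medians[[fcol]]
  expect_equal(sort(unique(imp[[fcol]][is.na(raw_test[[fcol]])])), med)
  expect_equal(std[[fcol]],
               (imp[[fcol]] - d$prep$standardize$mu[[fcol]]) /
                 d$prep$standardize$sigma[[fcol]])
})

test_that("preprocess state serializes to JSON", {
  d <- small_model_data(n = 30, seed = 52)
  f <- withr::local_tempfile(fileext = ".json")
  write_preprocess_state(d$prep, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(unlist(obj$mu[1]), d$prep$standardize$mu[1],
               tolerance = 1e-12, ignore_attr = TRUE)
})
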