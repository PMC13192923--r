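#' Fit median imputation on training rows
#'
#' Records the per-column median of each feature over the training panel;
#' [apply_impute()] replaces missing cells with these medians and leaves
#' observed cells untouched. Fitting on training rows only prevents
#' information leaking from held-out subjects.
#'
#' @param panel Training panel (long format).
#' @param feature_cols Numeric feature columns (default: `__` columns).
#' @return A list of class `impute_state` with per-feature medians.
#' @export
fit_impute <- function(panel, feature_cols = feature_columns(panel)) {
  med <- vapply(feature_cols, function(cl) {
    v <- panel[[cl]]
    if (!is.numeric(v)) stopf("feature column '%s' is not numeric", cl)
    if (all(is.na(v))) stopf("feature column '%s' is entirely missing in training data", cl)
    stats::median(v, na.rm = TRUE)
  }, numeric(1))
  structure(list(medians = med, feature_cols = feature_cols),
            class = "impute_state")
}

#' @rdname fit_impute
#' @param state An `impute_state` from [fit_impute()].
#' @export
apply_impute <- function(panel, state) {
  stopifnot(inherits(state, "impute_state"))
  for (cl in state$feature_cols) {
    v <- panel[[cl]]
    v[is.na(v)] <- state$medians[[cl]]
    panel[[cl]] <- v
  }
  panel
}

#' Fit feature standardization on training rows
#'
#' Computes per-feature mean and standard deviation (population convention,
#' divisor n) over the training panel so that `x' = (x - mu) / sigma` has
#' training mean 0 and standard deviation 1. Zero-variance features cannot be
#' standardized and are dropped with a warning; held-out rows are transformed
#' with the training parameters, never re-fitted.
#'
#' @param panel Training panel with no missing feature values.
#' @param feature_cols Feature columns.
#' @return A list of class `standardize_state` with `mu`, `sigma`, retained
#'   `feature_cols`, and any `dropped` columns.
#' @export
fit_standardize <- function(panel, feature_cols = feature_columns(panel)) {
  mu <- vapply(feature_cols, function(cl) mean(panel[[cl]]), numeric(1))
  sigma <- vapply(feature_cols, function(cl) {
    v <- panel[[cl]]
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  dropped <- feature_cols[sigma == 0 | !is.finite(sigma)]
  if (length(dropped))
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  keep <- setdiff(feature_cols, dropped)
  structure(list(mu = mu[keep], sigma = sigma[keep], feature_cols = keep,
                 dropped = dropped),
            class = "standardize_state")
}

#' @rdname fit_standardize
#' @param state A `standardize_state` from [fit_standardize()].
#' @export
apply_standardize <- function(panel, state) {
  stopifnot(inherits(state, "standardize_state"))
  for (cl in state$feature_cols)
    panel[[cl]] <- (panel[[cl]] - state$mu[[cl]]) / state$sigma[[cl]]
  panel[setdiff(names(panel), state$dropped)]
}

#' Build a full-rank covariate design matrix
#'
#' Assembles the covariate matrix `C` used for residualization: an intercept
#' column, numeric covariates as-is, and categorical covariates (e.g. site)
#' one-hot encoded with the first level dropped. Rank-deficient designs are
#' rejected with the offending columns named.
#'
#' @param panel Panel holding the covariate columns.
#' @param covariate_cols Covariate column names (default: `cov_` columns).
#' @return Numeric matrix with an `(Intercept)` column.
#' @export
covariate_design <- function(panel, covariate_cols = covariate_columns(panel)) {
  cols <- list(`(Intercept)` = rep(1, nrow(panel)))
  for (cl in covariate_cols) {
    v <- panel[[cl]]
    if (is.numeric(v)) {
      cols[[cl]] <- v
    } else {
      f <- factor(v)
      for (lev in levels(f)[-1])
        cols[[paste0(cl, lev)]] <- as.numeric(f == lev)
    }
  }
  C <- do.call(cbind, cols)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    bad <- colnames(C)[qrC$pivot[seq(qrC$rank + 1L, ncol(C))]]
    stopf("covariate design is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  C
}

#' Residualize predictors against covariates
#'
#' Replaces each predictor column with its least-squares residual against the
#' covariate matrix, `X_res = X - C (C'C)^{-1} C' X`, removing
#' covariate-explained variation (confounds such as population
#' stratification). The projection is computed by QR decomposition, which is
#' numerically equivalent to the normal-equations form but stable. When
#' `C = NULL` an intercept-only design is used, i.e. column centering.
#'
#' [fit_residualize()] stores the training-row projection coefficients so
#' held-out rows can be residualized with the training fit ([apply_residualize()]).
#'
#' @param X Numeric predictor matrix.
#' @param C Covariate matrix (an intercept column is appended if absent).
#' @return `residualize()`: the residual matrix. `fit_residualize()`: a
#'   `residualize_state` with the coefficient matrix.
#' @export
residualize <- function(X, C = NULL) {
  st <- fit_residualize(X, C)
  apply_residualize(X, if (is.null(C)) matrix(1, nrow(X), 1) else C, st)
}

#' @rdname residualize
#' @export
fit_residualize <- function(X, C = NULL) {
  X <- as.matrix(X)
  if (is.null(C)) C <- matrix(1, nrow(X), 0)
  C <- ensure_intercept(as.matrix(C))
  if (nrow(C) != nrow(X)) stopf("rows of X and C are not aligned")
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    bad <- colnames(C)[qrC$pivot[seq(qrC$rank + 1L, ncol(C))]] %||% "unnamed"
    stopf("covariate matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qrC, X)
  structure(list(coef = coef, n_cov = ncol(C)), class = "residualize_state")
}

#' @rdname residualize
#' @param state A `residualize_state` from [fit_residualize()].
#' @export
apply_residualize <- function(X, C, state) {
  stopifnot(inherits(state, "residualize_state"))
  X <- as.matrix(X)
  C <- ensure_intercept(as.matrix(C))
  if (ncol(C) != state$n_cov)
    stopf("covariate matrix width (%d) does not match fitted state (%d)",
          ncol(C), state$n_cov)
  X - C %*% state$coef
}

ensure_intercept <- function(C) {
  has_const <- ncol(C) > 0 &&
    any(apply(C, 2, function(v) max(v) == min(v) && v[1] != 0))
  if (!has_const) {
    C <- cbind(`(Intercept)` = 1, C)
  }
  C
}

#' Fit and apply the full preprocessing chain
#'
#' Convenience wrapper running impute -> standardize -> residualize in order,
#' fitted on the training panel only. Residualization pools all training rows
#' across time points by default; `per_timepoint = TRUE` fits a separate
#' projection at each visit index.
#'
#' @param panel Training panel.
#' @param feature_cols Feature columns.
#' @param covariate_cols Covariate columns (`cov_` prefix by default).
#' @param residualize Run the residualization step (default `TRUE`).
#' @param per_timepoint Fit residualization separately per visit index.
#' @return A `preprocess_state`; apply with [apply_preprocess()].
#' @export
fit_preprocess <- function(panel, feature_cols = feature_columns(panel),
                           covariate_cols = covariate_columns(panel),
                           residualize = TRUE, per_timepoint = FALSE) {
  imp <- fit_impute(panel, feature_cols)
  panel <- apply_impute(panel, imp)
  std <- fit_standardize(panel, feature_cols)
  panel <- apply_standardize(panel, std)
  res <- NULL
  if (residualize) {
    if (per_timepoint) {
      res <- lapply(split(seq_len(nrow(panel)), panel$t), function(ix) {
        fit_residualize(as.matrix(panel[ix, std$feature_cols]),
                        covariate_design(panel[ix, , drop = FALSE], covariate_cols))
      })
    } else {
      res <- fit_residualize(as.matrix(panel[std$feature_cols]),
                             covariate_design(panel, covariate_cols))
    }
  }
  structure(list(impute = imp, standardize = std, residualize = res,
                 covariate_cols = covariate_cols,
                 per_timepoint = per_timepoint),
            class = "preprocess_state")
}

#' @rdname fit_preprocess
#' @param state A `preprocess_state` from [fit_preprocess()].
#' @export
apply_preprocess <- function(panel, state) {
  stopifnot(inherits(state, "preprocess_state"))
  panel <- apply_impute(panel, state$impute)
  panel <- apply_standardize(panel, state$standardize)
  fc <- state$standardize$feature_cols
  if (!is.null(state$residualize)) {
    if (state$per_timepoint) {
      for (tv in names(state$residualize)) {
        ix <- which(panel$t == as.integer(tv))
        if (!length(ix)) next
        panel[ix, fc] <- apply_residualize(
          as.matrix(panel[ix, fc]),
          covariate_design(panel[ix, , drop = FALSE], state$covariate_cols),
          state$residualize[[tv]])
      }
    } else {
      panel[, fc] <- apply_residualize(
        as.matrix(panel[, fc]),
        covariate_design(panel, state$covariate_cols),
        state$residualize)
    }
  }
  panel
}

#' Serialize a preprocessing state to JSON
#'
#' Writes medians, standardization parameters, and residualization
#' coefficients so a fitted preprocessing chain can be reused exactly.
#'
#' @param state A `preprocess_state`.
#' @param path Output JSON path.
#' @export
write_preprocess_state <- function(state, path) {
  stopifnot(inherits(state, "preprocess_state"))
  obj <- list(
    medians = as.list(state$impute$medians),
    mu = as.list(state$standardize$mu),
    sigma = as.list(state$standardize$sigma),
    dropped = state$standardize$dropped,
    covariate_cols = state$covariate_cols,
    per_timepoint = state$per_timepoint,
    residualize = if (!is.null(state$residualize) && !state$per_timepoint)
      list(coef = state$residualize$coef, n_cov = state$residualize$n_cov)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
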