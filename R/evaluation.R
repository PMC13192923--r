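#' Regression metrics over valid positions
#'
#' Standard definitions computed only where `valid` is `TRUE`:
#' RMSE, MAE, `R2 = 1 - SS_res / SS_tot` (total sum of squares about the mean
#' of the observed truth), and the Pearson correlation. With constant truth
#' the correlation is undefined and returned as `NA` with a warning.
#'
#' @param y_true,y_pred Numeric vectors / matrices of the same shape.
#' @param valid Logical mask of positions to evaluate (default: all
#'   non-missing).
#' @return Named list: `rmse`, `mae`, `r2`, `r`, `n`.
#' @export
regression_metrics <- function(y_true, y_pred,
                               valid = !is.na(y_true) & !is.na(y_pred)) {
  yt <- as.numeric(y_true[valid])
  yp <- as.numeric(y_pred[valid])
  if (length(yt) < 2) stopf("need >= 2 valid positions")
  res <- yt - yp
  ss_res <- sum(res^2)
  ss_tot <- sum((yt - mean(yt))^2)
  r <- if (stats::sd(yt) == 0 || stats::sd(yp) == 0) {
    warning("constant truth or predictions: Pearson r undefined", call. = FALSE)
    NA_real_
  } else stats::cor(yt, yp)
  list(rmse = sqrt(mean(res^2)), mae = mean(abs(res)),
       r2 = 1 - ss_res / ss_tot, r = r, n = length(yt))
}

#' Classification metrics over valid positions
#'
#' AUROC is the Mann-Whitney probability that a random positive outscores a
#' random negative, with ties counted one half (computed from midranks).
#' AUPRC uses the average-precision step convention,
#' `sum over distinct thresholds of (R_k - R_{k-1}) * P_k`, which avoids the
#' optimistic trapezoidal interpolation on rare events. The Brier score is
#' the mean squared error of the probabilities. With single-class truth,
#' AUROC/AUPRC are undefined (`NA`, with a warning) while Brier is still
#' returned.
#'
#' @param y_true Binary labels (0/1).
#' @param scores Predicted scores; probabilities in `[0, 1]` for Brier.
#' @param valid Logical mask of positions to evaluate.
#' @return Named list: `auroc`, `auprc`, `brier`, `prevalence`, `n`.
#' @export
classification_metrics <- function(y_true, scores,
                                   valid = !is.na(y_true) & !is.na(scores)) {
  y <- as.numeric(y_true[valid])
  s <- as.numeric(scores[valid])
  if (!all(y %in% c(0, 1))) stopf("labels must be 0/1")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  brier <- mean((s - y)^2)
  if (n1 == 0 || n0 == 0) {
    warning("single-class truth: AUROC/AUPRC undefined", call. = FALSE)
    return(list(auroc = NA_real_, auprc = NA_real_, brier = brier,
                prevalence = n1 / length(y), n = length(y)))
  }
  list(auroc = auroc(y, s), auprc = average_precision(y, s), brier = brier,
       prevalence = n1 / length(y), n = length(y))
}

# Mann-Whitney AUROC via midranks; ties count 1/2
auroc <- function(y, s) {
  rk <- rank(s, ties.method = "average")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(rk[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average precision over distinct thresholds, descending
average_precision <- function(y, s) {
  o <- order(s, decreasing = TRUE)
  y <- y[o]; s <- s[o]
  # block ends of tied-score groups
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[ends]
  n_at <- ends
  n1 <- sum(y)
  rec <- tp / n1
  prec <- tp / n_at
  sum(diff(c(0, rec)) * prec)
}


#' Restrict a validity mask to each subject's last valid period
#'
#' Alternative evaluation convention for binary outcomes: keep only the last
#' valid subject-period per subject (one row per subject) instead of pooling
#' all valid person-periods.
#'
#' @param valid Logical matrix (subjects x time).
#' @return Logical matrix with at most one `TRUE` per row.
#' @export
per_subject_last_mask <- function(valid) {
  out <- valid & FALSE
  for (i in seq_len(nrow(valid))) {
    j <- which(valid[i, ])
    if (length(j)) out[i, j[length(j)]] <- TRUE
  }
  out
}
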