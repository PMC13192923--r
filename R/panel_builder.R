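#' Add lagged and change-score outcome columns
#'
#' For a continuous outcome `y` observed on the integer visit grid, adds the
#' lagged outcome `y_{t-1}` and the change score `dy_t = y_t - y_{t-1}`.
#' Both are defined only where the immediately preceding visit index was
#' observed for the same subject; at a subject's first observed visit, or
#' across an unobserved gap, they are marked invalid (`NA` with
#' `y_lag_valid = FALSE`).
#'
#' @param panel Long-format panel with `subject_id`, `t`, and the outcome.
#' @param outcome Name of the continuous outcome column (default `"y"`).
#' @return The panel with `y_lag`, `y_delta`, and `y_lag_valid` columns
#'   (named after `outcome`).
#' @export
build_continuous_targets <- function(panel, outcome = "y") {
  if (!outcome %in% names(panel))
    stopf("outcome column '%s' not present in panel", outcome)
  stopifnot(all(c("subject_id", "t") %in% names(panel)))
  check_unique_visits(panel)
  ord <- order(panel$subject_id, panel$t)
  p <- panel[ord, , drop = FALSE]
  prev_same <- c(FALSE, p$subject_id[-1] == p$subject_id[-nrow(p)] &
                   p$t[-1] == p$t[-nrow(p)] + 1L)
  lag <- c(NA_real_, p[[outcome]][-nrow(p)])
  lag[!prev_same] <- NA_real_
  p[[paste0(outcome, "_lag")]] <- lag
  p[[paste0(outcome, "_delta")]] <- p[[outcome]] - lag
  p[[paste0(outcome, "_lag_valid")]] <- prev_same & !is.na(lag) &
    !is.na(p[[outcome]])
  p[order(ord), , drop = FALSE]
}

check_unique_visits <- function(panel) {
  if (anyDuplicated(panel[c("subject_id", "t")]))
    stopf("duplicate (subject_id, t) rows in panel")
  invisible(TRUE)
}

#' Discrete-time survival coding of an event outcome
#'
#' Expands a (time-to-event, indicator) pair into a per-period binary label
#' sequence: at period `t_a` the label is 1 if the event occurred by then
#' (`delta = 1` and `T <= t_a`), 0 while the subject is known event-free
#' (`T > t_a`), and missing (`NA`) once a censored subject's follow-up has
#' ended (`delta = 0` and `T <= t_a`). With `drop_post_event = TRUE` the
#' periods strictly after an event are set to `NA` instead of 1, the
#' classical person-period convention.
#'
#' @param event_time Integer event or censoring time `T`.
#' @param event Event indicator `delta` in `{0, 1}`.
#' @param times Ordered integer vector of period indices (default `0:4`).
#' @param drop_post_event Drop periods after the event (default `FALSE`).
#' @return Integer vector of labels (`1`, `0`, or `NA`) along `times`.
#' @export
encode_discrete_time_event <- function(event_time, event, times = 0:4,
                                       drop_post_event = FALSE) {
  assert_that(length(event_time) == 1L && length(event) == 1L,
              "encode_discrete_time_event is per subject; see encode_event_labels")
  assert_that(event %in% c(0L, 1L), "event indicator must be 0 or 1")
  if (is.finite(event_time) && event_time < 0)
    stopf("negative event time")
  lab <- rep(NA_integer_, length(times))
  lab[event == 1L & event_time <= times] <- 1L
  lab[event_time > times] <- 0L
  if (drop_post_event && event == 1L) lab[times > event_time] <- NA_integer_
  lab
}

#' Per-subject discrete-time labels for a whole panel
#'
#' Vectorized wrapper around [encode_discrete_time_event()] that attaches a
#' per-row `event_label` column aligned with each subject's visit index.
#'
#' @param panel Long panel with `subject_id`, `t`, `event`, `event_time`.
#' @inheritParams encode_discrete_time_event
#' @return The panel with an `event_label` column.
#' @export
encode_event_labels <- function(panel, drop_post_event = FALSE) {
  stopifnot(all(c("event", "event_time") %in% names(panel)))
  if (any(panel$event_time < 0, na.rm = TRUE)) stopf("negative event time")
  lab <- rep(NA_integer_, nrow(panel))
  lab[panel$event == 1L & panel$event_time <= panel$t] <- 1L
  lab[panel$event_time > panel$t] <- 0L
  if (drop_post_event)
    lab[panel$event == 1L & panel$t > panel$event_time] <- NA_integer_
  panel$event_label <- lab
  panel
}

#' Build padded, masked model-ready sequences
#'
#' Converts a long panel into fixed-length per-subject sequences padded to
#' `T_max + 1` slots. The observation mask is 1 exactly where the panel has a
#' row; padded slots carry mask 0 and zero feature values, so they contribute
#' nothing to masked losses or metrics. Continuous targets (with lag and
#' change score) and/or discrete-time event labels are carried alongside with
#' their own validity masks.
#'
#' @param panel Long panel; features must already be numeric (preprocessed).
#' @param feature_cols Feature column names (default: all `__` columns).
#' @param T_max Largest visit index (default: max `t` in the panel).
#' @param outcome Continuous outcome column to carry as target, or `NULL`.
#' @param event_labels Carry `event_label` (from [encode_event_labels()]) as
#'   the binary target if present (default `TRUE` when the column exists).
#' @return An object of class `sequence_batch`: list with `X` (array
#'   `n x T x p`), `mask` (`n x T`), `target`, `target_valid`, `lag`,
#'   `delta`, `lag_valid`, `event_label`, `event_valid`, `subjects`,
#'   `times`, `feature_names`.
#' @export
build_sequences <- function(panel, feature_cols = feature_columns(panel),
                            T_max = NULL, outcome = "y",
                            event_labels = "event_label" %in% names(panel)) {
  stopifnot(all(c("subject_id", "t") %in% names(panel)))
  check_unique_visits(panel)
  if (length(feature_cols) == 0) stopf("no feature columns")
  if (anyNA(panel[feature_cols]))
    stopf("features contain missing values; impute before building sequences")
  T_max <- T_max %||% max(panel$t)
  times <- 0:T_max
  subjects <- sort(unique(panel$subject_id))
  n <- length(subjects)
  Tn <- length(times)
  p <- length(feature_cols)

  si <- match(panel$subject_id, subjects)
  ti <- panel$t + 1L
  if (any(panel$t > T_max) || any(panel$t < 0))
    stopf("panel contains t outside 0..T_max")

  X <- array(0, dim = c(n, Tn, p), dimnames = list(subjects, NULL, feature_cols))
  mask <- matrix(0L, n, Tn, dimnames = list(subjects, NULL))
  mask[cbind(si, ti)] <- 1L
  fm <- as.matrix(panel[feature_cols])
  for (j in seq_len(p)) X[cbind(si, ti, j)] <- fm[, j]

  fill <- function(col) {
    m <- matrix(NA_real_, n, Tn, dimnames = list(subjects, NULL))
    if (col %in% names(panel)) m[cbind(si, ti)] <- panel[[col]]
    m
  }
  out <- list(X = X, mask = mask, subjects = subjects, times = times,
              feature_names = feature_cols)
  if (!is.null(outcome) && outcome %in% names(panel)) {
    out$target <- fill(outcome)
    out$target_valid <- (mask == 1L) & !is.na(out$target)
    lagc <- paste0(outcome, "_lag")
    if (lagc %in% names(panel)) {
      out$lag <- fill(lagc)
      out$delta <- fill(paste0(outcome, "_delta"))
      lv <- fill(paste0(outcome, "_lag_valid"))
      out$lag_valid <- (mask == 1L) & !is.na(lv) & (lv == 1)
    }
  }
  if (isTRUE(event_labels)) {
    out$event_label <- fill("event_label")
    out$event_valid <- (mask == 1L) & !is.na(out$event_label)
  }
  structure(out, class = "sequence_batch")
}

#' @export
print.sequence_batch <- function(x, ...) {
  cat(sprintf("Sequence batch: %d subjects x %d time slots x %d features; %d observed cells\n",
              dim(x$X)[1], dim(x$X)[2], dim(x$X)[3], sum(x$mask)))
  invisible(x)
}

#' Flatten a sequence batch back to a long panel
#'
#' Inverse of [build_sequences()]: emits one row per observed (mask = 1)
#' subject-period with the feature values and any carried targets. Padded
#' positions are dropped.
#'
#' @param batch A `sequence_batch`.
#' @return A long data.frame ordered by subject then time.
#' @export
sequences_to_panel <- function(batch) {
  stopifnot(inherits(batch, "sequence_batch"))
  idx <- which(batch$mask == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(subject_id = batch$subjects[idx[, 1]],
                    t = batch$times[idx[, 2]],
                    stringsAsFactors = FALSE)
  fm <- matrix(0, nrow(idx), length(batch$feature_names))
  for (j in seq_along(batch$feature_names))
    fm[, j] <- batch$X[cbind(idx[, 1], idx[, 2], j)]
  colnames(fm) <- batch$feature_names
  if (!is.null(batch$target)) out$y <- batch$target[idx]
  if (!is.null(batch$event_label)) out$event_label <- batch$event_label[idx]
  cbind(out, as.data.frame(fm))
}

#' Extract a subset of subjects from a sequence batch
#'
#' @param batch A `sequence_batch`.
#' @param subjects Subject ids to keep.
#' @return A `sequence_batch` restricted to `subjects`.
#' @export
subset_batch <- function(batch, subjects) {
  keep <- match(subjects, batch$subjects)
  if (anyNA(keep)) stopf("unknown subject ids in subset")
  out <- batch
  out$X <- batch$X[keep, , , drop = FALSE]
  for (f in c("mask", "target", "target_valid", "lag", "delta", "lag_valid",
              "event_label", "event_valid"))
    if (!is.null(batch[[f]])) out[[f]] <- batch[[f]][keep, , drop = FALSE]
  out$subjects <- batch$subjects[keep]
  out
}
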