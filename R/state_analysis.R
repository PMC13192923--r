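#' Graph energy of a state vector
#'
#' The energy of a system-state vector is its mean squared entry,
#' `E = (1/N) sum_j x_j^2` — a scalar summary of system activation.
#' [graph_energy()] is the same quantity computed after one message-passing
#' step, `E_graph = (1/N) sum_j (A x)_j^2`; with a row-normalized
#' non-negative adjacency it never exceeds the raw energy (averaging is a
#' contraction under the mean-square norm).
#'
#' @param x Finite numeric vector.
#' @return Non-negative scalar.
#' @export
energy <- function(x) {
  if (length(x) == 0) stopf("empty state vector")
  mean(x^2)
}

#' @rdname energy
#' @param A Adjacency matrix or `graph_spec`.
#' @export
graph_energy <- function(A, x) energy(message_pass(A, x))

#' Energy-change series over observed time points
#'
#' Consecutive differences `dE_t = E_t - E_{t-1}` over a subject's observed
#' time points; undefined (`NA`) at the first observed point and wherever
#' the series itself is unobserved. With fewer than two observed points the
#' result is all-`NA` with a warning.
#'
#' @param E Numeric energy series (use `NA` at unobserved time points).
#' @return Numeric vector of the same length as `E`.
#' @export
delta_energy <- function(E) {
  obs <- which(!is.na(E))
  out <- rep(NA_real_, length(E))
  if (length(obs) < 2) {
    warning("fewer than 2 observed energies: empty change series", call. = FALSE)
    return(out)
  }
  out[obs[-1]] <- diff(E[obs])
  out
}

#' Detect collapse-like states
#'
#' Flags a time point as collapse-like when its energy increase strictly
#' exceeds the reference mean plus one standard deviation:
#' `collapse_t = 1` iff `dE_t > mu_ref + sd_ref`. The reference population
#' is typically the cohort-wide pool of energy changes so flags are
#' comparable across subjects. A zero-variance reference degrades the
#' threshold to the mean (a message is emitted). `NA` changes are never
#' flagged.
#'
#' @param dE Numeric vector of energy changes.
#' @param reference Reference population of energy changes (>= 2 values);
#'   defaults to `dE` itself.
#' @return Integer vector of 0/1 flags.
#' @export
detect_collapse <- function(dE, reference = dE) {
  ref <- reference[!is.na(reference)]
  if (length(ref) < 2) stopf("reference population needs >= 2 values")
  s <- stats::sd(ref)
  if (s == 0) message("zero-variance reference: collapse threshold equals the mean")
  thr <- mean(ref) + s
  as.integer(!is.na(dE) & dE > thr)
}

#' Per-subject energy traces
#'
#' Computes, for every subject and observed time point, the state energy
#' `E_t`, the graph-propagated energy `E_graph_t` (energy of the
#' message-passed node vector), the energy change `dE_t`, and the collapse
#' flag. The state vector is either the trained graph-temporal model's
#' hidden state `h_t` (default, `source = "hidden_state"`; requires `model`)
#' or the input node-summary vector `x_t` (`source = "node_summaries"`).
#' `E_graph_t` is always computed from the node summaries, where the
#' adjacency matrix is defined.
#'
#' @param batch A `sequence_batch` of node summaries.
#' @param graph A `graph_spec` (for `E_graph` and for `graph_gtrnn` inputs).
#' @param model A `trained_model`, required for `source = "hidden_state"`.
#' @param source State vector used for `E_t` / `dE_t` / collapse.
#' @param reference Collapse reference population: `"cohort"` pools all
#'   subjects' energy changes, `"per_subject"` references each subject to
#'   their own series.
#' @return A data.frame of class `energy_trace` with columns `subject_id`,
#'   `t`, `E`, `E_graph`, `dE`, `collapse`, and attribute `source`.
#' @export
compute_energy_traces <- function(batch, graph = NULL, model = NULL,
                                  source = c("hidden_state", "node_summaries"),
                                  reference = c("cohort", "per_subject")) {
  source <- match.arg(source)
  reference <- match.arg(reference)
  n <- dim(batch$X)[1]; Tn <- dim(batch$X)[2]
  if (source == "hidden_state") {
    if (is.null(model)) stopf("hidden-state energy requires a trained model")
    gr <- if (model$config$architecture == "graph_gtrnn") graph else NULL
    S <- hidden_states(model, batch, gr)
  } else {
    S <- batch$X
  }
  Emat <- apply(S^2, c(1, 2), mean)
  Emat[batch$mask == 0L] <- NA_real_
  Eg <- matrix(NA_real_, n, Tn)
  if (!is.null(graph)) {
    A <- if (inherits(graph, "graph_spec")) graph$A else graph
    for (t in seq_len(Tn)) {
      M <- batch$X[, t, , drop = FALSE]
      dim(M) <- c(n, dim(batch$X)[3])
      Eg[, t] <- rowMeans((M %*% t(A))^2)
    }
    Eg[batch$mask == 0L] <- NA_real_
  }
  dE <- t(apply(Emat, 1, function(e) suppressWarnings(delta_energy(e))))
  flags <- matrix(0L, n, Tn)
  if (reference == "cohort") {
    ref <- dE[!is.na(dE)]
    if (length(ref) >= 2) flags <- matrix(detect_collapse(as.vector(dE), ref),
                                          n, Tn)
  } else {
    for (i in seq_len(n)) {
      ri <- dE[i, !is.na(dE[i, ])]
      if (length(ri) >= 2) flags[i, ] <- detect_collapse(dE[i, ], ri)
    }
  }
  obs <- which(batch$mask == 1L, arr.ind = TRUE)
  obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
  out <- data.frame(subject_id = batch$subjects[obs[, 1]],
                    t = batch$times[obs[, 2]],
                    E = Emat[obs], E_graph = Eg[obs],
                    dE = dE[obs], collapse = flags[obs],
                    stringsAsFactors = FALSE)
  attr(out, "source") <- source
  class(out) <- c("energy_trace", "data.frame")
  out
}

#' Per-subject energy summaries
#'
#' Reduces an energy trace to one row per subject: time-mean energy, energy
#' at the last observed time point, mean energy change, and the count of
#' collapse flags.
#'
#' @param traces An `energy_trace` data.frame.
#' @return Data.frame with one row per subject.
#' @export
summarize_energy <- function(traces) {
  sp <- split(traces, traces$subject_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$t), ]
    data.frame(subject_id = d$subject_id[1],
               mean_energy = mean(d$E, na.rm = TRUE),
               final_energy = d$E[nrow(d)],
               mean_delta = if (all(is.na(d$dE))) NA_real_
                            else mean(d$dE, na.rm = TRUE),
               n_collapse = sum(d$collapse, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Contrast energy summaries between two groups
#'
#' Compares mean energy, final energy, and mean energy change between a
#' high-risk (high-symptom or event/case) group and a comparison group:
#' per-group means over member subjects plus the high-minus-comparison
#' differences.
#'
#' @param traces An `energy_trace`.
#' @param groups Named vector mapping `subject_id` to one of exactly two
#'   labels.
#' @param high Label of the high-risk group (default: the rarer label).
#' @return List of class `group_energy_summary`: `per_group` (one row per
#'   group with n, mean/final energy, mean delta) and `difference`.
#' @export
group_contrast <- function(traces, groups, high = NULL) {
  per <- summarize_energy(traces)
  g <- groups[per$subject_id]
  if (anyNA(g)) stopf("group labels missing for some subjects")
  labs <- unique(g)
  if (length(labs) != 2) stopf("need exactly two non-empty groups, got %d",
                               length(labs))
  if (is.null(high)) high <- labs[which.min(tabulate(match(g, labs)))]
  low <- setdiff(labs, high)
  agg <- function(lbl) {
    d <- per[g == lbl, ]
    c(n = nrow(d), mean_energy = mean(d$mean_energy, na.rm = TRUE),
      final_energy = mean(d$final_energy, na.rm = TRUE),
      mean_delta = mean(d$mean_delta, na.rm = TRUE))
  }
  hi <- agg(high); lo <- agg(low)
  per_group <- data.frame(group = c(high, low), rbind(hi, lo),
                          row.names = NULL)
  diff <- hi[-1] - lo[-1]
  structure(list(per_group = per_group, difference = diff,
                 high = high, comparison = low),
            class = "group_energy_summary")
}

#' @export
print.group_energy_summary <- function(x, ...) {
  cat(sprintf("Energy contrast: %s (n=%d) vs %s (n=%d)\n", x$high,
              x$per_group$n[1], x$comparison, x$per_group$n[2]))
  print(x$per_group, row.names = FALSE)
  cat(sprintf("difference (high - comparison): mean %+.4f, final %+.4f, delta %+.4f\n",
              x$difference[["mean_energy"]], x$difference[["final_energy"]],
              x$difference[["mean_delta"]]))
  invisible(x)
}

#' Split subjects into high- and lower-symptom groups
#'
#' Labels the top quantile of the last observed continuous outcome as the
#' high-symptom group; the cut point is configurable and defaults to the
#' upper quartile.
#'
#' @param panel Long panel with `subject_id`, `t`, and the outcome.
#' @param outcome Outcome column (default `"y"`).
#' @param prob Quantile cut (default 0.75: top quartile is high-symptom).
#' @return Named character vector subject -> `"high"` / `"comparison"`.
#' @export
high_symptom_groups <- function(panel, outcome = "y", prob = 0.75) {
  sp <- split(panel, panel$subject_id)
  last_y <- vapply(sp, function(d) {
    d <- d[!is.na(d[[outcome]]), ]
    if (!nrow(d)) return(NA_real_)
    d[[outcome]][which.max(d$t)]
  }, numeric(1))
  thr <- stats::quantile(last_y, prob, na.rm = TRUE)
  out <- ifelse(last_y > thr, "high", "comparison")
  out[is.na(out)] <- "comparison"
  stats::setNames(out, names(sp))
}

#' Event / no-event group labels
#'
#' @param panel Long panel with `subject_id` and `event`.
#' @return Named character vector subject -> `"event"` / `"no_event"`.
#' @export
event_groups <- function(panel) {
  sp <- split(panel$event, panel$subject_id)
  stats::setNames(ifelse(vapply(sp, function(e) any(e == 1L), logical(1)),
                         "event", "no_event"), names(sp))
}

#' Write energy traces / group summaries to tidy CSV
#'
#' @param x An `energy_trace` or `group_energy_summary`.
#' @param path Output CSV path.
#' @export
write_energy_csv <- function(x, path) {
  if (inherits(x, "group_energy_summary")) x <- x$per_group
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
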