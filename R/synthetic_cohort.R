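#' Specify a synthetic longitudinal cohort
#'
#' Defines the generative model for a synthetic multi-domain panel: per-node
#' latent states follow subject-level AR(1) dynamics, observed features load
#' on their node's latent state with measurement noise, a continuous symptom
#' outcome carries a planted linear signal from a subset of nodes, and a rare
#' binary initiation event is drawn from a per-period logistic hazard
#' calibrated to a target marginal prevalence. A planted "high-risk" subgroup
#' has its latent innovation noise scaled by `volatility_ratio`, emulating
#' dysregulated system dynamics.
#'
#' @param n_subjects Number of subjects.
#' @param n_timepoints Number of visits; time index runs `0:(n_timepoints-1)`.
#' @param n_nodes Number of domain nodes (default 11).
#' @param features_per_node Observed features loading on each node.
#' @param n_pcs Number of principal-component-like covariates.
#' @param n_sites Number of site factor levels.
#' @param continuous_effect_size Fraction of continuous-outcome variance
#'   explained by the planted linear node signal, in `[0, 1)`.
#' @param ar_coefficient AR(1) coefficient of the latent node states, in
#'   `[0, 1)`.
#' @param event_rate Target marginal prevalence of the binary initiation
#'   event (fraction of subjects with an observed event).
#' @param censor_rate Fraction of subjects censored before the final visit.
#' @param volatility_ratio Multiplier on latent innovation noise for the
#'   high-risk subgroup (1 = no planted dysregulation).
#' @param high_risk_fraction Fraction of subjects in the high-risk subgroup.
#' @param missing_rate Per-cell missing-completely-at-random probability for
#'   feature columns.
#' @param hazard_strength Multiplier on the hazard coefficients; scales how
#'   strongly the latent states drive the event hazard (1 = baseline).
#' @param n_signal_nodes Number of nodes carrying outcome signal.
#' @param seed Integer seed; identical spec + seed gives identical output.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [planted_truth()]
#' @export
cohort_spec <- function(n_subjects,
                        n_timepoints = 5L,
                        n_nodes = 11L,
                        features_per_node = 5L,
                        n_pcs = 10L,
                        n_sites = 4L,
                        continuous_effect_size = 0.5,
                        ar_coefficient = 0.6,
                        event_rate = 0.05,
                        censor_rate = 0.15,
                        volatility_ratio = 1,
                        high_risk_fraction = 0.25,
                        missing_rate = 0.1,
                        hazard_strength = 1,
                        n_signal_nodes = 4L,
                        seed = 1L) {
  assert_that(is_count(n_subjects), "n_subjects must be a positive integer")
  assert_that(is_count(n_timepoints, 2L), "n_timepoints must be >= 2")
  assert_that(is_count(n_nodes), "n_nodes must be >= 1")
  assert_that(is_count(features_per_node), "features_per_node must be >= 1")
  assert_that(event_rate >= 0 && event_rate <= 1,
              "event_rate must be in [0, 1]")
  assert_that(ar_coefficient >= 0 && ar_coefficient < 1,
              "ar_coefficient must be in [0, 1)")
  assert_that(continuous_effect_size >= 0 && continuous_effect_size < 1,
              "continuous_effect_size must be in [0, 1)")
  assert_that(censor_rate >= 0 && censor_rate <= 1,
              "censor_rate must be in [0, 1]")
  assert_that(volatility_ratio > 0, "volatility_ratio must be positive")
  assert_that(high_risk_fraction >= 0 && high_risk_fraction <= 1,
              "high_risk_fraction must be in [0, 1]")
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must be in [0, 1)")
  assert_that(hazard_strength >= 0, "hazard_strength must be non-negative")
  n_signal_nodes <- min(as.integer(n_signal_nodes), as.integer(n_nodes))
  if (event_rate == 0 && censor_rate == 1)
    stopf("infeasible calibration: event_rate = 0 with censor_rate = 1 leaves no observable event process")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_timepoints = as.integer(n_timepoints),
    n_nodes = as.integer(n_nodes),
    features_per_node = as.integer(features_per_node),
    n_pcs = as.integer(n_pcs),
    n_sites = as.integer(n_sites),
    continuous_effect_size = continuous_effect_size,
    ar_coefficient = ar_coefficient,
    event_rate = event_rate,
    censor_rate = censor_rate,
    volatility_ratio = volatility_ratio,
    high_risk_fraction = high_risk_fraction,
    missing_rate = missing_rate,
    hazard_strength = hazard_strength,
    n_signal_nodes = n_signal_nodes,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  %d subjects x %d visits, %d nodes x %d features/node\n",
              x$n_subjects, x$n_timepoints, x$n_nodes, x$features_per_node))
  cat(sprintf("  signal R2 %.2f on %d nodes | AR(1) phi %.2f | event rate %.3f | censoring %.2f\n",
              x$continuous_effect_size, x$n_signal_nodes, x$ar_coefficient,
              x$event_rate, x$censor_rate))
  cat(sprintf("  high-risk fraction %.2f (volatility x%.1f) | MCAR %.2f | seed %d\n",
              x$high_risk_fraction, x$volatility_ratio, x$missing_rate, x$seed))
  invisible(x)
}

default_node_names <- function(n) {
  base <- c("prs", "env", "family", "school", "peer", "health",
            "sleep", "tech", "neurocog", "brainstr", "brainfun")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("dom%02d", seq_len(n - length(base))))
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a long-format subject-by-visit panel from the generative model in
#' [cohort_spec()], together with the planted ground truth. Latent node
#' states start at their stationary distribution and evolve as
#' `z_t = phi * z_{t-1} + s_i * eps_t` where `s_i` is `volatility_ratio` for
#' high-risk subjects and 1 otherwise. The continuous outcome is
#' `y = beta' z(signal nodes) + eta` with AR(1) residual `eta`, the residual
#' scale chosen so the planted signal explains `continuous_effect_size` of
#' the outcome variance. Events arise from the per-period hazard
#' `plogis(b0 + theta' z_t)` for `t >= 1`, with the intercept `b0` calibrated
#' by bisection so the realized fraction of event subjects matches
#' `event_rate`. Censored subjects contribute no rows after their censoring
#' visit; feature cells are additionally blanked at the MCAR rate.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `panel` (a long
#'   data.frame with reserved columns `subject_id`, `t`, `y`, `event`,
#'   `event_time`, covariates prefixed `cov_`, and features named
#'   `<domain>__<feature>`), `truth` (see [planted_truth()]), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_subjects
  Tn <- spec$n_timepoints
  N <- spec$n_nodes
  phi <- spec$ar_coefficient
  nodes <- default_node_names(N)

  subject_id <- sprintf("S%05d", seq_len(n))
  n_risk <- round(spec$high_risk_fraction * n)
  high_risk <- logical(n)
  high_risk[sample.int(n, n_risk)] <- TRUE
  innov_sd <- ifelse(high_risk, spec$volatility_ratio, 1)

  # latent node states, stationary AR(1) start
  z <- array(0, dim = c(n, Tn, N))
  stat_sd <- innov_sd / sqrt(1 - phi^2)
  z[, 1, ] <- matrix(rnorm(n * N), n, N) * stat_sd
  for (t in 2:Tn)
    z[, t, ] <- phi * z[, t - 1, ] + matrix(rnorm(n * N), n, N) * innov_sd

  # observed features: loading * latent + covariate contamination + noise
  p <- N * spec$features_per_node
  loadings <- matrix(runif(p, 0.8, 1.2), nrow = spec$features_per_node)
  feat_node <- rep(seq_len(N), each = spec$features_per_node)
  feature_names <- paste0(nodes[feat_node], "__f",
                          rep(seq_len(spec$features_per_node), times = N))
  feature_noise_sd <- 0.5

  # subject-level covariates
  sex <- rbinom(n, 1L, 0.5)
  age0 <- sample(9:10, n, replace = TRUE)
  pcs <- matrix(rnorm(n * spec$n_pcs), n, spec$n_pcs)
  site <- factor(sprintf("site%02d", sample.int(spec$n_sites, n, replace = TRUE)),
                 levels = sprintf("site%02d", seq_len(spec$n_sites)))
  # small planted covariate leakage into features, removed by residualization
  cov_w <- matrix(runif(3 * p, -0.3, 0.3), nrow = 3)

  # continuous outcome: planted node signal + AR(1) residual
  sig_nodes <- seq_len(spec$n_signal_nodes)
  beta <- if (spec$continuous_effect_size > 0)
    runif(spec$n_signal_nodes, 0.6, 1.0) * sample(c(-1, 1), spec$n_signal_nodes, replace = TRUE)
  else rep(0, spec$n_signal_nodes)
  signal <- matrix(0, n, Tn)
  for (j in seq_along(sig_nodes))
    signal <- signal + beta[j] * z[, , sig_nodes[j]]
  v_sig <- stats::var(as.vector(signal))
  v_noise <- if (spec$continuous_effect_size > 0)
    v_sig * (1 - spec$continuous_effect_size) / spec$continuous_effect_size
  else 1
  eta_innov_sd <- sqrt(v_noise * (1 - phi^2))
  eta <- matrix(0, n, Tn)
  eta[, 1] <- rnorm(n, sd = sqrt(v_noise))
  for (t in 2:Tn) eta[, t] <- phi * eta[, t - 1] + rnorm(n, sd = eta_innov_sd)
  y <- signal + eta
  gen_r2 <- v_sig / stats::var(as.vector(y))

  # censoring: censored subjects stop at a visit strictly before the last
  cens <- logical(n)
  if (spec$censor_rate > 0) cens[sample.int(n, round(spec$censor_rate * n))] <- TRUE
  last_t <- ifelse(cens & Tn > 2,
                   sample(seq_len(Tn - 2), n, replace = TRUE),
                   ifelse(cens, 0L, Tn - 1L))
  last_t <- as.integer(last_t)

  # binary initiation event from a calibrated per-period logistic hazard
  theta <- spec$hazard_strength * runif(spec$n_signal_nodes, 0.5, 1.0) *
    sample(c(-1, 1), spec$n_signal_nodes, replace = TRUE)
  lp <- matrix(0, n, Tn)
  for (j in seq_along(sig_nodes)) lp <- lp + theta[j] * z[, , sig_nodes[j]]
  u <- matrix(runif(n * Tn), n, Tn)

  realize_events <- function(b0) {
    ev_time <- rep(NA_integer_, n)
    for (t in 2:Tn) { # hazard periods t >= 1 (0-based index t-1)
      hit <- is.na(ev_time) & (t - 1L) <= last_t &
        u[, t] < sigmoid(b0 + lp[, t])
      ev_time[hit] <- t - 1L
    }
    ev_time
  }
  if (spec$event_rate == 0) {
    b0 <- -Inf
    ev_time <- rep(NA_integer_, n)
  } else {
    prev_at <- function(b0) mean(!is.na(realize_events(b0)))
    lo <- -30; hi <- 30
    if (prev_at(hi) < spec$event_rate - 1e-9)
      stopf("infeasible calibration: maximum achievable event prevalence %.3f < target %.3f",
            prev_at(hi), spec$event_rate)
    for (it in seq_len(60)) {
      mid <- (lo + hi) / 2
      if (prev_at(mid) < spec$event_rate) lo <- mid else hi <- mid
    }
    b0 <- hi
    ev_time <- realize_events(b0)
    tol <- max(0.005, 2 / n)
    if (abs(mean(!is.na(ev_time)) - spec$event_rate) > tol + 1e-9)
      stopf("infeasible calibration: achieved prevalence %.3f, target %.3f",
            mean(!is.na(ev_time)), spec$event_rate)
  }
  delta <- as.integer(!is.na(ev_time))
  T_i <- ifelse(delta == 1L, ev_time, last_t)

  # assemble the long panel: censored subjects drop out after last_t
  keep_t <- lapply(seq_len(n), function(i) 0:last_t[i])
  idx <- rep(seq_len(n), lengths(keep_t))
  tt <- unlist(keep_t)
  X <- matrix(0, length(idx), p)
  for (j in seq_len(N)) {
    cols <- which(feat_node == j)
    zl <- z[cbind(idx, tt + 1L, j)]
    for (kk in seq_along(cols)) {
      cj <- cols[kk]
      X[, cj] <- loadings[kk, j] * zl +
        cov_w[1, cj] * sex[idx] + cov_w[2, cj] * pcs[idx, 1] +
        cov_w[3, cj] * (age0[idx] + tt - 10) +
        rnorm(length(idx), sd = feature_noise_sd)
    }
  }
  if (spec$missing_rate > 0)
    X[matrix(runif(length(X)) < spec$missing_rate, nrow(X), p)] <- NA_real_

  panel <- data.frame(
    subject_id = subject_id[idx],
    t = as.integer(tt),
    cov_sex = sex[idx],
    cov_age = as.integer(age0[idx] + tt),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(spec$n_pcs)) panel[[sprintf("cov_pc%d", k)]] <- pcs[idx, k]
  panel$cov_site <- as.character(site[idx])
  panel$y <- y[cbind(idx, tt + 1L)]
  panel$event <- delta[idx]
  panel$event_time <- as.integer(T_i[idx])
  colnames(X) <- feature_names
  panel <- cbind(panel, as.data.frame(X))
  rownames(panel) <- NULL

  truth <- structure(list(
    nodes = nodes,
    signal_nodes = nodes[sig_nodes],
    beta = stats::setNames(beta, nodes[sig_nodes]),
    hazard_coefficients = stats::setNames(theta, nodes[sig_nodes]),
    hazard_intercept = b0,
    generative_r2 = gen_r2,
    ar_coefficient = phi,
    loadings = loadings,
    subjects = data.frame(subject_id = subject_id,
                          high_risk = high_risk,
                          censored = cens,
                          last_t = last_t,
                          event = delta,
                          event_time = as.integer(T_i),
                          stringsAsFactors = FALSE)
  ), class = "cohort_truth")

  structure(list(panel = panel, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' Planted ground truth of a synthetic cohort
#'
#' Recomputes (deterministically, from the spec's seed) the generative
#' parameters behind [generate_cohort()]: the signal coefficient vector, the
#' hazard coefficients and calibrated intercept, the realized generative
#' R-squared, and per-subject subgroup / censoring / event labels. Used by
#' parameter-recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `cohort_truth`.
#' @export
planted_truth <- function(spec) generate_cohort(spec)$truth

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d rows, %d nodes, %d features\n",
              x$spec$n_subjects, nrow(x$panel), x$spec$n_nodes,
              x$spec$n_nodes * x$spec$features_per_node))
  cat(sprintf("  event prevalence %.3f | generative R2 %.3f\n",
              mean(x$truth$subjects$event), x$truth$generative_r2))
  invisible(x)
}

#' Panel feature / covariate column helpers
#'
#' Feature columns follow the `<domain>__<feature>` naming convention;
#' covariates are prefixed `cov_`.
#'
#' @param panel A long-format panel data.frame.
#' @return Character vector of column names.
#' @export
feature_columns <- function(panel) grep("__", names(panel), value = TRUE)

#' @rdname feature_columns
#' @export
covariate_columns <- function(panel) grep("^cov_", names(panel), value = TRUE)

#' Read or write a long-format panel as CSV
#'
#' @param panel A panel data.frame.
#' @param path File path.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
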