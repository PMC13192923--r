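test_that("energy is the mean squared entry", {
  expect_equal(energy(c(0, 0, 0)), 0)
  expect_equal(energy(c(3, 4)), 12.5)
  for (N in c(1, 5, 17)) expect_equal(energy(rep(1, N)), 1)
  expect_error(energy(numeric(0)), "empty")
  # scale equivariance
  x <- rnorm(6)
  expect_equal(energy(3 * x), 9 * energy(x))
})

test_that("graph energy reduces and contracts as expected", {
  x <- c(1, -2, 3)
  expect_equal(graph_energy(diag(3), x), energy(x))
  expect_equal(graph_energy(matrix(0, 3, 3), x), 0)
  set.seed(90)
  for (k in 1:200) {
    N <- sample(2:8, 1)
    W <- matrix(runif(N * N), N, N)
    W <- (W + t(W)) / 2
    diag(W) <- 1
    A <- W / rowSums(W)
    x <- rnorm(N, sd = 2)
    expect_lte(graph_energy(A, x), energy(x) + 1e-12)
  }
})

test_that("energy changes are consecutive differences with a telescoping sum", {
  expect_equal(delta_energy(c(1, 1, 1)), c(NA, 0, 0))
  expect_equal(delta_energy(c(1, 4, 2)), c(NA, 3, -2))
  set.seed(91)
  for (k in 1:20) {
    E <- abs(rnorm(6))
    E[sample(6, 2)] <- NA
    dE <- suppressWarnings(delta_energy(E))
    obs <- E[!is.na(E)]
    if (length(obs) >= 2)
      expect_equal(sum(dE, na.rm = TRUE), obs[length(obs)] - obs[1])
  }
  expect_warning(delta_energy(c(2, NA, NA)), "fewer than 2")
})

test_that("collapse detection thresholds at mean plus one sd", {
  expect_message(f0 <- detect_collapse(rep(0.5, 4)), "zero-variance")
  expect_equal(f0, rep(0L, 4))
  ref <- c(-1.5, 0.5, 2.5) # mean 0.5, sd 2
  expect_equal(detect_collapse(c(0, 0, 0, 10), ref), c(0L, 0L, 0L, 1L))
  expect_error(detect_collapse(c(1, 2), reference = 1), ">= 2")
})

test_that("self-referenced Gaussian changes flag the upper normal tail", {
  fr <- vapply(1:5, function(s) {
    dE <- dynograph:::with_seed(900 + s, rnorm(500))
    mean(detect_collapse(dE))
  }, numeric(1))
  expect_true(all(abs(fr - pnorm(1, lower.tail = FALSE)) < 0.04))
})

test_that("raising changes against a fixed reference never unsets flags", {
  set.seed(92)
  dE <- rnorm(50)
  ref <- rnorm(100)
  f1 <- detect_collapse(dE, ref)
  f2 <- detect_collapse(dE + 0.3, ref)
  expect_true(all(f2 >= f1))
})

test_that("energy traces summarize observed slots only", {
  d <- small_model_data(n = 20, seed = 64)
  tr <- compute_energy_traces(d$nb, d$graph, source = "node_summaries")
  expect_s3_class(tr, "energy_trace")
  expect_equal(nrow(tr), sum(d$nb$mask))
  expect_true(all(tr$E >= 0))
  expect_true(all(tr$E_graph >= 0))
  # contraction of the row-normalized graph, per observed row
  expect_true(all(tr$E_graph <= tr$E + 1e-12))
  # dE defined from each subject's second observed time
  first_rows <- !duplicated(tr$subject_id)
  expect_true(all(is.na(tr$dE[first_rows])))
  expect_true(all(tr$collapse %in% c(0L, 1L)))
})

test_that("hidden-state traces come from the trained recurrent state", {
  d <- small_model_data(n = 20, seed = 65)
  cfg <- model_config("graph_gtrnn", input_width = length(d$graph$nodes),
                      head = "continuous", hidden = 4, max_epochs = 2,
                      patience = 2, seed = 1)
  fit <- train_model(cfg, subset_batch(d$nb, d$split$train),
                     subset_batch(d$nb, d$split$val), d$graph)
  tr <- compute_energy_traces(d$nb, d$graph, fit, source = "hidden_state")
  H <- hidden_states(fit, d$nb, d$graph)
  i <- match(tr$subject_id[1], d$nb$subjects)
  expect_equal(tr$E[1], mean(H[i, tr$t[1] + 1, ]^2))
  expect_error(compute_energy_traces(d$nb, d$graph, NULL, "hidden_state"),
               "requires a trained model")
})

test_that("group contrasts are exact for identical and shifted groups", {
  tr <- data.frame(subject_id = rep(c("a", "b", "c", "d"), each = 3),
                   t = rep(0:2, 4),
                   E = rep(c(1, 2, 3), 4), E_graph = NA_real_,
                   dE = rep(c(NA, 1, 1), 4), collapse = 0L)
  class(tr) <- c("energy_trace", "data.frame")
  same <- group_contrast(tr, stats::setNames(c("g1", "g1", "g2", "g2"),
                                             c("a", "b", "c", "d")),
                         high = "g1")
  expect_equal(unname(same$difference), c(0, 0, 0))
  tr2 <- tr
  shift <- tr2$subject_id %in% c("c", "d")
  tr2$E[shift] <- tr2$E[shift] + 5
  tr2$dE[shift & !is.na(tr2$dE)] <- tr2$dE[shift & !is.na(tr2$dE)]
  up <- group_contrast(tr2, stats::setNames(c("lo", "lo", "hi", "hi"),
                                            c("a", "b", "c", "d")),
                       high = "hi")
  expect_equal(up$difference[["mean_energy"]], 5)
  expect_equal(up$difference[["final_energy"]], 5)
  expect_equal(up$difference[["mean_delta"]], 0)
  expect_error(group_contrast(tr, stats::setNames(rep("g", 4),
                                                  c("a", "b", "c", "d"))),
               "two non-empty groups")
})

test_that("high-symptom grouping takes the top quantile of the last outcome", {
  set.seed(93)
  p <- data.frame(subject_id = rep(sprintf("S%03d", 1:100), each = 2),
                  t = rep(0:1, 100), y = rnorm(200))
  g <- high_symptom_groups(p)
  expect_equal(sort(unique(g)), c("comparison", "high"))
  expect_equal(unname(sum(g == "high")), 25, tolerance = 2)
  # event groups
  p$event <- rep(rbinom(100, 1, 0.2), each = 2)
  eg <- event_groups(p)
  expect_equal(unname(eg[p$subject_id[p$event == 1][1]]), "event")
})

test_that("energy traces export to tidy CSV", {
  d <- small_model_data(n = 12, seed = 66)
  tr <- compute_energy_traces(d$nb, d$graph, source = "node_summaries")
  f <- withr::local_tempfile(fileext = ".csv")
  write_energy_csv(tr, f)
  back <- utils::read.csv(f)
  expect_equal(names(back), c("subject_id", "t", "E", "E_graph", "dE",
                              "collapse"))
  expect_equal(nrow(back), nrow(tr))
})
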