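# BPTT gradients are checked against central finite differences — the
# independent oracle for the recurrent cores.
test_that("backpropagated gradients match numerical differentiation", {
  set.seed(70)
  n <- 4; Tn <- 3; p <- 3; h <- 4
  for (arch in c("lstm", "gru")) {
    for (head in c("continuous", "binary")) {
      Xs <- lapply(1:Tn, function(t) matrix(rnorm(n * p), n, p))
      mask <- matrix(rbinom(n * Tn, 1, 0.7), n, Tn); mask[, 1] <- 1
      target <- matrix(if (head == "binary") rbinom(n * Tn, 1, 0.5)
                       else rnorm(n * Tn), n, Tn)
      valid <- mask == 1
      params <- dynograph:::init_params(arch, p, h)
      g <- dynograph:::rnn_grad(params, arch, Xs, mask, target, valid, head)
      f <- function(pp) dynograph:::masked_loss(
        dynograph:::head_forward(
          pp, dynograph:::rnn_forward_core(pp, arch, Xs, mask)$Hs),
        target, valid, head)
      for (nm in names(params)) {
        idx <- seq_len(min(length(params[[nm]]), 6))
        for (k in idx) {
          e <- 1e-5
          p1 <- params; p1[[nm]][k] <- p1[[nm]][k] + e
          p2 <- params; p2[[nm]][k] <- p2[[nm]][k] - e
          num <- (f(p1) - f(p2)) / (2 * e)
          expect_lt(abs(g$grads[[nm]][k] - num), 1e-6 * max(1, abs(num)))
        }
      }
    }
  }
})

test_that("forward passes respect the head contracts", {
  d <- small_model_data(n = 30, seed = 54)
  p <- length(d$fc)
  m <- manual_model("graph_lstm", p, 6, head = "binary")
  pr <- forward_graph_lstm(m, d$batch)
  expect_true(all(is.finite(pr)))
  expect_true(all(pr > 0 & pr < 1))
  # zero-weight head: continuous predictions all equal the bias
  mc <- manual_model("graph_lstm", p, 6, head = "continuous")
  mc$params$Wy[] <- 0; mc$params$by <- 0.7
  expect_true(all(forward_graph_lstm(mc, d$batch) == 0.7))
})

test_that("predictions are equivariant to subject order", {
  d <- small_model_data(n = 20, seed = 55)
  m <- manual_model("graph_lstm", length(d$fc), 5)
  pr <- forward_graph_lstm(m, d$batch)
  perm <- rev(d$batch$subjects)
  pr2 <- forward_graph_lstm(m, subset_batch(d$batch, perm))
  expect_equal(pr2, pr[perm, ], tolerance = 1e-12)
})

test_that("graph-temporal GRU with identity adjacency reduces to a plain GRU", {
  d <- small_model_data(n = 15, seed = 56)
  N <- length(d$graph$nodes)
  m <- manual_model("graph_gtrnn", N, 8)
  idg <- build_adjacency(matrix(rnorm(10 * N), 10, N), method = "identity")
  expect_identical(forward_graph_gtrnn(m, idg, d$nb), forward_gru(m, d$nb))
})

test_that("zero adjacency collapses predictions across subjects", {
  d <- small_model_data(n = 12, seed = 57)
  N <- length(d$graph$nodes)
  m <- manual_model("graph_gtrnn", N, 6)
  zg <- list(A = matrix(0, N, N), nodes = d$graph$nodes)
  class(zg) <- "graph_spec"
  full <- subset_batch(d$nb, d$nb$subjects[rowSums(d$nb$mask) == 5])
  pr <- forward_graph_gtrnn(m, zg, full)
  expect_true(all(abs(sweep(pr, 2, pr[1, ])) < 1e-12))
})

test_that("width mismatches raise errors", {
  d <- small_model_data(n = 10, seed = 58)
  m <- manual_model("graph_lstm", 3, 4)
  expect_error(forward_graph_lstm(m, d$batch), "width")
  mg <- manual_model("graph_gtrnn", 11, 4)
  badg <- list(A = diag(4), nodes = letters[1:4])
  class(badg) <- "graph_spec"
  expect_error(forward_graph_gtrnn(mg, badg, d$nb), "nodes")
})

test_that("training fits a constant target", {
  set.seed(71)
  n <- 30
  p <- data.frame(subject_id = rep(sprintf("S%02d", 1:n), each = 3),
                  t = rep(0:2, n), y = 4,
                  env__a = rnorm(3 * n), env__b = rnorm(3 * n))
  p <- build_continuous_targets(p)
  b <- build_sequences(p)
  ids <- unique(p$subject_id)
  cfg <- model_config("graph_lstm", input_width = 2, head = "continuous",
                      hidden = 4, max_epochs = 60, seed = 1)
  fit <- train_model(cfg, subset_batch(b, ids[1:20]),
                     subset_batch(b, ids[21:30]))
  pr <- forward_graph_lstm(fit, b)
  expect_true(all(abs(pr - 4) < 0.05 * 4 + 0.05))
})

test_that("training overfits a strongly separable small cohort", {
  d <- small_model_data(n = 50, seed = 59)
  ids <- d$split
  b <- d$batch
  cfg <- model_config("graph_lstm", input_width = length(d$fc),
                      head = "continuous", hidden = 16, max_epochs = 200,
                      patience = 200, seed = 2)
  fit <- train_model(cfg, subset_batch(b, ids$train), subset_batch(b, ids$val))
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], 0.2 * h$train_loss[1])
})

test_that("training is deterministic under a fixed seed", {
  d <- small_model_data(n = 24, seed = 60)
  cfg <- model_config("graph_lstm", input_width = length(d$fc),
                      head = "continuous", hidden = 4, max_epochs = 5,
                      patience = 5, seed = 9)
  f1 <- train_model(cfg, subset_batch(d$batch, d$split$train),
                    subset_batch(d$batch, d$split$val))
  f2 <- train_model(cfg, subset_batch(d$batch, d$split$train),
                    subset_batch(d$batch, d$split$val))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("degenerate training inputs are rejected", {
  d <- small_model_data(n = 20, seed = 61)
  cfg <- model_config("graph_lstm", input_width = length(d$fc),
                      head = "continuous", hidden = 4, max_epochs = 2, seed = 1)
  expect_error(train_model(cfg, subset_batch(d$batch, d$split$train),
                           subset_batch(d$batch, d$split$train)),
               "share subjects")
  nb <- subset_batch(d$batch, d$split$val)
  nb$target_valid[] <- FALSE
  expect_error(train_model(cfg, subset_batch(d$batch, d$split$train), nb),
               "no valid")
})

test_that("masked positions cannot influence losses or predictions", {
  d <- small_model_data(n = 25, seed = 62)
  b <- d$batch
  m <- manual_model("graph_lstm", length(d$fc), 6)
  tg <- dynograph:::batch_target(b, "continuous")
  pr <- forward_graph_lstm(m, b)
  loss <- dynograph:::masked_loss(pr, tg$target, tg$valid, "continuous")
  # perturb every padded cell wildly
  b2 <- b
  for (j in seq_len(dim(b2$X)[3])) {
    slab <- b2$X[, , j]
    slab[b2$mask == 0L] <- 1e6
    b2$X[, , j] <- slab
  }
  pr2 <- forward_graph_lstm(m, b2)
  expect_equal(pr2[tg$valid], pr[tg$valid], tolerance = 1e-12)
  expect_equal(dynograph:::masked_loss(pr2, tg$target, tg$valid, "continuous"),
               loss, tolerance = 1e-12)
  m1 <- regression_metrics(b$target, pr, tg$valid)
  m2 <- regression_metrics(b2$target, pr2, tg$valid)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("positive-label weighting shifts the binary loss as specified", {
  z <- matrix(c(0.3, -0.2, 1.1, -0.9), 2, 2)
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  v <- matrix(TRUE, 2, 2)
  base <- dynograph:::masked_loss(z, y, v, "binary", pos_weight = 1)
  wt <- dynograph:::masked_loss(z, y, v, "binary", pos_weight = 3)
  # oracle: weighted mean of elementwise BCE
  bce <- -(y * log(plogis(z)) + (1 - y) * log(1 - plogis(z)))
  w <- ifelse(y == 1, 3, 1)
  expect_equal(base, mean(bce), tolerance = 1e-12)
  expect_equal(wt, sum(w * bce) / sum(w), tolerance = 1e-12)
})

test_that("multi-seed runs aggregate per-seed metrics", {
  d <- small_model_data(n = 30, seed = 63)
  cfg <- model_config("graph_lstm", input_width = length(d$fc),
                      head = "continuous", hidden = 4, max_epochs = 3,
                      patience = 3)
  one <- multi_seed_run(cfg, subset_batch(d$batch, d$split$train),
                        subset_batch(d$batch, d$split$val),
                        subset_batch(d$batch, d$split$test), seeds = 1)
  expect_equal(one$summary$sd, rep(0, nrow(one$summary)))
  two <- multi_seed_run(cfg, subset_batch(d$batch, d$split$train),
                        subset_batch(d$batch, d$split$val),
                        subset_batch(d$batch, d$split$test), seeds = c(1, 2))
  expect_equal(two$summary$mean[two$summary$metric == "r2"],
               mean(two$per_seed$r2))
})
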