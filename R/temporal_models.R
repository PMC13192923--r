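#' Configure a temporal model
#'
#' @param architecture `"graph_lstm"` (LSTM over feature sequences) or
#'   `"graph_gtrnn"` (GRU over message-passed node summaries).
#' @param input_width Number of input columns per time step (features for
#'   the LSTM, nodes for the graph-temporal GRU).
#' @param head `"continuous"` (linear output, masked MSE) or `"binary"`
#'   (logistic output, masked cross-entropy).
#' @param hidden Hidden-state width (default 32).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size in subjects (default 64).
#' @param max_epochs Maximum training epochs (default 200).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 10).
#' @param standardize_target Standardize a continuous target on training
#'   positions before fitting; predictions are returned on the original
#'   scale (default `TRUE`).
#' @param pos_weight Weight on positive labels in the binary loss (default 1,
#'   no re-weighting).
#' @param seed Seed for weight initialization and minibatch shuffling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(architecture = c("graph_lstm", "graph_gtrnn"),
                         input_width,
                         head = c("continuous", "binary"),
                         hidden = 32L, learning_rate = 1e-3,
                         batch_size = 64L, max_epochs = 200L,
                         patience = 10L, standardize_target = TRUE,
                         pos_weight = 1, seed = 1L) {
  architecture <- match.arg(architecture)
  head <- match.arg(head)
  assert_that(is_count(hidden), "hidden width must be >= 1")
  assert_that(is_count(patience), "patience must be >= 1")
  assert_that(is_count(input_width), "input_width must be >= 1")
  structure(list(architecture = architecture, input_width = as.integer(input_width),
                 head = head, hidden = as.integer(hidden),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 standardize_target = isTRUE(standardize_target),
                 pos_weight = pos_weight,
                 seed = as.integer(seed)),
            class = "model_config")
}

core_arch <- function(architecture)
  if (architecture == "graph_lstm") "lstm" else "gru"

# slice a batch's feature array into a list of n x p matrices, one per slot,
# optionally message-passing each slot through the adjacency matrix
batch_inputs <- function(batch, graph = NULL) {
  d <- dim(batch$X)
  Xs <- lapply(seq_len(d[2]), function(t) {
    M <- batch$X[, t, , drop = FALSE]
    dim(M) <- c(d[1], d[3])
    M
  })
  if (!is.null(graph)) {
    A <- if (inherits(graph, "graph_spec")) graph$A else graph
    if (ncol(A) != d[3])
      stopf("graph has %d nodes but batch has %d input columns", ncol(A), d[3])
    Xs <- lapply(Xs, function(M) M %*% t(A))
  }
  Xs
}

# target/validity pair for the configured head
batch_target <- function(batch, head) {
  if (head == "continuous") {
    if (is.null(batch$target)) stopf("batch carries no continuous target")
    list(target = ifelse(is.na(batch$target), 0, batch$target),
         valid = batch$target_valid & batch$mask == 1L)
  } else {
    if (is.null(batch$event_label)) stopf("batch carries no event labels")
    list(target = ifelse(is.na(batch$event_label), 0, batch$event_label),
         valid = batch$event_valid & batch$mask == 1L)
  }
}

#' Reduce a feature-level sequence batch to node summaries
#'
#' Replaces the feature axis by the node axis, each node the mean of its
#' assigned features at that slot ([node_summaries()] applied per time step).
#'
#' @param batch A `sequence_batch` over features.
#' @param map Feature-to-node map from [assign_nodes()].
#' @param nodes Node order (default: unique map values).
#' @return A `sequence_batch` whose `X` is `n x T x N`.
#' @export
node_batch <- function(batch, map, nodes = unique(unname(map))) {
  d <- dim(batch$X)
  out <- batch
  Xn <- array(0, dim = c(d[1], d[2], length(nodes)),
              dimnames = list(batch$subjects, NULL, nodes))
  for (t in seq_len(d[2])) {
    M <- batch$X[, t, , drop = FALSE]
    dim(M) <- c(d[1], d[3])
    colnames(M) <- batch$feature_names
    Xn[, t, ] <- node_summaries(M, map, nodes)
  }
  out$X <- Xn
  out$feature_names <- nodes
  out
}

#' Forward pass of the sequence LSTM
#'
#' Runs the masked LSTM over the batch's feature sequences and applies the
#' prediction head at every slot: a linear read-out for continuous outcomes,
#' a logistic read-out (probability in (0, 1)) for binary outcomes. At masked
#' slots the recurrent state is carried over unchanged, so padded feature
#' values never reach an observed slot's prediction; predictions emitted at
#' masked slots are excluded from losses and metrics downstream.
#'
#' @param model A `trained_model` (or a list with `params`, `config`).
#' @param batch A `sequence_batch` of features.
#' @return Matrix n x T of per-slot predictions (original target scale, or
#'   event probabilities).
#' @export
forward_graph_lstm <- function(model, batch) {
  stopifnot(model$config$architecture == "graph_lstm")
  forward_model(model, batch, graph = NULL)
}

#' Forward pass of the graph-temporal GRU
#'
#' At each time step the node-summary vector is message-passed through the
#' adjacency matrix (`x_graph = A x`) and fed to a masked GRU; the prediction
#' head is as in [forward_graph_lstm()]. With an identity adjacency this is
#' exactly a plain GRU on the raw node summaries (see [forward_gru()]).
#'
#' @param model A `trained_model`.
#' @param graph A `graph_spec` (or adjacency matrix).
#' @param batch A `sequence_batch` of node summaries.
#' @return Matrix n x T of per-slot predictions.
#' @export
forward_graph_gtrnn <- function(model, graph, batch) {
  stopifnot(model$config$architecture == "graph_gtrnn")
  forward_model(model, batch, graph = graph)
}

#' @rdname forward_graph_gtrnn
#' @export
forward_gru <- function(model, batch) forward_model(model, batch, graph = NULL)

forward_model <- function(model, batch, graph = NULL) {
  cfg <- model$config
  d <- dim(batch$X)
  width_in <- if (is.null(graph)) d[3] else d[3]
  if (nrow(model$params$Wx) != width_in)
    stopf("batch width %d does not match model input width %d",
          width_in, nrow(model$params$Wx))
  Xs <- batch_inputs(batch, graph)
  fw <- rnn_forward_core(model$params, core_arch(cfg$architecture), Xs,
                         batch$mask, keep_cache = FALSE)
  z <- head_forward(model$params, fw$Hs)
  if (cfg$head == "binary") z <- sigmoid(z)
  else if (!is.null(model$target_scale))
    z <- z * model$target_scale$sd + model$target_scale$mean
  dimnames(z) <- list(batch$subjects, NULL)
  z
}

#' Hidden-state trajectories of a trained model
#'
#' @param model A `trained_model`.
#' @param batch A `sequence_batch` matching the model's inputs.
#' @param graph Graph spec for `graph_gtrnn` models.
#' @return Array n x T x hidden of hidden states.
#' @export
hidden_states <- function(model, batch, graph = NULL) {
  Xs <- batch_inputs(batch, graph)
  fw <- rnn_forward_core(model$params, core_arch(model$config$architecture),
                         Xs, batch$mask, keep_cache = FALSE)
  d <- c(dim(fw$Hs[[1]])[1], length(fw$Hs), ncol(fw$Hs[[1]]))
  out <- array(0, dim = d, dimnames = list(batch$subjects, NULL, NULL))
  for (t in seq_along(fw$Hs)) out[, t, ] <- fw$Hs[[t]]
  out
}

#' Train a temporal model with Adam and early stopping
#'
#' Minimizes the masked loss (MSE for continuous heads, cross-entropy for
#' binary heads) over observed, labelled subject-periods using Adam on
#' shuffled minibatches. After each epoch the validation loss is computed;
#' training stops once it has failed to improve for `patience` consecutive
#' epochs, and the best-epoch weights are restored. Fully deterministic
#' given the config seed.
#'
#' @param config A [model_config()].
#' @param train_batch,val_batch `sequence_batch`es of disjoint subjects.
#' @param graph Graph spec, required for `graph_gtrnn`.
#' @return An object of class `trained_model`: `config`, `params`,
#'   `history` (per-epoch train/val loss), `best_epoch`, `target_scale`.
#' @export
train_model <- function(config, train_batch, val_batch, graph = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (config$architecture == "graph_gtrnn" && is.null(graph))
    stopf("graph_gtrnn requires a graph")
  if (length(intersect(train_batch$subjects, val_batch$subjects)))
    stopf("train and validation batches share subjects")
  Xs_tr <- batch_inputs(train_batch, graph)
  Xs_va <- batch_inputs(val_batch, graph)
  if (ncol(Xs_tr[[1]]) != config$input_width)
    stopf("batch width %d does not match config input_width %d",
          ncol(Xs_tr[[1]]), config$input_width)
  tg_tr <- batch_target(train_batch, config$head)
  tg_va <- batch_target(val_batch, config$head)
  if (sum(tg_tr$valid) == 0 || sum(tg_va$valid) == 0)
    stopf("no valid (observed, labelled) positions for the loss")

  scale <- NULL
  if (config$head == "continuous" && config$standardize_target) {
    v <- tg_tr$target[tg_tr$valid]
    scale <- list(mean = mean(v), sd = max(stats::sd(v), 1e-12))
    tg_tr$target <- (tg_tr$target - scale$mean) / scale$sd
    tg_va$target <- (tg_va$target - scale$mean) / scale$sd
  }

  arch <- core_arch(config$architecture)
  n <- length(train_batch$subjects)
  with_seed(config$seed, {
    params <- init_params(arch, config$input_width, config$hidden)
    opt <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    stall <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0; ep_w <- 0
      for (s in starts) {
        ix <- ord[s:min(s + config$batch_size - 1L, n)]
        g <- rnn_grad(params, arch,
                      lapply(Xs_tr, function(M) M[ix, , drop = FALSE]),
                      train_batch$mask[ix, , drop = FALSE],
                      tg_tr$target[ix, , drop = FALSE],
                      tg_tr$valid[ix, , drop = FALSE], config$head,
                      config$pos_weight %||% 1)
        st <- adam_step(params, g$grads, opt, config$learning_rate)
        params <- st$params; opt <- st$state
        ep_loss <- ep_loss + g$loss * length(ix); ep_w <- ep_w + length(ix)
      }
      zv <- head_forward(params,
                         rnn_forward_core(params, arch, Xs_va,
                                          val_batch$mask)$Hs)
      vloss <- masked_loss(zv, tg_va$target, tg_va$valid, config$head,
                           config$pos_weight %||% 1)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = ep_loss / ep_w,
                                     val_loss = vloss))
      if (vloss < best$loss - 1e-12) {
        best <- list(loss = vloss, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    structure(list(config = config, params = best$params, history = hist,
                   best_epoch = best$epoch, val_loss = best$loss,
                   target_scale = scale),
              class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("Trained %s (%s head): hidden %d, best epoch %d/%d, val loss %.4g\n",
              x$config$architecture, x$config$head, x$config$hidden,
              x$best_epoch, nrow(x$history), x$val_loss))
  invisible(x)
}

#' Train and evaluate a model across several seeds
#'
#' Repeats [train_model()] with per-seed weight initialization and minibatch
#' order, evaluates each fit on the test batch, and reports per-seed metrics
#' plus their mean and standard deviation (SD 0 for a single seed).
#'
#' @param config A [model_config()] (its `seed` field is overridden).
#' @param train_batch,val_batch,test_batch Disjoint `sequence_batch`es.
#' @param graph Graph spec for `graph_gtrnn`.
#' @param seeds Integer vector of seeds.
#' @return List with `per_seed` (data.frame of metrics by seed), `summary`
#'   (mean and SD per metric), and `models`.
#' @export
multi_seed_run <- function(config, train_batch, val_batch, test_batch,
                           graph = NULL, seeds = 1:5) {
  assert_that(length(seeds) >= 1, "need at least one seed")
  rows <- list(); models <- list()
  for (s in seeds) {
    cfg <- config
    cfg$seed <- as.integer(s)
    fit <- train_model(cfg, train_batch, val_batch, graph)
    pred <- forward_model(fit, test_batch, graph =
                            if (config$architecture == "graph_gtrnn") graph)
    tg <- batch_target(test_batch, config$head)
    met <- if (config$head == "continuous")
      regression_metrics(test_batch$target, pred, tg$valid)
    else
      classification_metrics(test_batch$event_label, pred, tg$valid)
    rows[[as.character(s)]] <- data.frame(seed = s, t(unlist(met)))
    models[[as.character(s)]] <- fit
  }
  per_seed <- do.call(rbind, rows)
  rownames(per_seed) <- NULL
  mcols <- setdiff(names(per_seed), "seed")
  summary <- data.frame(
    metric = mcols,
    mean = vapply(mcols, function(m) mean(per_seed[[m]]), numeric(1)),
    sd = vapply(mcols, function(m)
      if (nrow(per_seed) > 1) stats::sd(per_seed[[m]]) else 0, numeric(1)))
  rownames(summary) <- NULL
  list(per_seed = per_seed, summary = summary, models = models)
}
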