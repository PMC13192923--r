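# Recurrent cores: masked LSTM / GRU forward passes, backpropagation through
# time, and Adam. Written against the usual gate equations; sequences are
# lists of n x p matrices (one per time slot) with an n x T observation mask.
# At a masked slot the hidden (and cell) state is carried over unchanged, so
# padded feature values can never influence any prediction at an observed slot.

init_params <- function(arch, p, h) {
  k <- 1 / sqrt(h)
  ng <- if (arch == "lstm") 4L else 3L
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  list(Wx = u(p, ng * h), Wh = u(h, ng * h), b = stats::runif(ng * h, -k, k),
       Wy = u(h, 1L), by = stats::runif(1L, -k, k))
}

# forward pass; returns hidden states and (optionally) caches for backprop
rnn_forward_core <- function(params, arch, Xs, mask, keep_cache = FALSE) {
  Tn <- length(Xs)
  n <- nrow(Xs[[1]])
  h <- nrow(params$Wy)
  H <- matrix(0, n, h)
  C <- matrix(0, n, h)
  Hs <- vector("list", Tn)
  cache <- if (keep_cache) vector("list", Tn)
  for (t in seq_len(Tn)) {
    mu <- mask[, t]
    Hprev <- H; Cprev <- C
    if (arch == "lstm") {
      A <- Xs[[t]] %*% params$Wx + Hprev %*% params$Wh +
        rep_row(params$b, n)
      ig <- sigmoid(A[, 1:h, drop = FALSE])
      fg <- sigmoid(A[, h + 1:h, drop = FALSE])
      gg <- tanh(A[, 2 * h + 1:h, drop = FALSE])
      og <- sigmoid(A[, 3 * h + 1:h, drop = FALSE])
      Ct <- fg * Cprev + ig * gg
      tC <- tanh(Ct)
      Ht <- og * tC
      C <- mu * Ct + (1 - mu) * Cprev
      H <- mu * Ht + (1 - mu) * Hprev
      if (keep_cache)
        cache[[t]] <- list(ig = ig, fg = fg, gg = gg, og = og, Ct = Ct,
                           tC = tC, Hprev = Hprev, Cprev = Cprev, mu = mu)
    } else {
      Ax <- Xs[[t]] %*% params$Wx + rep_row(params$b, n)
      Ah <- Hprev %*% params$Wh
      rg <- sigmoid(Ax[, 1:h, drop = FALSE] + Ah[, 1:h, drop = FALSE])
      zg <- sigmoid(Ax[, h + 1:h, drop = FALSE] + Ah[, h + 1:h, drop = FALSE])
      An3 <- Ah[, 2 * h + 1:h, drop = FALSE]
      ng <- tanh(Ax[, 2 * h + 1:h, drop = FALSE] + rg * An3)
      Ht <- (1 - zg) * ng + zg * Hprev
      H <- mu * Ht + (1 - mu) * Hprev
      if (keep_cache)
        cache[[t]] <- list(rg = rg, zg = zg, ng = ng, An3 = An3,
                           Hprev = Hprev, mu = mu)
    }
    Hs[[t]] <- H
  }
  list(Hs = Hs, cache = cache)
}

rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# linear head on each hidden state; z (logits / raw predictions), n x T
head_forward <- function(params, Hs) {
  do.call(cbind, lapply(Hs, function(H) H %*% params$Wy + params$by[1]))
}

# masked losses on the head output z. For continuous, z is the prediction;
# for binary, z is the logit and the loss is numerically stable BCE.
masked_loss <- function(z, target, valid, head, pos_weight = 1) {
  V <- sum(valid)
  if (V == 0) stopf("no valid (observed, labelled) positions for the loss")
  if (head == "continuous") {
    r <- (z - target)[valid]
    sum(r * r) / V
  } else {
    zt <- z[valid]; yt <- target[valid]
    w <- ifelse(yt == 1, pos_weight, 1)
    sum(w * (pmax(zt, 0) - zt * yt + log1p(exp(-abs(zt))))) / sum(w)
  }
}

# gradient of the masked loss w.r.t. z
masked_loss_grad <- function(z, target, valid, head, pos_weight = 1) {
  V <- sum(valid)
  g <- matrix(0, nrow(z), ncol(z))
  if (head == "continuous") {
    g[valid] <- 2 * (z[valid] - target[valid]) / V
  } else {
    w <- ifelse(target[valid] == 1, pos_weight, 1)
    g[valid] <- w * (sigmoid(z[valid]) - target[valid]) / sum(w)
  }
  g
}

# full forward + BPTT; returns loss and gradients for every parameter
rnn_grad <- function(params, arch, Xs, mask, target, valid, head,
                     pos_weight = 1) {
  fw <- rnn_forward_core(params, arch, Xs, mask, keep_cache = TRUE)
  z <- head_forward(params, fw$Hs)
  loss <- masked_loss(z, target, valid, head, pos_weight)
  dz <- masked_loss_grad(z, target, valid, head, pos_weight)

  Tn <- length(Xs)
  n <- nrow(Xs[[1]])
  h <- nrow(params$Wy)
  gWx <- params$Wx * 0; gWh <- params$Wh * 0; gb <- params$b * 0
  gWy <- params$Wy * 0; gby <- 0
  dH <- matrix(0, n, h)
  dC <- matrix(0, n, h)
  for (t in rev(seq_len(Tn))) {
    ca <- fw$cache[[t]]
    mu <- ca$mu
    dzt <- dz[, t, drop = FALSE]
    gWy <- gWy + t(fw$Hs[[t]]) %*% dzt
    gby <- gby + sum(dzt)
    dH <- dH + dzt %*% t(params$Wy)
    if (arch == "lstm") {
      dHt <- mu * dH
      dHprev_skip <- (1 - mu) * dH
      dCt <- mu * dC
      dCprev_skip <- (1 - mu) * dC
      dog <- dHt * ca$tC
      dCt <- dCt + dHt * ca$og * (1 - ca$tC^2)
      dfg <- dCt * ca$Cprev
      dig <- dCt * ca$gg
      dgg <- dCt * ca$ig
      dCprev <- dCt * ca$fg + dCprev_skip
      dA <- cbind(dig * ca$ig * (1 - ca$ig),
                  dfg * ca$fg * (1 - ca$fg),
                  dgg * (1 - ca$gg^2),
                  dog * ca$og * (1 - ca$og))
      gWx <- gWx + t(Xs[[t]]) %*% dA
      gWh <- gWh + t(ca$Hprev) %*% dA
      gb <- gb + colSums(dA)
      dH <- dA %*% t(params$Wh) + dHprev_skip
      dC <- dCprev
    } else {
      dHt <- mu * dH
      dHprev <- (1 - mu) * dH
      dng <- dHt * (1 - ca$zg)
      dzg <- dHt * (ca$Hprev - ca$ng)
      dHprev <- dHprev + dHt * ca$zg
      da_n <- dng * (1 - ca$ng^2)
      drg <- da_n * ca$An3
      dAn3 <- da_n * ca$rg
      da_z <- dzg * ca$zg * (1 - ca$zg)
      da_r <- drg * ca$rg * (1 - ca$rg)
      dA <- cbind(da_r, da_z, da_n)
      gWx <- gWx + t(Xs[[t]]) %*% dA
      gb <- gb + colSums(dA)
      gWh[, 1:h] <- gWh[, 1:h] + t(ca$Hprev) %*% da_r
      gWh[, h + 1:h] <- gWh[, h + 1:h] + t(ca$Hprev) %*% da_z
      gWh[, 2 * h + 1:h] <- gWh[, 2 * h + 1:h] + t(ca$Hprev) %*% dAn3
      dH <- da_r %*% t(params$Wh[, 1:h, drop = FALSE]) +
        da_z %*% t(params$Wh[, h + 1:h, drop = FALSE]) +
        dAn3 %*% t(params$Wh[, 2 * h + 1:h, drop = FALSE]) +
        dHprev
      dC <- dC # unused for GRU
    }
  }
  list(loss = loss,
       grads = list(Wx = gWx, Wh = gWh, b = gb, Wy = gWy, by = gby))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
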