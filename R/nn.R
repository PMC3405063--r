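# Shallow feed-forward networks (one hidden layer, sigmoid units) used by
# the per-atom-type predictors. Two training schemes are provided:
# plain batch back-propagation with fixed learning rate and momentum, and
# resilient propagation (Rprop-) with per-weight adaptive step sizes; the
# latter is used inside the bagged ensemble where the stopping iteration
# is chosen by validation MCC.

.sigmoid <- function(z) 1 / (1 + exp(-z))

.nn_init <- function(n_in, n_hidden, rng) {
  list(W1 = matrix(rng(n_hidden * (n_in + 1), 0.5), n_in + 1, n_hidden),
       W2 = matrix(rng(n_hidden + 1, 0.5), n_hidden + 1, 1))
}

.nn_forward <- function(net, X) {
  H <- .sigmoid(cbind(1, X) %*% net$W1)
  as.vector(.sigmoid(cbind(1, H) %*% net$W2))
}

# Gradients of the squared error summed over the batch (the aggregate of
# per-pattern updates, so the stated per-pattern learning rate applies).
.nn_grad <- function(net, X, y) {
  X1 <- cbind(1, X)
  H <- .sigmoid(X1 %*% net$W1)
  H1 <- cbind(1, H)
  out <- as.vector(.sigmoid(H1 %*% net$W2))
  d_out <- (out - y) * out * (1 - out)            # n
  g2 <- crossprod(H1, d_out)                      # (h+1) x 1
  d_hid <- (d_out %*% t(net$W2[-1, , drop = FALSE])) * H * (1 - H)
  g1 <- crossprod(X1, d_hid)                      # (p+1) x h
  list(g1 = g1, g2 = matrix(g2, ncol = 1), out = out)
}

# Plain back-propagation: fixed learning rate + momentum, stopping when
# the training mean absolute error stops moving (|delta MAE| < tol over
# `patience` iterations) or at max_iter.
.train_backprop <- function(X, y, hidden = 76L, lr = 0.01, momentum = 0.1,
                            max_iter = 1000L, tol = 1e-4, patience = 10L,
                            seed = 1L) {
  set.seed(seed)
  rng <- function(n, a) stats::runif(n, -a, a)
  net <- .nn_init(ncol(X), hidden, rng)
  v1 <- net$W1 * 0; v2 <- net$W2 * 0
  mae_hist <- rep(NA_real_, max_iter)
  for (it in seq_len(max_iter)) {
    gr <- .nn_grad(net, X, y)
    v1 <- momentum * v1 - lr * gr$g1
    v2 <- momentum * v2 - lr * gr$g2
    net$W1 <- net$W1 + v1
    net$W2 <- net$W2 + v2
    mae_hist[it] <- mean(abs(gr$out - y))
    # convergence check armed after a burn-in: early iterations can sit on
    # a flat stretch before the error starts moving
    if (it > max(patience, 100L) &&
        abs(mae_hist[it] - mae_hist[it - patience]) < tol) break
  }
  net$iterations <- it
  net
}

# Rprop- training with validation-based iteration selection: weights are
# snapshotted every `validate_every` iterations, the validation MCC (at
# the MCC-optimal threshold) is recorded, and the earliest iteration with
# the best MCC wins. Scanning stops early once a perfect validation MCC
# is seen, since no later iteration can change the selection.
.train_rprop <- function(X, y, Xval, yval, hidden = 76L, max_iter = 1000L,
                         validate_every = 10L, seed = 1L) {
  set.seed(seed)
  rng <- function(n, a) stats::runif(n, -a, a)
  net <- .nn_init(ncol(X), hidden, rng)
  eta_p <- 1.2; eta_m <- 0.5; d_max <- 50; d_min <- 1e-6
  D1 <- net$W1 * 0 + 0.1; D2 <- net$W2 * 0 + 0.1
  P1 <- net$W1 * 0; P2 <- net$W2 * 0
  best <- list(mcc = -Inf, net = net, iter = 0L)
  rprop_step <- function(W, g, g_prev, D) {
    s <- g * g_prev
    D <- ifelse(s > 0, pmin(D * eta_p, d_max),
                ifelse(s < 0, pmax(D * eta_m, d_min), D))
    g_eff <- ifelse(s < 0, 0, g)  # Rprop-: zero gradient after sign flip
    W <- W - sign(g_eff) * D
    list(W = W, D = D, g = g_eff)
  }
  mae_hist <- rep(NA_real_, max_iter)
  for (it in seq_len(max_iter)) {
    gr <- .nn_grad(net, X, y)
    s1 <- rprop_step(net$W1, gr$g1, P1, D1)
    s2 <- rprop_step(net$W2, gr$g2, P2, D2)
    net$W1 <- s1$W; D1 <- s1$D; P1 <- s1$g
    net$W2 <- s2$W; D2 <- s2$D; P2 <- s2$g
    mae_hist[it] <- mean(abs(gr$out - y))
    if (it %% validate_every == 0 || it == max_iter) {
      pv <- .nn_forward(net, Xval)
      mcc <- max(.mcc_scan(pv, yval)$mcc)
      if (mcc > best$mcc) best <- list(mcc = mcc, net = net, iter = it)
      if (best$mcc >= 1) break
    }
    # training-error plateau: later snapshots cannot beat the selection
    if (it > 20L && !is.na(mae_hist[it - 20L]) &&
        abs(mae_hist[it] - mae_hist[it - 20L]) < 1e-4) break
  }
  out <- best$net
  out$iterations <- best$iter
  out$val_mcc <- best$mcc
  out
}

.mcc_at <- function(outputs, labels, threshold) {
  pred <- outputs >= threshold
  tp <- sum(pred & labels); tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels); fn <- sum(!pred & labels)
  den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  if (den > 0) (tp * tn - fp * fn) / den else 0
}

# Vectorised threshold scan: MCC of `output >= t` for every midpoint of
# consecutive sorted unique outputs, via cumulative class counts.
.mcc_scan <- function(outputs, labels) {
  u <- sort(unique(outputs))
  cand <- if (length(u) == 1) u else (u[-length(u)] + u[-1]) / 2
  o <- order(outputs)
  lab <- labels[o]; out_s <- outputs[o]
  P <- sum(lab); N <- length(lab) - P
  cum_pos <- cumsum(lab); cum_neg <- cumsum(!lab)
  # index of the last output strictly below each candidate threshold
  k <- findInterval(cand, out_s)
  cp <- c(0, cum_pos); cn <- c(0, cum_neg)
  tp <- P - cp[k + 1]
  fp <- N - cn[k + 1]
  fn <- P - tp
  tn <- N - fp
  den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- ifelse(den > 0, (tp * tn - fp * fn) / den, 0)
  list(threshold = cand, mcc = mcc)
}
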