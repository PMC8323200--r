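# Independent scalar-loop oracles. These deliberately avoid the package's
# vectorised implementations: everything is written as plain elementwise
# loops transcribed from the defining equations.

sigm_o <- function(x) 1 / (1 + exp(-x))

# one LSTM step, elementwise
lstm_step_oracle <- function(x, h_prev, c_prev, params) {
  u <- length(h_prev)
  f <- g <- o <- i <- c_t <- h_t <- numeric(u)
  for (r in seq_len(u)) {
    zf <- sum(params$W$f[r, ] * x) + sum(params$U$f[r, ] * h_prev) +
      params$b$f[r]
    zg <- sum(params$W$g[r, ] * x) + sum(params$U$g[r, ] * h_prev) +
      params$b$g[r]
    zo <- sum(params$W$o[r, ] * x) + sum(params$U$o[r, ] * h_prev) +
      params$b$o[r]
    zi <- sum(params$W$i[r, ] * x) + sum(params$U$i[r, ] * h_prev) +
      params$b$i[r]
    f[r] <- sigm_o(zf); g[r] <- tanh(zg)
    o[r] <- sigm_o(zo); i[r] <- sigm_o(zi)
    c_t[r] <- f[r] * c_prev[r] + i[r] * g[r]
    h_t[r] <- o[r] * tanh(c_t[r])
  }
  list(h = h_t, c = c_t)
}

# one unidirectional pass via the step oracle
lstm_seq_oracle <- function(X, params) {
  u <- nrow(params$W$f)
  H <- matrix(0, nrow(X), u)
  h <- numeric(u); cc <- numeric(u)
  for (t in seq_len(nrow(X))) {
    st <- lstm_step_oracle(X[t, ], h, cc, params)
    h <- st$h; cc <- st$c
    H[t, ] <- h
  }
  H
}

squash_oracle <- function(s) {
  n <- sqrt(sum(s^2))
  if (n == 0) return(s * 0)
  (n^2 / (1 + n^2)) * (s / n)
}

# fully unrolled routing, scalar arithmetic only; returns per-iteration trace
routing_oracle <- function(u_hat, iterations) {
  cp <- dim(u_hat)[1]; k <- dim(u_hat)[2]; d <- dim(u_hat)[3]
  b <- matrix(0, cp, k)
  hist <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    cmat <- matrix(0, cp, k)
    for (i in seq_len(cp)) {
      mx <- max(b[i, ])
      ex <- exp(b[i, ] - mx)
      cmat[i, ] <- ex / sum(ex)
    }
    v <- matrix(0, k, d)
    for (j in seq_len(k)) {
      s_j <- numeric(d)
      for (i in seq_len(cp))
        for (dd in seq_len(d)) s_j[dd] <- s_j[dd] + cmat[i, j] * u_hat[i, j, dd]
      v[j, ] <- squash_oracle(s_j)
    }
    if (it < iterations) {
      for (i in seq_len(cp))
        for (j in seq_len(k))
          b[i, j] <- b[i, j] + sum(u_hat[i, j, ] * v[j, ])
    }
    hist[[it]] <- list(c = cmat, v = v, b = b)
  }
  hist
}

cosine_oracle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# confusion-count F1 oracles over binary matrices
micro_f1_oracle <- function(gold, pred) {
  tp <- fp <- fn <- 0
  for (i in seq_len(nrow(gold))) for (j in seq_len(ncol(gold))) {
    if (gold[i, j] == 1 && pred[i, j] == 1) tp <- tp + 1
    if (gold[i, j] == 0 && pred[i, j] == 1) fp <- fp + 1
    if (gold[i, j] == 1 && pred[i, j] == 0) fn <- fn + 1
  }
  if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
}

macro_f1_oracle <- function(gold, pred) {
  vals <- numeric(ncol(gold))
  for (j in seq_len(ncol(gold))) {
    tp <- fp <- fn <- 0
    for (i in seq_len(nrow(gold))) {
      if (gold[i, j] == 1 && pred[i, j] == 1) tp <- tp + 1
      if (gold[i, j] == 0 && pred[i, j] == 1) fp <- fp + 1
      if (gold[i, j] == 1 && pred[i, j] == 0) fn <- fn + 1
    }
    vals[j] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  mean(vals)
}

# rank-then-count top-k recall oracle (ties by label order)
top10_recall_oracle <- function(scores, gold, k_base = 10) {
  vals <- c()
  for (i in seq_len(nrow(gold))) {
    m <- sum(gold[i, ] == 1)
    if (m == 0) next
    K <- max(k_base, m)
    ord <- order(-scores[i, ], seq_len(ncol(scores)))
    top <- ord[seq_len(min(K, length(ord)))]
    hits <- sum(which(gold[i, ] == 1) %in% top)
    vals <- c(vals, hits / m)
  }
  mean(vals)
}

# all-pairs comparison AUC oracle (ties count 1/2)
auc_pairs_oracle <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg) {
    if (scores[p] > scores[n]) tot <- tot + 1
    else if (scores[p] == scores[n]) tot <- tot + 0.5
  }
  tot / (length(pos) * length(neg))
}

# sliding-window convolution oracle
conv_oracle <- function(X, filters, b0) {
  K1 <- nrow(filters[[1]])
  np <- nrow(X) - K1 + 1
  M <- matrix(0, np, length(filters))
  for (p in seq_len(np)) for (a in seq_along(filters)) {
    acc <- 0
    for (r in seq_len(K1)) for (cidx in seq_len(ncol(X)))
      acc <- acc + X[p + r - 1, cidx] * filters[[a]][r, cidx]
    M[p, a] <- max(0, acc + b0[a])
  }
  M
}
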