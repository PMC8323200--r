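#' N-gram convolution over a sequence
#'
#' Slides each K1 x e filter over the valid windows of `X` (no padding) and
#' applies a nonlinearity: `m_p^a = f(sum(X[p:(p+K1-1), ] * W_a) + b0_a)`.
#'
#' @param X T x e input sequence
#' @param filters list of K1 x e filter matrices
#' @param b0 bias vector, one per filter
#' @param activation `"relu"` (default) or `"identity"`
#' @return (T - K1 + 1) x A feature-map matrix with attribute `K1`
#' @export
conv_ngram <- function(X, filters, b0 = numeric(length(filters)),
                       activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  K1 <- nrow(filters[[1]])
  T_ <- nrow(X)
  if (T_ < K1)
    stop(sprintf("sequence length %d is shorter than the window K1=%d",
                 T_, K1))
  np <- T_ - K1 + 1L
  M <- matrix(0, np, length(filters))
  for (p in seq_len(np)) {
    win <- X[p:(p + K1 - 1L), , drop = FALSE]
    for (a in seq_along(filters))
      M[p, a] <- sum(win * filters[[a]]) + b0[a]
  }
  if (activation == "relu") M <- relu(M)
  attr(M, "K1") <- K1
  M
}

#' Primary capsule layer
#'
#' Maps each window's feature column to one d-dimensional capsule per channel
#' (`p = squash(W_b[[ch]] %*% M_p + b1[ch, ])`) and squashes it. Capsules are
#' ordered channel-major (all windows of channel 1, then channel 2, ...).
#'
#' @param M feature map from [conv_ngram()] (Np x A)
#' @param W_b list over channels of d x A matrices
#' @param b1 channels x d bias matrix
#' @param d capsule dimension
#' @return list with `P` (Np*channels x d matrix of squashed poses),
#'   `positions` and `channels` index vectors, class `primary_capsules`
#' @export
primary_capsules <- function(M, W_b, b1, d) {
  ch <- length(W_b)
  np <- nrow(M)
  P <- matrix(0, np * ch, d)
  for (cc in seq_len(ch)) {
    for (p in seq_len(np)) {
      s <- as.numeric(W_b[[cc]] %*% M[p, ] + b1[cc, ])
      P[(cc - 1L) * np + p, ] <- squash(s)
    }
  }
  structure(list(P = P,
                 positions = rep(seq_len(np), ch),
                 channels = rep(seq_len(ch), each = np),
                 d = d),
            class = "primary_capsules")
}

#' Squashing nonlinearity
#'
#' `v = (||s||^2 / (1 + ||s||^2)) * s / ||s||`, with `squash(0) = 0`. Output
#' norms lie in \[0, 1), grow monotonically with the input norm, and the
#' direction is preserved. A small epsilon in the denominator guards the
#' origin.
#'
#' @param s numeric vector
#' @param eps numerical guard added to `||s||` (default 1e-12)
#' @return squashed vector of the same length
#' @export
squash <- function(s, eps = 1e-12) {
  n2 <- sum(s * s)
  s * (n2 / ((1 + n2) * (sqrt(n2) + eps)))
}

#' Dynamic routing by agreement
#'
#' Iteratively couples lower capsules i to class capsules j: logits start at
#' zero; each iteration sets `c_i. = softmax(b_i.)` across classes, forms
#' `s_j = sum_i c_ij u_hat[i, j, ]`, squashes it into `v_j`, and (before every
#' iteration but the last) updates `b_ij <- b_ij + u_hat[i, j, ] . v_j`. The
#' full per-iteration trace is returned.
#'
#' @param u_hat Cp x k x d array of predictions from lower capsules
#' @param iterations number of routing iterations (>= 1)
#' @return a `routing_state`: list with final `b`, `c` (Cp x k), `v` (k x d),
#'   `iterations`, and `history` (per-iteration list of `c`, `v`, `b`)
#' @export
dynamic_routing <- function(u_hat, iterations = 3L) {
  if (iterations < 1L) stop("iterations must be >= 1")
  dims <- dim(u_hat)
  if (length(dims) != 3L) stop("u_hat must be a Cp x k x d array")
  cp <- dims[1]; k <- dims[2]; d <- dims[3]
  b <- matrix(0, cp, k)
  v <- matrix(0, k, d)
  history <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    cmat <- softmax_rows(b)
    for (j in seq_len(k)) {
      s_j <- numeric(d)
      for (i in seq_len(cp)) s_j <- s_j + cmat[i, j] * u_hat[i, j, ]
      v[j, ] <- squash(s_j)
    }
    if (it < iterations) {
      for (i in seq_len(cp))
        for (j in seq_len(k))
          b[i, j] <- b[i, j] + sum(u_hat[i, j, ] * v[j, ])
    }
    history[[it]] <- list(c = cmat, v = v, b = b)
  }
  structure(list(u_hat = u_hat, b = b, c = history[[iterations]]$c, v = v,
                 iterations = iterations, history = history),
            class = "routing_state")
}

# row-wise max-subtracted softmax
softmax_rows <- function(b) {
  m <- apply(b, 1, max)
  e <- exp(b - m)
  e / rowSums(e)
}

#' Class-capsule scores via prediction transforms and routing
#'
#' Applies the shared transform `W[[channel]][[j]]` to every primary capsule
#' to form the predictions `u_hat`, runs [dynamic_routing()], and returns the
#' class scores `||v_j||` together with the routing trace.
#'
#' @param caps a `primary_capsules` object
#' @param W list over channels of lists over classes of d_out x d matrices
#' @param iterations routing iterations
#' @return list with `scores` (k-vector in \[0, 1)) and `trace`
#'   (a `routing_state` with `positions`/`channels` attached)
#' @export
class_scores <- function(caps, W, iterations = 3L) {
  k <- length(W[[1]])
  d_out <- nrow(W[[1]][[1]])
  cp <- nrow(caps$P)
  u_hat <- array(0, c(cp, k, d_out))
  for (i in seq_len(cp)) {
    ch <- caps$channels[i]
    for (j in seq_len(k))
      u_hat[i, j, ] <- as.numeric(W[[ch]][[j]] %*% caps$P[i, ])
  }
  trace <- dynamic_routing(u_hat, iterations)
  trace$positions <- caps$positions
  trace$channels <- caps$channels
  list(scores = row_norms(trace$v), trace = trace)
}
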