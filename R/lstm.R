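#' Initialise LSTM parameters
#'
#' One weight matrix `W` (input), one recurrence matrix `U` and one bias `b`
#' per gate (`f`, `g`, `o`, `i`). Weights are Glorot-uniform; biases are zero
#' except the forget gate's, initialised to 1 (a standard choice that keeps
#' early memory open).
#'
#' @param input_dim input dimension
#' @param hidden_units number of hidden units u
#' @param seed integer seed
#' @return list with elements `W`, `U`, `b`, each a list over gates
#' @export
lstm_params <- function(input_dim, hidden_units, seed = 1L) {
  with_seed(seed, {
    gl <- function(nr, nc) {
      r <- sqrt(6 / (nr + nc))
      matrix(runif(nr * nc, -r, r), nr, nc)
    }
    gates <- c("f", "g", "o", "i")
    W <- setNames(lapply(gates, function(g) gl(hidden_units, input_dim)), gates)
    U <- setNames(lapply(gates, function(g) gl(hidden_units, hidden_units)),
                  gates)
    b <- setNames(lapply(gates, function(g) {
      if (g == "f") rep(1, hidden_units) else rep(0, hidden_units)
    }), gates)
    list(W = W, U = U, b = b)
  })
}

#' One LSTM step
#'
#' Computes the gate system
#' \deqn{f_t = \sigma(W_f x_t + U_f h_{t-1} + b_f)}
#' \deqn{g_t = \tanh(W_g x_t + U_g h_{t-1} + b_g)}
#' \deqn{o_t = \sigma(W_o x_t + U_o h_{t-1} + b_o)}
#' \deqn{i_t = \sigma(W_i x_t + U_i h_{t-1} + b_i)}
#' \deqn{c_t = f_t \odot c_{t-1} + i_t \odot g_t, \quad
#'       h_t = o_t \odot \tanh(c_t)}
#'
#' @param x input vector
#' @param h_prev,c_prev previous hidden and cell state (u-vectors)
#' @param params from [lstm_params()]
#' @return list with `h` and `c`
#' @export
lstm_step <- function(x, h_prev, c_prev, params) {
  u <- length(h_prev)
  if (length(c_prev) != u) stop("h_prev and c_prev lengths differ")
  if (ncol(params$W$f) != length(x))
    stop(sprintf("input length %d does not match W columns %d",
                 length(x), ncol(params$W$f)))
  gate <- function(g, act) {
    act(as.numeric(params$W[[g]] %*% x + params$U[[g]] %*% h_prev +
                     params$b[[g]]))
  }
  f <- gate("f", sigmoid)
  g <- gate("g", tanh)
  o <- gate("o", sigmoid)
  i <- gate("i", sigmoid)
  c_t <- f * c_prev + i * g
  list(h = o * tanh(c_t), c = c_t)
}

# run one direction over a T x in matrix; zero initial states
lstm_forward_seq <- function(X, params) {
  u <- nrow(params$W$f)
  H <- matrix(0, nrow(X), u)
  h <- numeric(u); cc <- numeric(u)
  for (t in seq_len(nrow(X))) {
    st <- lstm_step(X[t, ], h, cc, params)
    h <- st$h; cc <- st$c
    H[t, ] <- h
  }
  H
}

#' Bidirectional LSTM encoding
#'
#' Runs a forward pass and a backward pass (on the reversed sequence) with
#' independent parameters and zero initial states; position t of the output
#' holds the forward hidden state concatenated with the backward hidden state
#' for that position.
#'
#' @param X T x in matrix of input vectors (one row per position)
#' @param fwd_params,bwd_params parameter sets from [lstm_params()]
#' @return T x 2u matrix
#' @export
bilstm_encode <- function(X, fwd_params, bwd_params) {
  if (!is.matrix(X) || nrow(X) < 1L) stop("X must have at least one row")
  Hf <- lstm_forward_seq(X, fwd_params)
  Hb <- lstm_forward_seq(X[rev(seq_len(nrow(X))), , drop = FALSE], bwd_params)
  cbind(Hf, Hb[rev(seq_len(nrow(X))), , drop = FALSE])
}
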