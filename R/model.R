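#' Model configuration
#'
#' Collects every tunable of the hybrid coder with the defaults used in this
#' line of work: embedding dimension 200, 300 Bi-LSTM hidden units, capsule
#' dimension 50, 3 routing iterations, batch size 16, learning rate 0.01.
#' The convolution window (`K1 = 3`), filter count and primary-capsule
#' channels are configurable (they are not pinned down for the full model in
#' the literature this follows; kernel sizes 3--5 are typical).
#'
#' @param e word/label embedding dimension
#' @param hidden_units Bi-LSTM hidden units per direction
#' @param capsule_dim capsule dimension d
#' @param routing_iters dynamic-routing iterations
#' @param K1 n-gram convolution window
#' @param n_filters number of convolution filters
#' @param channels primary-capsule channels per position
#' @param batch_size minibatch size
#' @param learning_rate Adam learning rate
#' @param loss_mode `"sigmoid-bce"` (default; each label an independent
#'   Bernoulli, the decision rule is well-posed) or `"softmax-ce"`
#'   (softmax + cross-entropy against multi-hot targets normalised to sum 1)
#' @param label_fusion logical: enable the label-embedding fusion (G and D)
#' @param bilstm logical: enable the Bi-LSTM encoder
#' @param max_len maximum token sequence length
#' @param max_epochs training epoch cap
#' @param patience early-stopping patience (epochs without validation
#'   improvement)
#' @param threshold decision threshold for the `"threshold"` policy
#' @param top_k k for the `"topk"` decision policy
#' @param seed integer seed for initialisation and shuffling
#' @return a validated `caps_config` list
#' @export
model_config <- function(e = 200L, hidden_units = 300L, capsule_dim = 50L,
                         routing_iters = 3L, K1 = 3L, n_filters = 64L,
                         channels = 32L, batch_size = 16L,
                         learning_rate = 0.01,
                         loss_mode = c("sigmoid-bce", "softmax-ce"),
                         label_fusion = TRUE, bilstm = TRUE,
                         max_len = 2500L, max_epochs = 50L, patience = 3L,
                         threshold = 0.5, top_k = 8L, seed = 1L) {
  loss_mode <- match.arg(loss_mode)
  cfg <- list(e = as.integer(e), hidden_units = as.integer(hidden_units),
              capsule_dim = as.integer(capsule_dim),
              routing_iters = as.integer(routing_iters), K1 = as.integer(K1),
              n_filters = as.integer(n_filters),
              channels = as.integer(channels),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, loss_mode = loss_mode,
              label_fusion = isTRUE(label_fusion), bilstm = isTRUE(bilstm),
              max_len = as.integer(max_len), max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), threshold = threshold,
              top_k = as.integer(top_k), seed = as.integer(seed))
  ints <- c("e", "hidden_units", "capsule_dim", "routing_iters", "K1",
            "n_filters", "channels", "batch_size", "max_len", "max_epochs",
            "top_k")
  for (f in ints)
    if (cfg[[f]] < 1L) stop(sprintf("config field '%s' must be positive", f))
  if (cfg$learning_rate < 0) stop("learning_rate must be >= 0")
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop("threshold must lie in (0, 1)")
  structure(cfg, class = "caps_config")
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

#' Build the hybrid capsule coder
#'
#' Wires token embeddings -> word-label similarity augmentation -> Bi-LSTM ->
#' n-gram convolution -> primary capsules -> dynamic routing, with the pooled
#' sentence-label similarity vector D concatenated to the flattened class
#' capsules before the dense head. The ablation flags `label_fusion` and
#' `bilstm` produce the CapsNet / BiCapsNet / full variants: disabling fusion
#' zeroes the G tail and D while keeping tensor shapes, so the fused graph
#' degrades to the unfused one exactly. Initialisation is deterministic given
#' `config$seed`.
#'
#' @param config from [model_config()]
#' @param emb an `embedding_matrix` (its dimension must equal `config$e`)
#' @param label_emb a `label_embedding_matrix` over the label space
#' @return a `caps_model`: list with `config`, `params`, `emb`, `label_emb`,
#'   `labels`, and the precomputed token-label cosine lookup
#' @export
build_model <- function(config, emb, label_emb) {
  if (ncol(emb$vectors) != config$e)
    stop(sprintf("word embeddings have dimension %d but config$e = %d",
                 ncol(emb$vectors), config$e))
  if (ncol(label_emb$vectors) != config$e)
    stop(sprintf("label embeddings have dimension %d but config$e = %d",
                 ncol(label_emb$vectors), config$e))
  L <- length(label_emb$labels)
  e <- config$e; u <- config$hidden_units
  d <- config$capsule_dim; ch <- config$channels; A <- config$n_filters
  n_in <- e + L
  e_conv <- if (config$bilstm) 2L * u else n_in
  params <- with_seed(config$seed, {
    p <- list()
    for (dir in c("lf", "lb")) {
      p[[paste0(dir, "_W")]] <- glorot(4L * u, n_in)
      p[[paste0(dir, "_U")]] <- glorot(4L * u, u)
      b <- rep(0, 4L * u)
      b[seq_len(u)] <- 1 # forget-gate bias
      p[[paste0(dir, "_b")]] <- b
    }
    p$conv_W <- glorot(A, config$K1 * e_conv)
    p$conv_b <- rep(0, A)
    p$caps_W <- glorot(ch * d, A)
    p$caps_b <- rep(0, ch * d)
    p$route_W <- array(glorot(d, d * ch * L), dim = c(d, d, ch * L))
    p$proj_W <- glorot(e, e_conv)
    p$head_W <- glorot(L, L * d + L)
    p$head_b <- rep(0, L)
    p
  })
  Gv <- word_label_similarity(label_emb$vectors, emb$vectors) # L x vocab
  structure(list(config = config, params = params, emb = emb,
                 label_emb = label_emb, labels = label_emb$labels,
                 Gv = t(Gv)),
            class = "caps_model")
}

#' @export
print.caps_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    paste0("<caps_model> %s%slabels=%d e=%d u=%d d=%d K1=%d ch=%d ",
           "iters=%d loss=%s params=%s\n"),
    if (cfg$bilstm) "BiLSTM+" else "",
    if (cfg$label_fusion) "fusion+" else "",
    length(x$labels), cfg$e, cfg$hidden_units, cfg$capsule_dim, cfg$K1,
    cfg$channels, cfg$routing_iters, cfg$loss_mode,
    format(n_par, big.mark = ",")))
  invisible(x)
}

# engine-facing config list
engine_cfg <- function(model) {
  cfg <- model$config
  list(e = cfg$e, L = length(model$labels), u = cfg$hidden_units,
       K1 = cfg$K1, A = cfg$n_filters, ch = cfg$channels,
       d = cfg$capsule_dim, iters = cfg$routing_iters,
       loss_mode = if (cfg$loss_mode == "sigmoid-bce") 0L else 1L,
       use_bilstm = cfg$bilstm, use_fusion = cfg$label_fusion)
}

# 0-based token index sequences, padded to at least K1 positions
note_token_ids <- function(model, notes) {
  pad <- match(padding_token(), model$emb$vocab) - 1L
  K1 <- model$config$K1
  max_len <- model$config$max_len
  lapply(notes, function(n) {
    toks <- if (is.list(n)) n$tokens else n
    if (length(toks) > max_len) toks <- toks[seq_len(max_len)]
    idx <- token_indices(model$emb, toks) - 1L
    if (length(idx) < K1) idx <- c(idx, rep(pad, K1 - length(idx)))
    idx
  })
}

#' Gold multi-hot matrix for a list of tokenized notes
#'
#' @param notes a `tokenized_corpus`
#' @param labels canonical label order
#' @return binary N x L matrix, rows named by `hadm_id`
#' @export
gold_matrix <- function(notes, labels) {
  Y <- matrix(0, length(notes), length(labels),
              dimnames = list(vapply(notes, function(n) n$hadm_id,
                                     character(1)),
                              labels))
  for (i in seq_along(notes))
    Y[i, match(intersect(notes[[i]]$codes, labels), labels)] <- 1
  Y
}

#' Per-note label scores
#'
#' Runs the model forward over a set of notes. Notes whose token sequence is
#' empty after preprocessing are scored on padding alone and flagged via the
#' `"empty_notes"` attribute rather than dropped.
#'
#' @param model a `caps_model`
#' @param notes a `tokenized_corpus` (or list of token vectors)
#' @return N x L score matrix in \[0, 1\], rows named by `hadm_id` where
#'   available, columns by label
#' @export
predict_scores <- function(model, notes) {
  ids <- note_token_ids(model, notes)
  res <- cpp_run_batch(ids, matrix(0, 0, 0), model$params,
                       model$emb$vectors, model$Gv, model$label_emb$vectors,
                       engine_cfg(model), FALSE, TRUE)
  S <- res$scores
  rn <- vapply(seq_along(notes), function(i) {
    n <- notes[[i]]
    if (is.list(n) && !is.null(n$hadm_id)) n$hadm_id else as.character(i)
  }, character(1))
  dimnames(S) <- list(rn, model$labels)
  empty <- which(vapply(notes, function(n) {
    toks <- if (is.list(n)) n$tokens else n
    length(toks) == 0L
  }, logical(1)))
  if (length(empty)) {
    warning(sprintf("%d note(s) had empty token sequences; scored on padding",
                    length(empty)))
    attr(S, "empty_notes") <- empty
  }
  S
}

#' Mean loss of a model on a set of notes
#'
#' @param model a `caps_model`
#' @param notes a `tokenized_corpus`
#' @return mean per-note loss in the model's `loss_mode`
#' @export
model_loss <- function(model, notes) {
  ids <- note_token_ids(model, notes)
  Y <- gold_matrix(notes, model$labels)
  res <- cpp_run_batch(ids, Y, model$params, model$emb$vectors, model$Gv,
                       model$label_emb$vectors, engine_cfg(model),
                       FALSE, FALSE)
  res$loss_sum / res$n
}

#' Turn score rows into predicted code sets
#'
#' The threshold policy keeps labels with score >= tau; the top-k policy keeps
#' the k highest-scoring labels, breaking ties by canonical label order.
#' Deterministic.
#'
#' @param scores N x L score matrix with label column names
#' @param policy `"threshold"` or `"topk"`
#' @param threshold tau in (0, 1)
#' @param k number of labels for the top-k policy
#' @return list of character vectors of predicted labels, one per row
#' @export
scores_to_codes <- function(scores, policy = c("threshold", "topk"),
                            threshold = 0.5, k = 8L) {
  policy <- match.arg(policy)
  labels <- colnames(scores)
  apply_row <- function(s) {
    if (policy == "threshold") {
      labels[s >= threshold]
    } else {
      labels[order(-s, seq_along(s))[seq_len(min(k, length(s)))]]
    }
  }
  lapply(seq_len(nrow(scores)), function(i) apply_row(scores[i, ]))
}

#' Binary prediction matrix from code sets
#'
#' @param code_sets list of character vectors (e.g. from [scores_to_codes()])
#' @param labels canonical label order
#' @return binary matrix, one row per set
#' @export
codes_to_matrix <- function(code_sets, labels) {
  P <- matrix(0, length(code_sets), length(labels),
              dimnames = list(NULL, labels))
  for (i in seq_along(code_sets))
    P[i, match(intersect(code_sets[[i]], labels), labels)] <- 1
  P
}

# --- pure-R reference forward pass -----------------------------------------
# Chains the module-level functions (embed -> similarity -> Bi-LSTM -> conv ->
# capsules -> routing -> fusion -> head) so tests can confirm the C++ engine
# computes the same network. Slow; for verification only.
forward_note_reference <- function(model, tokens) {
  cfg <- model$config
  L <- length(model$labels)
  u <- cfg$hidden_units; d <- cfg$capsule_dim
  ch <- cfg$channels; A <- cfg$n_filters
  p <- model$params
  if (length(tokens) < cfg$K1)
    tokens <- c(tokens, rep(padding_token(), cfg$K1 - length(tokens)))
  V <- embed_tokens(model$emb, tokens)
  C <- model$label_emb$vectors
  G <- if (cfg$label_fusion) word_label_similarity(C, V)
       else matrix(0, L, nrow(V))
  X <- augment_tokens(G, V)
  split_gates <- function(W) {
    n <- nrow(W) / 4
    list(f = W[seq_len(n), , drop = FALSE],
         g = W[n + seq_len(n), , drop = FALSE],
         o = W[2 * n + seq_len(n), , drop = FALSE],
         i = W[3 * n + seq_len(n), , drop = FALSE])
  }
  split_bias <- function(b) {
    n <- length(b) / 4
    list(f = b[seq_len(n)], g = b[n + seq_len(n)],
         o = b[2 * n + seq_len(n)], i = b[3 * n + seq_len(n)])
  }
  H <- if (cfg$bilstm) {
    fwd <- list(W = split_gates(p$lf_W), U = split_gates(p$lf_U),
                b = split_bias(p$lf_b))
    bwd <- list(W = split_gates(p$lb_W), U = split_gates(p$lb_U),
                b = split_bias(p$lb_b))
    bilstm_encode(X, fwd, bwd)
  } else X
  filters <- lapply(seq_len(A), function(a)
    matrix(p$conv_W[a, ], nrow = cfg$K1, byrow = TRUE))
  M <- conv_ngram(H, filters, p$conv_b)
  W_b <- lapply(seq_len(ch), function(cc)
    p$caps_W[(cc - 1) * d + seq_len(d), , drop = FALSE])
  b1 <- matrix(p$caps_b, ch, d, byrow = TRUE)
  caps <- primary_capsules(M, W_b, b1, d)
  Wr <- lapply(seq_len(ch), function(cc)
    lapply(seq_len(L), function(j) p$route_W[, , (cc - 1) * L + j]))
  cs <- class_scores(caps, Wr, cfg$routing_iters)
  Dv <- if (cfg$label_fusion) {
    sentence_label_similarity(colMeans(H), C, p$proj_W)
  } else rep(0, L)
  fused <- fuse_for_classification(as.vector(t(cs$trace$v)), Dv)
  logits <- as.numeric(p$head_W %*% fused + p$head_b)
  if (cfg$loss_mode == "sigmoid-bce") sigmoid(logits)
  else {
    z <- exp(logits - max(logits)); z / sum(z)
  }
}
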