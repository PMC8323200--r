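#' Cosine similarity with a zero-norm convention
#'
#' Returns `a . b / (||a|| ||b||)`, or 0 when either norm is zero (so all-zero
#' padding vectors are neutral).
#'
#' @param a,b numeric vectors of equal length
#' @return scalar in \[-1, 1\]
#' @export
cosine_sim <- function(a, b) {
  if (length(a) != length(b)) stop("vectors have different lengths")
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Word-label similarity map G
#'
#' `G[i, t]` is the cosine similarity between label vector `C_i` and token
#' vector `V_t`; rows of either matrix with zero norm give zeros. Invariant to
#' positive rescaling of any row.
#'
#' @param C L x e label embedding matrix (or `label_embedding_matrix`)
#' @param V T x e token embedding matrix
#' @return L x T matrix of cosines
#' @export
word_label_similarity <- function(C, V) {
  if (inherits(C, "label_embedding_matrix")) C <- C$vectors
  if (ncol(C) != ncol(V))
    stop(sprintf("dimension mismatch: labels e=%d, tokens e=%d",
                 ncol(C), ncol(V)))
  nc <- row_norms(C); nv <- row_norms(V)
  G <- tcrossprod(C, V)
  denom <- outer(nc, nv)
  G <- ifelse(denom == 0, 0, G / ifelse(denom == 0, 1, denom))
  G
}

#' Concatenate the similarity map onto token embeddings
#'
#' Position t of the result is `[V_t ; G[, t]]`: the raw word vector followed
#' by its L label similarities. This augmented sequence is what the Bi-LSTM
#' encoder consumes in the fused model.
#'
#' @param G L x T similarity map from [word_label_similarity()]
#' @param V T x e token embedding matrix
#' @return T x (e + L) matrix
#' @export
augment_tokens <- function(G, V) {
  if (ncol(G) != nrow(V))
    stop(sprintf("shape mismatch: G has %d columns, V has %d rows",
                 ncol(G), nrow(V)))
  cbind(V, t(G))
}

#' Sentence-label similarity vector D
#'
#' Projects the pooled text representation `z` into the embedding space and
#' takes its cosine similarity with every label vector.
#'
#' @param z pooled text vector
#' @param C L x e label embedding matrix (or `label_embedding_matrix`)
#' @param projection `NULL` (identity; `z` must already be length e) or an
#'   e x length(z) projection matrix
#' @return L-vector of cosines
#' @export
sentence_label_similarity <- function(z, C, projection = NULL) {
  if (inherits(C, "label_embedding_matrix")) C <- C$vectors
  zp <- if (is.null(projection)) z else as.numeric(projection %*% z)
  if (length(zp) != ncol(C))
    stop(sprintf("projected z has length %d but labels have e=%d",
                 length(zp), ncol(C)))
  vapply(seq_len(nrow(C)), function(i) cosine_sim(zp, C[i, ]), numeric(1))
}

#' Fuse capsule features with the label similarity vector
#'
#' The classification head's input: the flattened class-capsule outputs
#' concatenated with D.
#'
#' @param capsule_features numeric vector (flattened class capsules)
#' @param D L-vector from [sentence_label_similarity()]
#' @return concatenated numeric vector
#' @export
fuse_for_classification <- function(capsule_features, D) {
  stopifnot(all(is.finite(capsule_features)), all(is.finite(D)))
  c(capsule_features, D)
}
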