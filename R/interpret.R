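#' Routing-strength attribution for one note
#'
#' The final-iteration coupling coefficients say how strongly each primary
#' capsule (an n-gram window) routes into each class capsule; summing them
#' over the capsule channels at a position gives a per-window, per-label
#' connection strength that works like an attention weight. Records are
#' sorted by descending strength within each label.
#'
#' @param trace routing trace: a list with `coupling` (or `c`) as a
#'   Ncap x k matrix, plus `np` and `channels` (as returned by
#'   [explain_note()]'s engine call or [class_scores()])
#' @param tokens the note's token vector (the one the trace was computed on)
#' @param K1 convolution window size
#' @param labels canonical label order (k labels)
#' @param aggregate `"sum"` (default; preserves the routing normalisation up
#'   to the channel count) or `"max"` over channels
#' @return data.frame with `label`, `ngram`, `position` (0-based window
#'   start), `strength`
#' @export
connection_strengths <- function(trace, tokens, K1, labels,
                                 aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  cmat <- trace$coupling %||% trace$c
  np <- trace$np %||% max(trace$positions)
  ch <- trace$channels
  if (length(ch) > 1L) ch <- max(ch) # class_scores stores per-capsule ids
  if (nrow(cmat) != np * ch)
    stop("trace does not match: coupling rows != positions * channels")
  if (length(tokens) < np + K1 - 1L)
    stop("trace does not match the supplied tokens")
  k <- ncol(cmat)
  if (length(labels) != k) stop("labels length does not match trace classes")
  agg <- matrix(0, np, k)
  for (p in seq_len(np)) {
    rows <- cmat[(seq_len(ch) - 1L) * np + p, , drop = FALSE] # channel-major
    agg[p, ] <- if (aggregate == "sum") colSums(rows) else apply(rows, 2, max)
  }
  ngrams <- vapply(seq_len(np), function(p)
    paste(tokens[p:(p + K1 - 1L)], collapse = " "), character(1))
  out <- data.frame(label = rep(labels, each = np),
                    ngram = rep(ngrams, k),
                    position = rep(seq_len(np) - 1L, k),
                    strength = as.vector(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$label, labels), -out$strength, out$position), ,
             drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Run a trained model on one note and return attribution records
#'
#' @param model a `caps_model`
#' @param note a tokenized note (`list(hadm_id, tokens, codes)`) or a token
#'   vector
#' @param aggregate channel aggregation, see [connection_strengths()]
#' @return list with `scores` (named label scores) and `attribution`
#'   (records from [connection_strengths()])
#' @export
explain_note <- function(model, note, aggregate = "sum") {
  tokens <- if (is.list(note)) note$tokens else note
  if (length(tokens) < model$config$K1)
    tokens <- c(tokens, rep(padding_token(),
                            model$config$K1 - length(tokens)))
  ids <- note_token_ids(model, list(tokens))[[1]]
  tr <- cpp_forward_trace(ids, model$params, model$emb$vectors, model$Gv,
                          model$label_emb$vectors, engine_cfg(model))
  att <- connection_strengths(tr, tokens, model$config$K1, model$labels,
                              aggregate = aggregate)
  list(scores = setNames(as.numeric(tr$scores), model$labels),
       attribution = att)
}

#' Top n-grams driving one label
#'
#' Duplicate n-gram strings are aggregated by their maximum strength (the
#' font-size semantics of a word cloud), then ranked.
#'
#' @param records attribution records from [connection_strengths()]
#' @param label one label
#' @param n how many n-grams to return
#' @return data.frame `ngram`, `strength`, descending
#' @export
top_ngrams <- function(records, label, n = 10L) {
  if (n < 1L) stop("n must be >= 1")
  if (!label %in% records$label) stop(sprintf("unknown label '%s'", label))
  r <- records[records$label == label, , drop = FALSE]
  s <- tapply(r$strength, r$ngram, max)
  out <- data.frame(ngram = names(s), strength = as.numeric(s),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$strength, out$ngram), , drop = FALSE]
  row.names(out) <- NULL
  utils::head(out, n)
}

#' Export word-cloud weights for one label
#'
#' Writes a two-column CSV (`ngram`, `weight`) with max-aggregated strengths
#' normalised to \[0, 1\] (the maximum is exactly 1 for a non-empty record
#' set); any word-cloud renderer can consume it.
#'
#' @param records attribution records
#' @param label one label
#' @param path output CSV path
#' @return the weights data.frame, invisibly
#' @export
export_wordcloud_weights <- function(records, label, path) {
  w <- top_ngrams(records, label, n = .Machine$integer.max)
  if (nrow(w)) w$weight <- w$strength / max(w$strength)
  else w$weight <- numeric(0)
  out <- w[, c("ngram", "weight")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
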