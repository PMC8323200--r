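#' Micro-averaged F1 over all note-label decisions
#'
#' Pools true/false positives and false negatives over every cell, so frequent
#' codes dominate: `2 TP / (2 TP + FP + FN)`.
#'
#' @param gold,pred N x L binary matrices
#' @return fraction in \[0, 1\]
#' @export
micro_f1 <- function(gold, pred) {
  check_same_shape(gold, pred)
  tp <- sum(gold == 1 & pred == 1)
  fp <- sum(gold == 0 & pred == 1)
  fn <- sum(gold == 1 & pred == 0)
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Macro-averaged F1 (unweighted mean over labels)
#'
#' Computes F1 per label and averages with equal weight, which emphasises
#' rare codes; a label with zero TP, FP and FN (or zero precision + recall)
#' contributes 0.
#'
#' @param gold,pred N x L binary matrices
#' @return fraction in \[0, 1\]
#' @export
macro_f1 <- function(gold, pred) {
  check_same_shape(gold, pred)
  f1 <- vapply(seq_len(ncol(gold)), function(l) {
    tp <- sum(gold[, l] == 1 & pred[, l] == 1)
    fp <- sum(gold[, l] == 0 & pred[, l] == 1)
    fn <- sum(gold[, l] == 1 & pred[, l] == 0)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

check_same_shape <- function(gold, pred) {
  if (!all(dim(gold) == dim(pred)))
    stop(sprintf("shape mismatch: gold %dx%d vs pred %dx%d",
                 nrow(gold), ncol(gold), nrow(pred), ncol(pred)))
}

#' Top-10 recall
#'
#' Per note with gold set M: the fraction of gold codes ranked within the top
#' `max(10, |M|)` scores (ties broken by label order), averaged over notes.
#' Notes with empty gold sets are excluded with a warning. Invariant to any
#' strictly monotone transform of the scores.
#'
#' @param scores N x L score matrix (columns in canonical label order)
#' @param gold N x L binary matrix, or a list of gold label-index vectors
#' @param k_base rank floor (default 10)
#' @return fraction in \[0, 1\]
#' @export
top10_recall <- function(scores, gold, k_base = 10L) {
  gold_sets <- if (is.matrix(gold)) {
    check_same_shape(gold, scores)
    lapply(seq_len(nrow(gold)), function(i) which(gold[i, ] == 1))
  } else gold
  m_sizes <- lengths(gold_sets)
  if (any(m_sizes == 0L)) {
    warning(sprintf("excluded %d note(s) with empty gold sets",
                    sum(m_sizes == 0L)))
  }
  keep <- which(m_sizes > 0L)
  vals <- vapply(keep, function(i) {
    m <- m_sizes[i]
    K <- max(k_base, m)
    top <- order(-scores[i, ], seq_len(ncol(scores)))[seq_len(min(K, ncol(scores)))]
    length(intersect(gold_sets[[i]], top)) / m
  }, numeric(1))
  mean(vals)
}

#' Rank-based AUC for one label
#'
#' Mann-Whitney formulation with average ranks for ties; equals the
#' probability that a random positive outscores a random negative.
#'
#' @param scores numeric score vector
#' @param labels binary gold vector
#' @return AUC in \[0, 1\], or `NA` when the label is all-positive or
#'   all-negative
#' @export
label_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Label-frequency bins
#'
#' Inclusive, non-overlapping count intervals used to group labels by their
#' training-set frequency. The default follows the common reporting scheme
#' for rare-code analysis, \[1,10\], \[11,50\], \[51,100\], \[101,Inf\) --
#' the last two bins are made disjoint at 100/101.
#'
#' @param lo,hi integer vectors of inclusive bounds
#' @return data.frame with `lo`, `hi`, `label`
#' @export
frequency_bins <- function(lo = c(1, 11, 51, 101),
                           hi = c(10, 50, 100, Inf)) {
  if (length(lo) != length(hi) || any(lo > hi))
    stop("bins must be ordered intervals lo <= hi")
  if (any(lo[-1] != utils::head(hi, -1) + 1))
    stop("bins must be non-overlapping and exhaustive")
  data.frame(lo = lo, hi = hi,
             label = sprintf("[%g,%s]", lo,
                             ifelse(is.finite(hi), as.character(hi), "Inf")),
             stringsAsFactors = FALSE)
}

bin_of <- function(counts, bins) {
  idx <- rep(NA_integer_, length(counts))
  for (b in seq_len(nrow(bins)))
    idx[counts >= bins$lo[b] & counts <= bins$hi[b]] <- b
  idx
}

#' Macro AUC by label-frequency group
#'
#' Assigns every label to a frequency bin by its training-set count, computes
#' each label's rank AUC on the evaluation scores, and averages (unweighted)
#' within each bin. Labels whose gold column is all-positive or all-negative
#' are skipped with a warning; empty groups are absent from the result, not 0.
#'
#' @param scores,gold N x L matrices
#' @param train_label_counts named numeric vector, label -> training count
#' @param bins from [frequency_bins()]
#' @return named numeric vector, one entry per non-empty group
#' @export
macro_auc_by_group <- function(scores, gold, train_label_counts,
                               bins = frequency_bins()) {
  check_same_shape(gold, scores)
  labels <- colnames(scores) %||% as.character(seq_len(ncol(scores)))
  counts <- train_label_counts[labels]
  counts[is.na(counts)] <- 0
  auc <- vapply(seq_len(ncol(scores)), function(l)
    label_auc(scores[, l], gold[, l]), numeric(1))
  if (anyNA(auc))
    warning(sprintf("skipped %d degenerate label(s) (all-positive/negative)",
                    sum(is.na(auc))))
  grp <- bin_of(counts, bins)
  out <- numeric(0)
  for (b in seq_len(nrow(bins))) {
    vals <- auc[which(grp == b)]
    vals <- vals[!is.na(vals)]
    if (length(vals)) out[bins$label[b]] <- mean(vals)
  }
  out
}

#' Per-label error breakdown and confused code pairs
#'
#' Tallies false positives and false negatives per label (annotated with the
#' label's frequency bin) and counts, per note, co-occurrences of a missed
#' gold code with a falsely predicted one -- the pattern behind rare codes
#' being predicted as similar frequent ones. A pair is marked similar when
#' the roots share a 2-character prefix or their description embeddings have
#' cosine >= `sim_threshold`.
#'
#' @param gold,pred N x L binary matrices with label column names
#' @param train_label_counts named numeric vector
#' @param bins from [frequency_bins()]
#' @param label_emb optional `label_embedding_matrix` for description cosine
#' @param sim_threshold cosine threshold for description similarity
#' @return list with `per_label` (data.frame label, fp, fn, bin) and
#'   `confused_pairs` (data.frame gold, pred, n, similar, sorted by n)
#' @export
error_breakdown <- function(gold, pred, train_label_counts,
                            bins = frequency_bins(), label_emb = NULL,
                            sim_threshold = 0.7) {
  check_same_shape(gold, pred)
  labels <- colnames(gold) %||% as.character(seq_len(ncol(gold)))
  fp <- colSums(gold == 0 & pred == 1)
  fn <- colSums(gold == 1 & pred == 0)
  counts <- train_label_counts[labels]
  counts[is.na(counts)] <- 0
  per_label <- data.frame(label = labels, fp = as.integer(fp),
                          fn = as.integer(fn),
                          bin = bins$label[bin_of(counts, bins)],
                          stringsAsFactors = FALSE, row.names = NULL)
  pair_counts <- list()
  for (i in seq_len(nrow(gold))) {
    fps <- which(gold[i, ] == 0 & pred[i, ] == 1)
    fns <- which(gold[i, ] == 1 & pred[i, ] == 0)
    for (b in fns) for (a in fps) {
      key <- paste(labels[b], labels[a], sep = "->")
      pair_counts[[key]] <- (pair_counts[[key]] %||% 0L) + 1L
    }
  }
  if (length(pair_counts)) {
    parts <- strsplit(names(pair_counts), "->", fixed = TRUE)
    g <- vapply(parts, `[`, character(1), 1)
    p <- vapply(parts, `[`, character(1), 2)
    similar <- substr(g, 1, 2) == substr(p, 1, 2)
    if (!is.null(label_emb)) {
      cs <- vapply(seq_along(g), function(j) {
        ig <- match(g[j], label_emb$labels)
        ip <- match(p[j], label_emb$labels)
        if (is.na(ig) || is.na(ip)) return(0)
        cosine_sim(label_emb$vectors[ig, ], label_emb$vectors[ip, ])
      }, numeric(1))
      similar <- similar | cs >= sim_threshold
    }
    confused <- data.frame(gold = g, pred = p,
                           n = as.integer(unlist(pair_counts)),
                           similar = similar, stringsAsFactors = FALSE)
    confused <- confused[order(-confused$n, confused$gold), , drop = FALSE]
    row.names(confused) <- NULL
  } else {
    confused <- data.frame(gold = character(0), pred = character(0),
                           n = integer(0), similar = logical(0))
  }
  list(per_label = per_label, confused_pairs = confused)
}

#' Assemble the full metrics report
#'
#' Micro/macro F1 under the given decision policy, top-10 recall, test loss,
#' per-frequency-group macro AUC, and the error breakdown, bundled with the
#' decision policy that produced the binary predictions.
#'
#' @param scores N x L score matrix (label column names required)
#' @param gold N x L binary gold matrix
#' @param train_label_counts named numeric vector of training-set label counts
#' @param bins from [frequency_bins()]
#' @param policy,threshold,k decision rule passed to [scores_to_codes()]
#' @param test_loss optional scalar loss to embed (from [model_loss()])
#' @param loss_mode string recorded alongside `test_loss`
#' @return a `metrics_report` list
#' @export
metrics_report <- function(scores, gold, train_label_counts,
                           bins = frequency_bins(),
                           policy = "threshold", threshold = 0.5, k = 8L,
                           test_loss = NA_real_, loss_mode = NA_character_) {
  sets <- scores_to_codes(scores, policy = policy, threshold = threshold,
                          k = k)
  pred <- codes_to_matrix(sets, colnames(scores))
  rep <- list(
    micro_f1 = micro_f1(gold, pred),
    macro_f1 = macro_f1(gold, pred),
    top10_recall = top10_recall(scores, gold),
    test_loss = test_loss,
    loss_mode = loss_mode,
    per_group_macro_auc = as.list(
      macro_auc_by_group(scores, gold, train_label_counts, bins)),
    error_breakdown = error_breakdown(gold, pred, train_label_counts, bins),
    decision_policy = list(policy = policy, threshold = threshold,
                           k = as.integer(k)),
    n_notes = nrow(gold), n_labels = ncol(gold))
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics over %d notes x %d labels (policy: %s)\n",
              x$n_notes, x$n_labels, x$decision_policy$policy))
  cat(sprintf("  micro F1      %.4f\n", x$micro_f1))
  cat(sprintf("  macro F1      %.4f\n", x$macro_f1))
  cat(sprintf("  top-10 recall %.4f\n", x$top10_recall))
  if (is.finite(x$test_loss))
    cat(sprintf("  test loss     %.4f (%s)\n", x$test_loss, x$loss_mode))
  if (length(x$per_group_macro_auc)) {
    cat("  macro AUC by label-frequency group:\n")
    for (g in names(x$per_group_macro_auc))
      cat(sprintf("    %-10s %.4f\n", g, x$per_group_macro_auc[[g]]))
  }
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' The error breakdown's confused-pair table is truncated to the top pairs to
#' keep reports compact.
#'
#' @param report a `metrics_report`
#' @param path optional output file
#' @param max_pairs confused pairs to keep
#' @return JSON string, invisibly when `path` is given
#' @export
write_metrics_report <- function(report, path = NULL, max_pairs = 20L) {
  report$error_breakdown$confused_pairs <-
    utils::head(report$error_breakdown$confused_pairs, max_pairs)
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
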