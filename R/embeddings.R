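#' Load pretrained word vectors (word2vec formats)
#'
#' Reads the common word2vec text or binary layout (header line `"<n> <dim>"`,
#' then one token per record). Gzipped files are handled transparently. Two
#' reserved rows are appended: the unknown token (mean of all loaded vectors)
#' and the padding token (zeros); if the file already contains them they are
#' kept as-is.
#'
#' @param path vector file
#' @param format `"word2vec-text"` or `"word2vec-binary"`
#' @return an `embedding_matrix`: list with `vocab` (character) and `vectors`
#'   (numeric matrix, one row per vocab entry, rownames = vocab)
#' @export
load_word_vectors <- function(path,
                              format = c("word2vec-text", "word2vec-binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read file '%s'", path))
  if (format == "word2vec-text") {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    header <- scan(con, what = integer(), n = 2, quiet = TRUE)
    n <- header[1]; dim <- header[2]
    vocab <- character(n)
    vecs <- matrix(0, n, dim)
    for (i in seq_len(n)) {
      fields <- scan(con, what = character(), n = dim + 1, quiet = TRUE)
      if (length(fields) != dim + 1)
        stop(sprintf("format error at row %d: expected %d values", i, dim))
      vocab[i] <- fields[1]
      v <- suppressWarnings(as.numeric(fields[-1]))
      if (anyNA(v))
        stop(sprintf("format error at row %d: non-numeric vector entry", i))
      vecs[i, ] <- v
    }
  } else {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    header <- read_bin_line(con)
    hd <- suppressWarnings(as.integer(strsplit(trimws(header), " +")[[1]]))
    if (length(hd) != 2 || anyNA(hd)) stop("format error: bad binary header")
    n <- hd[1]; dim <- hd[2]
    vocab <- character(n)
    vecs <- matrix(0, n, dim)
    for (i in seq_len(n)) {
      vocab[i] <- read_bin_token(con)
      v <- readBin(con, what = "numeric", n = dim, size = 4, endian = "little")
      if (length(v) != dim)
        stop(sprintf("format error at row %d: truncated vector", i))
      vecs[i, ] <- v
    }
  }
  if (anyDuplicated(vocab)) stop("format error: duplicated tokens in file")
  if (!unknown_token() %in% vocab) {
    vocab <- c(vocab, unknown_token())
    vecs <- rbind(vecs, colMeans(vecs))
  }
  if (!padding_token() %in% vocab) {
    vocab <- c(vocab, padding_token())
    vecs <- rbind(vecs, rep(0, dim))
  }
  rownames(vecs) <- vocab
  structure(list(vocab = vocab, vectors = vecs), class = "embedding_matrix")
}

# read bytes up to '\n' as a string
read_bin_line <- function(con) {
  out <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (!length(b) || b == as.raw(10L)) break
    out <- c(out, b)
  }
  rawToChar(out)
}

# read bytes up to ' ' (skipping leading newlines) as a token
read_bin_token <- function(con) {
  out <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (!length(b)) break
    if (b == as.raw(10L) && !length(out)) next
    if (b == as.raw(32L)) break
    out <- c(out, b)
  }
  rawToChar(out)
}

#' Write word vectors in word2vec text or binary format
#'
#' Reserved unknown/padding rows are excluded so a written file round-trips
#' through [load_word_vectors()] (which re-appends them).
#'
#' @param emb an `embedding_matrix`, or a numeric matrix with rownames
#' @param path output file (a `.gz` suffix triggers gzip)
#' @param format `"word2vec-text"` or `"word2vec-binary"`
#' @return `path`, invisibly
#' @export
write_word_vectors <- function(emb, path,
                               format = c("word2vec-text", "word2vec-binary")) {
  format <- match.arg(format)
  vecs <- if (inherits(emb, "embedding_matrix")) emb$vectors else emb
  keep <- !rownames(vecs) %in% c(unknown_token(), padding_token())
  vecs <- vecs[keep, , drop = FALSE]
  open_fun <- if (grepl("\\.gz$", path)) gzfile else file
  if (format == "word2vec-text") {
    con <- open_fun(path, "wt")
    on.exit(close(con))
    writeLines(sprintf("%d %d", nrow(vecs), ncol(vecs)), con)
    for (i in seq_len(nrow(vecs)))
      writeLines(paste(rownames(vecs)[i],
                       paste(sprintf("%.9g", vecs[i, ]), collapse = " ")),
                 con)
  } else {
    con <- open_fun(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("%d %d\n", nrow(vecs), ncol(vecs))), con)
    for (i in seq_len(nrow(vecs))) {
      writeBin(charToRaw(paste0(rownames(vecs)[i], " ")), con)
      writeBin(as.numeric(vecs[i, ]), con, size = 4, endian = "little")
      writeBin(charToRaw("\n"), con)
    }
  }
  invisible(path)
}

#' Random embedding matrix over a vocabulary
#'
#' Gaussian entries scaled by `1/sqrt(dim)`; used for synthetic corpora and
#' tests. Deterministic given `seed`.
#'
#' @param vocab character vector of tokens
#' @param dim embedding dimension
#' @param seed integer seed
#' @return an `embedding_matrix` (with reserved rows appended)
#' @export
random_embeddings <- function(vocab, dim, seed = 1L) {
  vecs <- with_seed(seed, matrix(rnorm(length(vocab) * dim) / sqrt(dim),
                                 length(vocab), dim))
  rownames(vecs) <- vocab
  vocab2 <- c(vocab, unknown_token(), padding_token())
  vecs <- rbind(vecs, colMeans(vecs), rep(0, dim))
  rownames(vecs) <- vocab2
  structure(list(vocab = vocab2, vectors = vecs), class = "embedding_matrix")
}

#' Row indices of tokens in an embedding matrix
#'
#' Tokens absent from the vocabulary map to the unknown row.
#'
#' @param emb an `embedding_matrix`
#' @param tokens character vector
#' @return integer vector of row indices (1-based)
#' @export
token_indices <- function(emb, tokens) {
  idx <- match(tokens, emb$vocab)
  idx[is.na(idx)] <- match(unknown_token(), emb$vocab)
  idx
}

#' Embed a token sequence
#'
#' @param emb an `embedding_matrix`
#' @param tokens character vector
#' @return T x e numeric matrix of word vectors
#' @export
embed_tokens <- function(emb, tokens) {
  emb$vectors[token_indices(emb, tokens), , drop = FALSE]
}

#' Build label embeddings from ICD code descriptions
#'
#' Each label's vector is the elementwise mean of the word vectors of its
#' preprocessed description tokens, placing labels in the same space as words
#' (required by the similarity fusion). Labels whose description is entirely
#' out-of-vocabulary fall back to the unknown row. Row order follows `labels`
#' (the canonical label index), so permuting the description table leaves the
#' result unchanged.
#'
#' @param descriptions data.frame from [read_descriptions()]
#' @param emb an `embedding_matrix`
#' @param labels character vector of category roots in canonical order
#'   (defaults to the description table's codes)
#' @param on_missing `"error"` (default) or `"unknown"`: what to do for a
#'   label with no description row
#' @return a `label_embedding_matrix`: list with `labels` and `vectors`
#'   (L x e matrix, rownames = labels)
#' @export
build_label_embeddings <- function(descriptions, emb, labels = NULL,
                                   on_missing = c("error", "unknown")) {
  on_missing <- match.arg(on_missing)
  descriptions <- canonical_cols(descriptions)
  labels <- labels %||% descriptions$code
  e <- ncol(emb$vectors)
  unk_row <- emb$vectors[match(unknown_token(), emb$vocab), ]
  desc <- setNames(descriptions$description, descriptions$code)
  vecs <- matrix(0, length(labels), e, dimnames = list(labels, NULL))
  for (i in seq_along(labels)) {
    d <- if (labels[i] %in% names(desc)) desc[[labels[i]]] else NA
    if (is.na(d)) {
      if (on_missing == "error")
        stop(sprintf("label '%s' has no description", labels[i]))
      warning(sprintf("label '%s' has no description; using unknown row",
                      labels[i]))
      vecs[i, ] <- unk_row
      next
    }
    toks <- tokenize_text(d)
    toks <- toks[toks %in% emb$vocab]
    vecs[i, ] <- if (length(toks)) {
      colMeans(emb$vectors[match(toks, emb$vocab), , drop = FALSE])
    } else unk_row
  }
  structure(list(labels = labels, vectors = vecs),
            class = "label_embedding_matrix")
}
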