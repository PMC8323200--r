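#' Specification for a synthetic clinical corpus
#'
#' The generator emulates the statistical shape of ICD-coded discharge
#' corpora: long multi-label notes, a power-law-skewed label space, and
#' per-code textual signatures mirrored in the code descriptions. Each label
#' owns a disjoint set of signature tokens; its description is built from
#' them (so label-embedding fusion has genuine signal), and notes tagged with
#' the label carry planted signature tokens among Zipf-distributed background
#' tokens (so low-frequency-token filtering is exercised). Real clinical
#' language, abbreviations and misspellings are deliberately out of scope.
#'
#' @param n_labels number of 3-digit codes
#' @param vocab_size total vocabulary size (signatures + background)
#' @param n_notes number of notes
#' @param note_length_mean mean note length in tokens (Poisson); real
#'   discharge summaries average roughly 1500 words, the default of 200 keeps
#'   test corpora small
#' @param labels_per_note_mean mean codes per note (Poisson truncated to
#'   \[1, n_labels\]); about 8, as in real admission-level code sets
#' @param signature_tokens_per_label disjoint signature tokens per label
#' @param signal_insertion_rate probability each signature token of an
#'   assigned label is planted in the note (in (0, 1\]; 1 makes keyword
#'   matching a perfect classifier, the ceiling model training is judged
#'   against)
#' @param popularity_exponent power-law exponent of label popularity
#'   (weight of the i-th label is `i^-exponent`)
#' @param background_zipf_exponent Zipf exponent of background token draws
#' @return a validated `synthetic_spec` list
#' @export
synthetic_spec <- function(n_labels = 50L, vocab_size = 5000L,
                           n_notes = 1000L, note_length_mean = 200L,
                           labels_per_note_mean = 8,
                           signature_tokens_per_label = 3L,
                           signal_insertion_rate = 1.0,
                           popularity_exponent = 1.5,
                           background_zipf_exponent = 1.2) {
  spec <- list(n_labels = as.integer(n_labels),
               vocab_size = as.integer(vocab_size),
               n_notes = as.integer(n_notes),
               note_length_mean = note_length_mean,
               labels_per_note_mean = labels_per_note_mean,
               signature_tokens_per_label =
                 as.integer(signature_tokens_per_label),
               signal_insertion_rate = signal_insertion_rate,
               popularity_exponent = popularity_exponent,
               background_zipf_exponent = background_zipf_exponent)
  num <- vapply(spec, function(x) is.numeric(x) && x > 0, logical(1))
  if (!all(num))
    stop("all synthetic_spec fields must be positive numbers")
  if (spec$signal_insertion_rate > 1)
    stop("signal_insertion_rate must lie in (0, 1]")
  n_sig <- spec$n_labels * spec$signature_tokens_per_label
  if (n_sig >= spec$vocab_size)
    stop(sprintf("vocab too small: %d signature tokens need vocab > %d",
                 n_sig, n_sig))
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic clinical corpus
#'
#' Produces the three tables the corpus readers consume (notes, diagnoses
#' with 4--5 digit ICD-9 codes whose roots are the planted labels, and root
#' descriptions), fully deterministic given `seed`. Diagnosis codes extend
#' each 3-digit root with random extra digits so the rollup step is
#' exercised.
#'
#' @param spec a `synthetic_spec`
#' @param seed integer seed
#' @return list with `notes`, `diagnoses`, `descriptions` (data.frames in
#'   the [read_notes()]/[read_diagnoses()]/[read_descriptions()] schemas),
#'   `vocab`, `labels` and `signatures` (list label -> signature tokens)
#' @export
generate_corpus <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    nl <- spec$n_labels
    s <- spec$signature_tokens_per_label
    vocab <- sprintf("w%05d", seq_len(spec$vocab_size))
    labels <- sprintf("%03d", seq_len(nl))
    signatures <- lapply(seq_len(nl), function(i)
      vocab[(i - 1L) * s + seq_len(s)])
    names(signatures) <- labels
    background <- vocab[(nl * s + 1L):spec$vocab_size]
    bg_w <- seq_along(background)^(-spec$background_zipf_exponent)
    pop_w <- seq_len(nl)^(-spec$popularity_exponent)

    descriptions <- data.frame(
      ICD9_CODE = labels,
      DESCRIPTION = vapply(signatures, paste, character(1), collapse = " "),
      stringsAsFactors = FALSE)

    notes <- vector("list", spec$n_notes)
    diags <- vector("list", spec$n_notes)
    for (n in seq_len(spec$n_notes)) {
      hadm <- sprintf("H%06d", n)
      n_lab <- min(nl, max(1L, rpois(1, spec$labels_per_note_mean)))
      labs <- sort(sample.int(nl, n_lab, prob = pop_w))
      planted <- character(0)
      for (i in labs) {
        keep <- runif(s) < spec$signal_insertion_rate
        planted <- c(planted, signatures[[i]][keep])
      }
      len <- max(rpois(1, spec$note_length_mean), length(planted) + 2L,
                 3L)
      toks <- sample(background, len, replace = TRUE, prob = bg_w)
      if (length(planted))
        toks[sample.int(len, length(planted))] <- planted
      text <- paste(toks, collapse = " ")
      notes[[n]] <- data.frame(SUBJECT_ID = sprintf("S%05d", n),
                               HADM_ID = hadm, TEXT = text,
                               stringsAsFactors = FALSE)
      # extend roots with random digits so the rollup step has work to do
      full <- vapply(labs, function(i) {
        extra <- sample(0:2, 1)
        paste0(labels[i],
               paste(sample(0:9, extra, replace = TRUE), collapse = ""))
      }, character(1))
      diags[[n]] <- data.frame(HADM_ID = hadm, SEQ_NUM = seq_along(labs),
                               ICD9_CODE = full, stringsAsFactors = FALSE)
    }
    list(notes = do.call(rbind, notes),
         diagnoses = do.call(rbind, diags),
         descriptions = descriptions,
         vocab = vocab, labels = labels, signatures = signatures)
  })
}

#' Descriptive statistics of a corpus
#'
#' Exact counts used both to check the generator's targets and to bin labels
#' for the frequency-grouped evaluation. Empty corpora give empty tables.
#'
#' @param notes notes data.frame (schema of [read_notes()] or its output)
#' @param diagnoses diagnoses data.frame
#' @return list with `label_counts` (named vector of 3-digit root counts),
#'   `note_lengths` (words per note), `codes_per_note` (named vector)
#' @export
corpus_stats <- function(notes, diagnoses) {
  text_col <- if ("TEXT" %in% names(notes)) "TEXT" else "text"
  code_col <- if ("ICD9_CODE" %in% names(diagnoses)) "ICD9_CODE"
              else "icd9_code"
  hadm_col <- if ("HADM_ID" %in% names(diagnoses)) "HADM_ID" else "hadm_id"
  label_counts <- if (nrow(diagnoses)) {
    roots <- truncate_icd9(diagnoses[[code_col]])
    tab <- sort(table(roots), decreasing = TRUE)
    setNames(as.integer(tab), names(tab))
  } else setNames(integer(0), character(0))
  note_lengths <- if (nrow(notes)) {
    vapply(notes[[text_col]], function(t) length(tokenize_text(t)),
           numeric(1), USE.NAMES = FALSE)
  } else numeric(0)
  codes_per_note <- if (nrow(diagnoses)) {
    tab <- table(diagnoses[[hadm_col]])
    setNames(as.integer(tab), names(tab))
  } else setNames(integer(0), character(0))
  list(label_counts = label_counts, note_lengths = note_lengths,
       codes_per_note = codes_per_note)
}

#' Keyword-matching ceiling classifier
#'
#' Predicts a label whenever any of its signature tokens occurs in the raw
#' note text. On a corpus generated with `signal_insertion_rate = 1` this is
#' a perfect classifier (micro F1 = 1), the ceiling against which trained
#' models are judged.
#'
#' @param notes notes data.frame
#' @param signatures list label -> signature token vector
#' @return N x L binary prediction matrix (columns in `names(signatures)`
#'   order)
#' @export
keyword_baseline <- function(notes, signatures) {
  text_col <- if ("TEXT" %in% names(notes)) "TEXT" else "text"
  labels <- names(signatures)
  P <- matrix(0, nrow(notes), length(labels),
              dimnames = list(notes[["HADM_ID"]] %||% notes[["hadm_id"]],
                              labels))
  tok_sets <- lapply(notes[[text_col]], function(t) unique(tokenize_text(t)))
  for (l in seq_along(labels))
    P[, l] <- vapply(tok_sets, function(ts)
      as.numeric(any(signatures[[l]] %in% ts)), numeric(1))
  P
}

#' Write a synthetic corpus (plus random embeddings) to disk
#'
#' Emits the same three CSV schemas the corpus readers consume, and a
#' word2vec-text embedding file covering the synthetic vocabulary.
#'
#' @param corpus from [generate_corpus()]
#' @param dir output directory (created if needed)
#' @param embedding_dim dimension of the random embeddings
#' @param seed seed for the embedding draw
#' @return named vector of file paths, invisibly
#' @export
write_corpus_csv <- function(corpus, dir, embedding_dim = 32L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(notes = file.path(dir, "notes.csv"),
             diagnoses = file.path(dir, "diagnoses.csv"),
             descriptions = file.path(dir, "descriptions.csv"),
             embeddings = file.path(dir, "embeddings.vec"))
  utils::write.csv(corpus$notes, paths["notes"], row.names = FALSE)
  utils::write.csv(corpus$diagnoses, paths["diagnoses"], row.names = FALSE)
  utils::write.csv(corpus$descriptions, paths["descriptions"],
                   row.names = FALSE)
  emb <- random_embeddings(corpus$vocab, embedding_dim, seed = seed)
  write_word_vectors(emb, paths["embeddings"])
  invisible(paths)
}
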