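#' Read clinical notes from CSV
#'
#' Reads a notes table (one row per note) with configurable column names, the
#' schema used by MIMIC-style note-event exports. Quoted multi-line text fields
#' are preserved verbatim. Empty note texts are kept but counted in a warning,
#' never dropped silently.
#'
#' @param path CSV file path
#' @param column_map named character vector mapping the canonical roles
#'   `subject_id`, `hadm_id`, `text` to the file's column names
#' @return data.frame with columns `subject_id`, `hadm_id`, `text` in file order
#' @export
read_notes <- function(path,
                       column_map = c(subject_id = "SUBJECT_ID",
                                      hadm_id = "HADM_ID",
                                      text = "TEXT")) {
  df <- read_table_checked(path, column_map,
                           required = c("subject_id", "hadm_id", "text"))
  out <- data.frame(subject_id = df[[column_map[["subject_id"]]]],
                    hadm_id = df[[column_map[["hadm_id"]]]],
                    text = df[[column_map[["text"]]]],
                    stringsAsFactors = FALSE)
  if (any(out$hadm_id == "" | is.na(out$hadm_id)))
    stop("notes table contains empty hadm_id values")
  n_empty <- sum(!nzchar(out$text) | is.na(out$text))
  if (n_empty > 0)
    warning(sprintf("%d note(s) have empty text (kept, flagged)", n_empty))
  out
}

#' Read a diagnosis table from CSV
#'
#' ICD-9 codes are normalised (whitespace and dots stripped, upper-cased) and
#' validated against the ICD-9 shape (`NNN[NN]`, `VNN[NN]`, `ENNN[N]`);
#' malformed codes are rejected with a warning that counts them.
#'
#' @param path CSV file path
#' @param column_map named character vector mapping `hadm_id`, `seq_num`,
#'   `icd9_code` to the file's column names
#' @return data.frame with columns `hadm_id`, `seq_num` (integer), `icd9_code`
#' @export
read_diagnoses <- function(path,
                           column_map = c(hadm_id = "HADM_ID",
                                          seq_num = "SEQ_NUM",
                                          icd9_code = "ICD9_CODE")) {
  df <- read_table_checked(path, column_map,
                           required = c("hadm_id", "seq_num", "icd9_code"))
  code <- normalize_icd9(df[[column_map[["icd9_code"]]]])
  ok <- grepl(icd9_pattern(), code)
  if (any(!ok))
    warning(sprintf("rejected %d record(s) with malformed ICD-9 codes: %s",
                    sum(!ok),
                    paste(utils::head(unique(code[!ok]), 5), collapse = ", ")))
  data.frame(hadm_id = df[[column_map[["hadm_id"]]]][ok],
             seq_num = as.integer(df[[column_map[["seq_num"]]]][ok]),
             icd9_code = code[ok],
             stringsAsFactors = FALSE)
}

#' Read ICD-9 code descriptions
#'
#' Accepts a two-column CSV or TSV (`code`, `description`); the separator is
#' auto-detected from the header line. Codes are normalised like diagnoses.
#'
#' @param path CSV/TSV file path
#' @param column_map named character vector mapping `code` and `description`
#' @return data.frame with columns `code`, `description`, one row per code
#' @export
read_descriptions <- function(path,
                              column_map = c(code = "ICD9_CODE",
                                             description = "DESCRIPTION")) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(unname(column_map), names(df))
  if (length(missing))
    stop(sprintf("missing column(s) in '%s': %s", path,
                 paste(missing, collapse = ", ")))
  out <- data.frame(code = normalize_icd9(df[[column_map[["code"]]]]),
                    description = df[[column_map[["description"]]]],
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$description)))
    stop("description table contains empty descriptions")
  if (anyDuplicated(out$code))
    stop("description table has more than one row for code(s): ",
         paste(unique(out$code[duplicated(out$code)]), collapse = ", "))
  out
}

read_table_checked <- function(path, column_map, required) {
  if (!file.exists(path)) stop(sprintf("cannot read file '%s'", path))
  miss_roles <- setdiff(required, names(column_map))
  if (length(miss_roles))
    stop("column_map must name: ", paste(miss_roles, collapse = ", "))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(unname(column_map[required]), names(df))
  if (length(missing))
    stop(sprintf("missing column(s) in '%s': %s", path,
                 paste(missing, collapse = ", ")))
  df
}

icd9_pattern <- function() "^([0-9]{3,5}|V[0-9]{2,4}|E[0-9]{3,4})$"

# accept both the canonical lowercase schema and the raw CSV schema
canonical_cols <- function(df, map = c(subject_id = "SUBJECT_ID",
                                       hadm_id = "HADM_ID", text = "TEXT",
                                       seq_num = "SEQ_NUM",
                                       icd9_code = "ICD9_CODE",
                                       code = "ICD9_CODE",
                                       description = "DESCRIPTION")) {
  for (canon in names(map)) {
    if (!canon %in% names(df) && map[[canon]] %in% names(df))
      df[[canon]] <- df[[map[[canon]]]]
  }
  df
}

normalize_icd9 <- function(code) toupper(gsub("[.[:space:]]", "", code))

#' Roll an ICD-9 code up to its 3-digit category root
#'
#' Numeric codes keep their first three characters; under the ICD-9-CM category
#' convention V-codes keep `V` plus two digits and E-codes keep `E` plus three
#' digits (a literal first-three-characters scheme would merge distinct E
#' categories). Vectorised.
#'
#' @param code character vector of (normalised or raw) ICD-9 codes
#' @param scheme `"icd9cm"` (default, category convention) or `"first3"`
#'   (literal first three characters)
#' @return character vector of category roots
#' @examples
#' truncate_icd9(c("45829", "486", "V4501", "E9342"))
#' @export
truncate_icd9 <- function(code, scheme = c("icd9cm", "first3")) {
  scheme <- match.arg(scheme)
  code <- normalize_icd9(code)
  bad <- !grepl(icd9_pattern(), code)
  if (any(bad))
    stop("non-conforming ICD-9 code(s): ",
         paste(utils::head(unique(code[bad]), 5), collapse = ", "))
  if (scheme == "first3") return(substr(code, 1L, 3L))
  ifelse(startsWith(code, "E"), substr(code, 1L, 4L), substr(code, 1L, 3L))
}

#' Built-in English stopword list
#'
#' A compact list of common English function words used as the default
#' stopword set; fully replaceable by the caller.
#'
#' @return character vector
#' @export
english_stopwords <- function() {
  c("a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "could", "did",
    "do", "does", "doing", "down", "during", "each", "few", "for", "from",
    "further", "had", "has", "have", "having", "he", "her", "here", "hers",
    "him", "his", "how", "i", "if", "in", "into", "is", "it", "its", "itself",
    "just", "me", "more", "most", "my", "no", "nor", "not", "now", "of",
    "off", "on", "once", "only", "or", "other", "our", "ours", "out", "over",
    "own", "same", "she", "should", "so", "some", "such", "than", "that",
    "the", "their", "theirs", "them", "then", "there", "these", "they",
    "this", "those", "through", "to", "too", "under", "until", "up", "very",
    "was", "we", "were", "what", "when", "where", "which", "while", "who",
    "whom", "why", "will", "with", "would", "you", "your", "yours")
}

# lowercase + strip punctuation -> token vector
tokenize_text <- function(text) {
  text <- tolower(text)
  text <- gsub("[^a-z0-9]+", " ", text)
  toks <- strsplit(trimws(text), " +")[[1]]
  toks[nzchar(toks)]
}

#' Corpus-level token frequencies
#'
#' @param texts character vector of raw note texts
#' @return named integer vector of token counts after basic tokenisation
#' @export
token_frequencies <- function(texts) {
  toks <- unlist(lapply(texts, tokenize_text), use.names = FALSE)
  if (!length(toks)) return(setNames(integer(0), character(0)))
  tab <- table(toks)
  setNames(as.integer(tab), names(tab))
}

#' Reserved unknown / padding token strings
#' @name reserved-tokens
#' @return single string
#' @export
unknown_token <- function() "<unk>"

#' @rdname reserved-tokens
#' @export
padding_token <- function() "<pad>"

#' Preprocess one note's text into a token sequence
#'
#' Lower-cases, strips punctuation, removes stopwords, replaces tokens whose
#' corpus frequency is below `min_token_freq` with the reserved unknown token,
#' and truncates to `max_len`. Order of surviving tokens is preserved. An
#' empty result is allowed.
#'
#' @param text single character string
#' @param stopwords character vector of stopwords to drop
#' @param token_counts named integer vector of corpus token frequencies
#'   (required when `min_token_freq > 1`, see [token_frequencies()])
#' @param min_token_freq minimum corpus frequency for a token to be kept as
#'   itself (default 3); rarer tokens become the unknown token
#' @param max_len maximum sequence length (default 2500; notes in this domain
#'   average roughly 1500 words)
#' @return character vector of tokens
#' @export
preprocess_text <- function(text, stopwords = english_stopwords(),
                            token_counts = NULL, min_token_freq = 3L,
                            max_len = 2500L) {
  toks <- tokenize_text(text)
  if (length(stopwords)) toks <- toks[!toks %in% stopwords]
  if (min_token_freq > 1L) {
    if (is.null(token_counts))
      stop("token_counts is required when min_token_freq > 1")
    cnt <- token_counts[toks]
    cnt[is.na(cnt)] <- 0L
    toks[cnt < min_token_freq] <- unknown_token()
  }
  if (length(toks) > max_len) toks <- toks[seq_len(max_len)]
  toks
}

#' Select the label space: the k most frequent category roots
#'
#' Ties are broken lexicographically; the returned order is the canonical
#' label index used everywhere downstream. Invariant to the iteration order of
#' `code_counts`.
#'
#' @param code_counts named numeric vector, category root -> count
#' @param k number of labels to keep
#' @return character vector of k roots, descending count
#' @export
select_label_space <- function(code_counts, k) {
  if (k > length(code_counts))
    stop(sprintf("k (%d) exceeds the number of distinct roots (%d)",
                 k, length(code_counts)))
  ord <- order(-as.numeric(code_counts), names(code_counts),
               method = "radix")
  names(code_counts)[ord][seq_len(k)]
}

#' Count 3-digit category roots in a diagnosis table
#'
#' @param diagnoses data.frame from [read_diagnoses()]
#' @param scheme rollup scheme passed to [truncate_icd9()]
#' @return named integer vector root -> record count
#' @export
code_root_counts <- function(diagnoses, scheme = "icd9cm") {
  diagnoses <- canonical_cols(diagnoses)
  roots <- truncate_icd9(diagnoses$icd9_code, scheme = scheme)
  tab <- table(roots)
  setNames(as.integer(tab), names(tab))
}

#' Tokenize a corpus of notes and attach gold label sets
#'
#' Runs [preprocess_text()] over every note with corpus-level frequencies,
#' rolls the diagnosis codes up to roots, filters them to `label_space`, and
#' drops notes whose gold set becomes empty (with a message counting them,
#' never silently). Notes with empty token sequences are kept and flagged.
#'
#' @param notes data.frame from [read_notes()]
#' @param diagnoses data.frame from [read_diagnoses()]
#' @param label_space character vector of selected roots (canonical order)
#' @param stopwords,min_token_freq,max_len see [preprocess_text()]
#' @param scheme rollup scheme for [truncate_icd9()]
#' @return list of tokenized notes, each `list(hadm_id, tokens, codes)`,
#'   class `tokenized_corpus`
#' @export
tokenize_corpus <- function(notes, diagnoses, label_space,
                            stopwords = english_stopwords(),
                            min_token_freq = 3L, max_len = 2500L,
                            scheme = "icd9cm") {
  notes <- canonical_cols(notes)
  diagnoses <- canonical_cols(diagnoses)
  counts <- token_frequencies(notes$text)
  roots <- truncate_icd9(diagnoses$icd9_code, scheme = scheme)
  codes_by_hadm <- split(roots, diagnoses$hadm_id)
  out <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    hadm <- notes$hadm_id[i]
    codes <- intersect(unique(codes_by_hadm[[hadm]]), label_space)
    toks <- preprocess_text(notes$text[i], stopwords = stopwords,
                            token_counts = counts,
                            min_token_freq = min_token_freq,
                            max_len = max_len)
    out[[i]] <- list(hadm_id = hadm, tokens = toks, codes = codes)
  }
  empty_codes <- vapply(out, function(n) length(n$codes) == 0L, logical(1))
  if (any(empty_codes))
    message(sprintf("dropped %d note(s) with no gold codes in the label space",
                    sum(empty_codes)))
  out <- out[!empty_codes]
  n_empty_tok <- sum(vapply(out, function(n) length(n$tokens) == 0L,
                            logical(1)))
  if (n_empty_tok > 0)
    message(sprintf("%d note(s) have empty token sequences (kept, flagged)",
                    n_empty_tok))
  structure(out, class = "tokenized_corpus")
}

#' Split a corpus into train / validation / test sets
#'
#' Deterministic given `seed`; the partition is exhaustive and disjoint by
#' note. Sizes are `round(n * ratios[1:2])` with the remainder going to test,
#' so each fraction is within one note of its target.
#'
#' @param notes list of tokenized notes (or any list)
#' @param ratios length-3 numeric summing to 1
#' @param seed integer seed
#' @return list with elements `train`, `valid`, `test`, `seed`, class
#'   `dataset_split`
#' @export
split_dataset <- function(notes, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be three fractions summing to 1")
  n <- length(notes)
  perm <- with_seed(seed, sample.int(n))
  n1 <- round(n * ratios[1])
  n2 <- round(n * ratios[2])
  if (n1 + n2 > n) n2 <- n - n1
  idx_train <- perm[seq_len(n1)]
  idx_valid <- perm[seq_len(n2) + n1]
  idx_test <- perm[setdiff(seq_len(n), seq_len(n1 + n2))]
  structure(list(train = notes[idx_train],
                 valid = notes[idx_valid],
                 test = notes[idx_test],
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' Serialize / read a tokenized corpus as JSON-lines
#'
#' One JSON object per line with fields `hadm_id`, `tokens`, `codes`, so a
#' processed corpus can be reused across runs.
#'
#' @param corpus list of tokenized notes
#' @param path output file
#' @return `path`, invisibly (writer); the corpus (reader)
#' @export
write_tokenized_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(n) {
    jsonlite::toJSON(list(hadm_id = n$hadm_id,
                          tokens = n$tokens,
                          codes = n$codes),
                     auto_unbox = FALSE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tokenized_corpus
#' @export
read_tokenized_corpus <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    list(hadm_id = as.character(x$hadm_id)[1],
         tokens = as.character(x$tokens),
         codes = as.character(x$codes))
  })
  structure(out, class = "tokenized_corpus")
}
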