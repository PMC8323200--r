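test_that("read_notes preserves rows, order and multi-line quoted text", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(SUBJECT_ID = c("s1", "s2"), HADM_ID = c("h1", "h2"),
                   TEXT = c("chest pain", "line one\nline two, with comma"))
  write.csv(df, f, row.names = FALSE)
  notes <- read_notes(f)
  expect_equal(nrow(notes), 2)
  expect_equal(notes$hadm_id, c("h1", "h2"))
  expect_equal(notes$text[2], "line one\nline two, with comma")
})

test_that("read_notes reports missing columns by name and flags empty text", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(SUBJECT_ID = "s1", TEXT = "x"), f, row.names = FALSE)
  expect_error(read_notes(f), "HADM_ID")
  write.csv(data.frame(SUBJECT_ID = "s1", HADM_ID = "h1", TEXT = ""), f,
            row.names = FALSE)
  expect_warning(read_notes(f), "empty text")
  expect_error(read_notes(tempfile()), "cannot read")
})

test_that("read_diagnoses normalises codes and rejects malformed ones", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(HADM_ID = c("h1", "h1", "h2"),
                       SEQ_NUM = c(1, 2, 1),
                       ICD9_CODE = c(" 486. ", "45.829", "BAD!!")), f,
            row.names = FALSE)
  expect_warning(d <- read_diagnoses(f), "malformed")
  expect_equal(d$icd9_code, c("486", "45829"))
  expect_equal(d$seq_num, c(1L, 2L))
})

test_that("read_descriptions keeps ICD-9 category descriptions verbatim", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(ICD9_CODE = c("001", "003"),
                       DESCRIPTION = c("Cholera",
                                       "Other salmonella inflections")), f,
            row.names = FALSE)
  d <- read_descriptions(f)
  expect_equal(d$description[d$code == "001"], "Cholera")
  expect_equal(d$description[d$code == "003"],
               "Other salmonella inflections")
  # two-column TSV dialect
  ft <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ICD9_CODE\tDESCRIPTION", "002\tTyphoid and paratyphoid fevers"),
             ft)
  expect_equal(read_descriptions(ft)$description,
               "Typhoid and paratyphoid fevers")
  writeLines(c("ICD9_CODE,DESCRIPTION", "001,a", "001,b"), f)
  expect_error(read_descriptions(f), "more than one row")
})

test_that("truncate_icd9 follows the ICD-9-CM category rollup convention", {
  expect_equal(truncate_icd9("45829"), "458")
  expect_equal(truncate_icd9("486"), "486")
  expect_equal(truncate_icd9("V4501"), "V45")
  expect_equal(truncate_icd9("E9342"), "E934")
  expect_equal(truncate_icd9("E9342", scheme = "first3"), "E93")
  expect_error(truncate_icd9("XYZ"), "non-conforming")
})

test_that("rollup is idempotent over random valid codes", {
  codes <- with_seed(5, c(
    sprintf("%03d%s", sample(999, 30), sample(c("", "1", "42"), 30, TRUE)),
    sprintf("V%02d%s", sample(99, 10), sample(c("", "0", "11"), 10, TRUE)),
    sprintf("E%03d%s", sample(999, 10), sample(c("", "4"), 10, TRUE))))
  once <- truncate_icd9(codes)
  expect_identical(truncate_icd9(once), once)
})

test_that("preprocess_text lowercases, strips punctuation and stopwords", {
  expect_equal(preprocess_text("Chest pain, chest pain.", stopwords = NULL,
                               min_token_freq = 1),
               c("chest", "pain", "chest", "pain"))
  expect_equal(preprocess_text("Chest pain, chest pain.",
                               stopwords = "pain", min_token_freq = 1),
               c("chest", "chest"))
})

test_that("rare tokens map to the unknown token via corpus frequencies", {
  corpus <- c("the zygote", "cell cell cell", "cell membrane membrane")
  counts <- token_frequencies(corpus)
  expect_equal(unname(counts["cell"]), 4L)
  toks <- preprocess_text("zygote cell", stopwords = NULL,
                          token_counts = counts, min_token_freq = 2)
  expect_equal(toks, c(unknown_token(), "cell"))
  expect_error(preprocess_text("x", stopwords = NULL, min_token_freq = 2),
               "token_counts")
  # order preservation and truncation
  long <- paste(rep(c("alpha", "beta"), 10), collapse = " ")
  out <- preprocess_text(long, stopwords = NULL, min_token_freq = 1,
                         max_len = 5)
  expect_equal(out, c("alpha", "beta", "alpha", "beta", "alpha"))
})

test_that("select_label_space ranks by count with lexicographic ties", {
  expect_equal(select_label_space(c("458" = 5, "427" = 3, "276" = 1), 2),
               c("458", "427"))
  expect_equal(select_label_space(c(B = 2, A = 2), 1), "A")
  expect_error(select_label_space(c(A = 1), 2), "exceeds")
  counts <- with_seed(9, setNames(sample(30, 50, TRUE),
                                  sprintf("%03d", sample(999, 50))))
  got <- select_label_space(counts, 20)
  ord <- order(-counts, names(counts))
  expect_equal(got, names(counts)[ord][1:20])
  # invariance to iteration order
  shuf <- with_seed(2, counts[sample(length(counts))])
  expect_equal(select_label_space(shuf, 20), got)
})

test_that("split_dataset is a deterministic exhaustive disjoint partition", {
  notes <- as.list(seq_len(10))
  sp <- split_dataset(notes, seed = 0)
  expect_equal(lengths(sp[c("train", "valid", "test")]),
               c(train = 7L, valid = 1L, test = 2L))
  expect_identical(split_dataset(notes, seed = 0)[1:3], sp[1:3])
  notes <- as.list(seq_len(1000))
  sp <- split_dataset(notes, seed = 4)
  all_ids <- unlist(sp[c("train", "valid", "test")])
  expect_setequal(all_ids, seq_len(1000))
  expect_equal(length(all_ids), 1000)
  expect_error(split_dataset(notes, ratios = c(0.5, 0.2, 0.2)), "sum")
})

test_that("tokenize_corpus filters codes and drops label-free notes loudly", {
  prep <- tiny_prepared_corpus(n_notes = 30)
  tc <- prep$tokenized
  expect_true(all(vapply(tc, function(n)
    all(n$codes %in% prep$labels), logical(1))))
  # restricting the label space drops notes with a message, not silently
  lab1 <- prep$labels[1]
  expect_message(
    tc1 <- tokenize_corpus(prep$corpus$notes, prep$corpus$diagnoses, lab1,
                           min_token_freq = 1),
    "dropped")
  expect_true(all(vapply(tc1, function(n) identical(n$codes, lab1),
                         logical(1))))
})

test_that("tokenized corpora round-trip through JSON-lines", {
  tc <- tiny_prepared_corpus(n_notes = 12)$tokenized
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_tokenized_corpus(tc, f)
  back <- read_tokenized_corpus(f)
  expect_equal(length(back), length(tc))
  for (i in seq_along(tc)) {
    expect_equal(back[[i]]$tokens, tc[[i]]$tokens)
    expect_equal(back[[i]]$codes, tc[[i]]$codes)
  }
})
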