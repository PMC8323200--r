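test_that("the generator is deterministic and validates its spec", {
  spec <- synthetic_spec(n_labels = 5, vocab_size = 100, n_notes = 20,
                         note_length_mean = 40)
  c1 <- generate_corpus(spec, seed = 3)
  c2 <- generate_corpus(spec, seed = 3)
  expect_identical(c1$notes, c2$notes)
  expect_identical(c1$diagnoses, c2$diagnoses)
  c3 <- generate_corpus(spec, seed = 4)
  expect_false(identical(c1$notes$TEXT, c3$notes$TEXT))
  expect_error(synthetic_spec(n_labels = 50, vocab_size = 100,
                              signature_tokens_per_label = 3),
               "vocab too small")
  expect_error(synthetic_spec(signal_insertion_rate = 1.5), "signal")
})

test_that("full insertion guarantees every signature token of every label", {
  spec <- synthetic_spec(n_labels = 4, vocab_size = 60, n_notes = 30,
                         note_length_mean = 50, signal_insertion_rate = 1)
  corp <- generate_corpus(spec, seed = 7)
  roots <- truncate_icd9(corp$diagnoses$ICD9_CODE)
  for (n in seq_len(nrow(corp$notes))) {
    hadm <- corp$notes$HADM_ID[n]
    toks <- strsplit(corp$notes$TEXT[n], " ")[[1]]
    for (lab in roots[corp$diagnoses$HADM_ID == hadm])
      expect_true(all(corp$signatures[[lab]] %in% toks))
  }
  # background never emits signature tokens, so keyword matching is exact
  sig_all <- unlist(corp$signatures)
  for (n in seq_len(nrow(corp$notes))) {
    hadm <- corp$notes$HADM_ID[n]
    toks <- strsplit(corp$notes$TEXT[n], " ")[[1]]
    labs <- unique(roots[corp$diagnoses$HADM_ID == hadm])
    stray <- setdiff(intersect(toks, sig_all),
                     unlist(corp$signatures[labs]))
    expect_length(stray, 0)
  }
})

test_that("keyword matching reaches the identifiability ceiling", {
  spec <- synthetic_spec(n_labels = 6, vocab_size = 150, n_notes = 100,
                         note_length_mean = 60, signal_insertion_rate = 1)
  corp <- generate_corpus(spec, seed = 5)
  pred <- keyword_baseline(corp$notes, corp$signatures)
  gold <- matrix(0, nrow(corp$notes), 6,
                 dimnames = list(corp$notes$HADM_ID, corp$labels))
  roots <- truncate_icd9(corp$diagnoses$ICD9_CODE)
  for (i in seq_len(nrow(corp$diagnoses)))
    gold[corp$diagnoses$HADM_ID[i], roots[i]] <- 1
  expect_equal(micro_f1(gold, pred), 1.0)
})

test_that("label popularity is power-law skewed", {
  spec <- synthetic_spec(n_labels = 40, vocab_size = 400, n_notes = 2000,
                         note_length_mean = 30, labels_per_note_mean = 4,
                         popularity_exponent = 1.5)
  corp <- generate_corpus(spec, seed = 1)
  stats <- corpus_stats(corp$notes, corp$diagnoses)
  counts <- stats$label_counts[corp$labels]
  counts[is.na(counts)] <- 0
  total <- sum(counts)
  top10 <- sum(sort(counts, decreasing = TRUE)[1:10]) / total
  bottom10 <- sum(sort(counts)[1:10]) / total
  expect_gt(top10, 2 * 10 / 40)    # far above the uniform share
  expect_lt(bottom10, 0.5 * 10 / 40)
  # popularity ranks follow the configured order on the common labels
  expect_gt(counts["001"], counts["020"])
})

test_that("corpus statistics are exact counts", {
  notes <- data.frame(HADM_ID = c("h1", "h2", "h3"),
                      SUBJECT_ID = c("s1", "s2", "s3"),
                      TEXT = c("a b", "a b c", "a b c d"))
  diags <- data.frame(HADM_ID = rep(c("h1", "h2", "h3"), times = c(2, 3, 4)),
                      SEQ_NUM = c(1:2, 1:3, 1:4),
                      ICD9_CODE = c("0011", "002", "0031", "004", "00512",
                                    "001", "002", "003", "004"))
  st <- corpus_stats(notes, diags)
  expect_equal(mean(st$codes_per_note), 3)
  expect_equal(st$note_lengths, c(2, 3, 4))
  expect_equal(unname(st$label_counts[c("001", "002")]), c(2L, 2L))
  empty <- corpus_stats(notes[0, ], diags[0, ])
  expect_length(empty$label_counts, 0)
  expect_length(empty$note_lengths, 0)
})

test_that("generated tables agree with the generator's own bookkeeping", {
  spec <- synthetic_spec(n_labels = 5, vocab_size = 100, n_notes = 50,
                         note_length_mean = 40)
  corp <- generate_corpus(spec, seed = 9)
  st <- corpus_stats(corp$notes, corp$diagnoses)
  # every diagnosis root is a generated label; descriptions cover all labels
  expect_true(all(names(st$label_counts) %in% corp$labels))
  expect_setequal(corp$descriptions$ICD9_CODE, corp$labels)
  # each description is that label's signature tokens
  for (i in seq_len(nrow(corp$descriptions))) {
    lab <- corp$descriptions$ICD9_CODE[i]
    expect_equal(strsplit(corp$descriptions$DESCRIPTION[i], " ")[[1]],
                 corp$signatures[[lab]])
  }
  expect_true(all(st$codes_per_note >= 1))
})

test_that("relabeling labels and signatures together changes no metric", {
  spec <- synthetic_spec(n_labels = 4, vocab_size = 80, n_notes = 60,
                         note_length_mean = 40)
  corp <- generate_corpus(spec, seed = 2)
  gold <- matrix(0, nrow(corp$notes), 4,
                 dimnames = list(corp$notes$HADM_ID, corp$labels))
  roots <- truncate_icd9(corp$diagnoses$ICD9_CODE)
  for (i in seq_len(nrow(corp$diagnoses)))
    gold[corp$diagnoses$HADM_ID[i], roots[i]] <- 1
  pred <- keyword_baseline(corp$notes, corp$signatures)
  perm <- c(3, 1, 4, 2)
  expect_equal(micro_f1(gold[, perm], pred[, perm]), micro_f1(gold, pred))
  expect_equal(macro_f1(gold[, perm], pred[, perm]), macro_f1(gold, pred))
})
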