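test_that("micro and macro F1 agree with counting oracles", {
  gold <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(micro_f1(gold, gold), 1.0)
  expect_equal(macro_f1(gold, gold), 1.0)
  # 2 gold positives, 2 predicted, 1 overlapping -> micro F1 = 0.5
  gold2 <- matrix(c(1, 1, 0, 0), 1, 4)
  pred2 <- matrix(c(1, 0, 1, 0), 1, 4)
  expect_equal(micro_f1(gold2, pred2), 0.5)
  for (s in 1:50) {
    gold <- with_seed(s, matrix(rbinom(200, 1, 0.3), 20, 10))
    pred <- with_seed(s + 500, matrix(rbinom(200, 1, 0.3), 20, 10))
    expect_equal(micro_f1(gold, pred), micro_f1_oracle(gold, pred),
                 tolerance = 1e-12)
    expect_equal(macro_f1(gold, pred), macro_f1_oracle(gold, pred),
                 tolerance = 1e-12)
  }
  expect_error(micro_f1(gold, pred[, 1:5]), "shape")
})

test_that("F1 metrics are invariant to joint row permutation", {
  gold <- with_seed(1, matrix(rbinom(100, 1, 0.4), 10, 10))
  pred <- with_seed(2, matrix(rbinom(100, 1, 0.4), 10, 10))
  perm <- with_seed(3, sample(10))
  expect_equal(micro_f1(gold[perm, ], pred[perm, ]), micro_f1(gold, pred))
  expect_equal(macro_f1(gold[perm, ], pred[perm, ]), macro_f1(gold, pred))
})

test_that("macro F1 equals micro F1 under identical per-label confusions", {
  # every label: 1 TP, 1 FP, 1 FN over three notes
  gold <- rbind(c(1, 1), c(1, 1), c(0, 0))
  pred <- rbind(c(1, 1), c(0, 0), c(1, 1))
  expect_equal(macro_f1(gold, pred), micro_f1(gold, pred))
})

test_that("top-10 recall follows the max(10, |M|) definition", {
  # |M| = 3, all three gold in the top 10 of 12 labels
  scores <- matrix(seq(0.95, 0.2, length.out = 12), 1, 12)
  gold <- matrix(0, 1, 12); gold[1, c(1, 3, 5)] <- 1
  expect_equal(top10_recall(scores, gold), 1.0)
  # |M| = 12 with exactly 6 gold codes inside the top 12 of 20
  L <- 20
  scores <- matrix(0, 1, L)
  scores[1, 1:12] <- seq(1, 0.5, length.out = 12)    # the top-12 ranks
  scores[1, 13:20] <- seq(0.4, 0.1, length.out = 8)
  gold <- matrix(0, 1, L)
  gold[1, c(1:6, 13:18)] <- 1                        # 6 in, 6 out
  expect_equal(top10_recall(scores, gold),
               top10_recall_oracle(scores, gold))
  expect_equal(top10_recall(scores, gold), 0.5)
  # empty gold sets are excluded with a warning
  gold2 <- rbind(gold, 0)
  scores2 <- rbind(scores, scores)
  expect_warning(r <- top10_recall(scores2, gold2), "empty gold")
  expect_equal(r, 0.5)
})

test_that("tied scores resolve by label order, matching the oracle", {
  scores <- matrix(0.5, 3, 15)
  gold <- with_seed(4, matrix(rbinom(45, 1, 0.4), 3, 15))
  gold[rowSums(gold) == 0, 1] <- 1
  expect_equal(top10_recall(scores, gold), top10_recall_oracle(scores, gold))
})

test_that("top-10 recall is invariant under monotone score transforms", {
  scores <- with_seed(5, matrix(runif(300), 20, 15))
  gold <- with_seed(6, matrix(rbinom(300, 1, 0.3), 20, 15))
  gold[rowSums(gold) == 0, 1] <- 1
  base <- top10_recall(scores, gold)
  expect_equal(top10_recall(scores^3, gold), base)
  expect_equal(top10_recall(1 / (1 + exp(-7 * scores)), gold), base)
})

test_that("per-label AUC matches the all-pairs oracle and pROC", {
  for (s in 1:10) {
    x <- with_seed(s, round(runif(40), 2)) # rounding forces ties
    y <- with_seed(s + 50, rbinom(40, 1, 0.4))
    if (sum(y) %in% c(0, 40)) y[1] <- 1 - y[1]
    expect_equal(label_auc(x, y), auc_pairs_oracle(x, y), tolerance = 1e-12)
  }
  x <- with_seed(99, runif(60)); y <- with_seed(98, rbinom(60, 1, 0.5))
  expect_equal(label_auc(x, y),
               as.numeric(pROC::auc(pROC::roc(y, x, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
  # perfect separation and the complement identity
  expect_equal(label_auc(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(label_auc(-x, y), 1 - label_auc(x, y), tolerance = 1e-12)
  expect_true(is.na(label_auc(x, rep(1, 60))))
})

test_that("random scores give AUC near one half", {
  x <- with_seed(7, runif(4000))
  y <- with_seed(8, rbinom(4000, 1, 0.5))
  expect_equal(label_auc(x, y), 0.5, tolerance = 0.05)
})

test_that("grouped macro AUC bins labels by training frequency", {
  L <- 8
  scores <- with_seed(9, matrix(runif(50 * L), 50, L,
                                dimnames = list(NULL, paste0("l", 1:L))))
  gold <- with_seed(10, matrix(rbinom(50 * L, 1, 0.4), 50, L,
                               dimnames = list(NULL, paste0("l", 1:L))))
  gold[, 8] <- 1 # degenerate label, must be skipped with a warning
  counts <- setNames(c(3, 7, 20, 40, 60, 90, 200, 5), paste0("l", 1:L))
  expect_warning(g <- macro_auc_by_group(scores, gold, counts), "degenerate")
  expect_setequal(names(g), c("[1,10]", "[11,50]", "[51,100]", "[101,Inf]"))
  aucs <- vapply(1:7, function(l) label_auc(scores[, l], gold[, l]),
                 numeric(1))
  expect_equal(unname(g["[1,10]"]), mean(aucs[c(1, 2)])) # l8 skipped
  expect_equal(unname(g["[11,50]"]), mean(aucs[c(3, 4)]))
  expect_equal(unname(g["[101,Inf]"]), aucs[7])
  # an emptied group is absent, not zero
  counts2 <- counts; counts2[c(3, 4)] <- 1
  expect_warning(g2 <- macro_auc_by_group(scores, gold, counts2))
  expect_false("[11,50]" %in% names(g2))
})

test_that("frequency bins must tile the counts", {
  b <- frequency_bins()
  expect_equal(nrow(b), 4)
  expect_error(frequency_bins(c(1, 10), c(12, 50)), "non-overlapping")
  expect_error(frequency_bins(c(5, 1), c(10, 4)), "non-overlapping")
})

test_that("error breakdown tallies FP/FN and confused code pairs", {
  labels <- c("007", "008", "042")
  gold <- matrix(0, 1, 3, dimnames = list(NULL, labels))
  pred <- gold
  gold[1, "007"] <- 1
  pred[1, "008"] <- 1
  eb <- error_breakdown(gold, pred, c("007" = 19, "008" = 579, "042" = 10))
  expect_equal(eb$per_label$fp[eb$per_label$label == "008"], 1L)
  expect_equal(eb$per_label$fn[eb$per_label$label == "007"], 1L)
  expect_equal(eb$confused_pairs$gold, "007")
  expect_equal(eb$confused_pairs$pred, "008")
  expect_true(eb$confused_pairs$similar) # shared "00" prefix
  # perfect predictions leave everything at zero
  eb0 <- error_breakdown(gold, gold, c("007" = 19, "008" = 579, "042" = 10))
  expect_true(all(eb0$per_label$fp == 0) && all(eb0$per_label$fn == 0))
  expect_equal(nrow(eb0$confused_pairs), 0)
  # random instance against a counting oracle
  gold <- with_seed(11, matrix(rbinom(60, 1, 0.4), 20, 3,
                               dimnames = list(NULL, labels)))
  pred <- with_seed(12, matrix(rbinom(60, 1, 0.4), 20, 3,
                               dimnames = list(NULL, labels)))
  eb <- error_breakdown(gold, pred, c("007" = 1, "008" = 1, "042" = 1))
  expect_equal(eb$per_label$fp, unname(colSums(gold == 0 & pred == 1)))
  expect_equal(eb$per_label$fn, unname(colSums(gold == 1 & pred == 0)))
})

test_that("metrics reports assemble and serialize", {
  L <- 6
  scores <- with_seed(13, matrix(runif(30 * L), 30, L,
                                 dimnames = list(NULL, paste0("l", 1:L))))
  gold <- with_seed(14, matrix(rbinom(30 * L, 1, 0.5), 30, L,
                               dimnames = list(NULL, paste0("l", 1:L))))
  gold[rowSums(gold) == 0, 1] <- 1
  counts <- setNames(c(2, 15, 55, 120, 8, 70), paste0("l", 1:L))
  rep <- metrics_report(scores, gold, counts, test_loss = 0.31,
                        loss_mode = "sigmoid-bce")
  expect_s3_class(rep, "metrics_report")
  expect_true(all(c(rep$micro_f1, rep$macro_f1, rep$top10_recall) >= 0))
  f <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$micro_f1, rep$micro_f1, tolerance = 1e-12)
  expect_equal(back$decision_policy$policy, "threshold")
  expect_output(print(rep), "micro F1")
})
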