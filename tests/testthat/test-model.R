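test_that("model builds are deterministic and score in [0, 1]", {
  m1 <- tiny_model(seed = 7)
  m2 <- tiny_model(seed = 7)
  expect_identical(m1$params, m2$params)
  m3 <- tiny_model(seed = 8)
  expect_false(identical(m1$params, m3$params))
  toks <- with_seed(1, sample(tiny_vocab(), 9))
  s <- predict_scores(m1, list(toks))
  expect_equal(dim(s), c(1, 3))
  expect_true(all(is.finite(s)) && all(s >= 0 & s <= 1))
})

test_that("the C++ engine reproduces the chained module functions", {
  combos <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE),
                 c(FALSE, TRUE))
  for (cb in combos) {
    m <- tiny_model(seed = 13, bilstm = cb[1], label_fusion = cb[2])
    for (s in 1:3) {
      toks <- with_seed(s, sample(tiny_vocab(), sample(4:12, 1)))
      expect_equal(as.numeric(predict_scores(m, list(toks))),
                   icdcaps:::forward_note_reference(m, toks),
                   tolerance = 1e-12)
    }
  }
  # softmax-ce output mode
  m <- tiny_model(seed = 14, loss_mode = "softmax-ce")
  toks <- with_seed(4, sample(tiny_vocab(), 8))
  s <- predict_scores(m, list(toks))
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_equal(as.numeric(s), icdcaps:::forward_note_reference(m, toks),
               tolerance = 1e-12)
})

test_that("backpropagation matches central finite differences", {
  m <- tiny_model(seed = 21)
  toks <- with_seed(5, list(sample(tiny_vocab(), 8),
                            sample(tiny_vocab(), 6)))
  ids <- icdcaps:::note_token_ids(m, toks)
  Y <- rbind(c(1, 0, 1), c(0, 1, 0))
  ec <- icdcaps:::engine_cfg(m)
  loss_at <- function(p)
    icdcaps:::cpp_run_batch(ids, Y, p, m$emb$vectors, m$Gv,
                            m$label_emb$vectors, ec, FALSE, FALSE)$loss_sum
  res <- icdcaps:::cpp_run_batch(ids, Y, m$params, m$emb$vectors, m$Gv,
                                 m$label_emb$vectors, ec, TRUE, FALSE)
  h <- 1e-6
  for (nm in names(m$params)) {
    idx <- with_seed(match(nm, names(m$params)),
                     sample(length(m$params[[nm]]),
                            min(3, length(m$params[[nm]]))))
    for (i in idx) {
      p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + h
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - h
      fd <- (loss_at(p1) - loss_at(p2)) / (2 * h)
      an <- res$grads[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd), abs(an)), 1e-4)
    }
  }
})

test_that("disabling fusion equals zeroing the label embeddings, bit for bit", {
  m_off <- tiny_model(seed = 7, label_fusion = FALSE)
  m_zero <- tiny_model(seed = 7)
  m_zero$label_emb$vectors[] <- 0
  m_zero$Gv[] <- 0
  toks <- with_seed(6, lapply(1:4, function(i) sample(tiny_vocab(), 10)))
  expect_identical(as.numeric(predict_scores(m_off, toks)),
                   as.numeric(predict_scores(m_zero, toks)))
})

test_that("training is deterministic, improves loss, and lr = 0 is identity", {
  prep <- tiny_prepared_corpus()
  emb <- random_embeddings(prep$corpus$vocab, 8, seed = 2)
  le <- build_label_embeddings(prep$corpus$descriptions, emb,
                               labels = prep$labels)
  cfg <- model_config(e = 8, hidden_units = 4, capsule_dim = 4,
                      routing_iters = 2, K1 = 2, n_filters = 4,
                      channels = 2, seed = 5, batch_size = 8)
  m <- build_model(cfg, emb, le)
  m0 <- train_model(m, prep$split, max_epochs = 1, early_stopping = FALSE,
                    learning_rate = 0)
  expect_equal(m0$params, m$params, tolerance = 1e-15)
  expect_equal(nrow(m0$history), 1)
  mt1 <- train_model(m, prep$split, max_epochs = 3, early_stopping = FALSE)
  mt2 <- train_model(m, prep$split, max_epochs = 3, early_stopping = FALSE)
  expect_identical(predict_scores(mt1, prep$split$test),
                   predict_scores(mt2, prep$split$test))
  expect_lt(mt1$history$train_loss[3], mt1$history$train_loss[1])
})

test_that("ablation flags drop the corresponding computation paths", {
  prep <- tiny_prepared_corpus(n_notes = 40)
  emb <- random_embeddings(prep$corpus$vocab, 8, seed = 2)
  le <- build_label_embeddings(prep$corpus$descriptions, emb,
                               labels = prep$labels)
  cfg <- model_config(e = 8, hidden_units = 4, capsule_dim = 4,
                      routing_iters = 2, K1 = 2, n_filters = 4, channels = 2,
                      seed = 5, bilstm = FALSE, label_fusion = FALSE)
  m <- build_model(cfg, emb, le)
  # pure CapsNet: convolution consumes the token dimension directly
  expect_equal(ncol(m$params$conv_W), cfg$K1 * (8 + length(prep$labels)))
  s <- predict_scores(m, prep$split$test[1:3])
  expect_true(all(is.finite(s)))
})

test_that("decision policies follow their definitions", {
  scores <- matrix(c(0.9, 0.2, 0.6), 1, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(scores_to_codes(scores, "threshold", threshold = 0.5)[[1]],
               c("a", "c"))
  tie <- matrix(c(0.3, 0.3), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(scores_to_codes(tie, "topk", k = 1)[[1]], "a")
  S <- with_seed(7, matrix(runif(1000), 100, 10,
                           dimnames = list(NULL, paste0("l", 1:10))))
  got <- codes_to_matrix(scores_to_codes(S, "threshold", threshold = 0.5),
                         paste0("l", 1:10))
  expect_equal(unname(got), unname((S >= 0.5) * 1))
})

test_that("empty notes are scored on padding and flagged", {
  m <- tiny_model(seed = 7)
  expect_warning(
    s <- predict_scores(m, list(list(hadm_id = "h1", tokens = character(0),
                                     codes = "001"))),
    "empty token")
  expect_true(all(is.finite(s)))
})
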