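# Shared tiny fixtures, all built in code.

tiny_vocab <- function(n = 40) sprintf("w%02d", seq_len(n))

tiny_label_emb <- function(emb) {
  desc <- data.frame(code = c("001", "002", "003"),
                     description = c("w01 w02", "w03", "w04 w05"),
                     stringsAsFactors = FALSE)
  build_label_embeddings(desc, emb)
}

# a small but fully wired model over 3 labels
tiny_model <- function(seed = 7, e = 8, ...) {
  emb <- random_embeddings(tiny_vocab(), e, seed = 3)
  le <- tiny_label_emb(emb)
  cfg <- model_config(e = e, hidden_units = 4, capsule_dim = 4,
                      routing_iters = 3, K1 = 2, n_filters = 5,
                      channels = 2, seed = seed, ...)
  build_model(cfg, emb, le)
}

# zero-weight LSTM parameter set (including biases) for closed-form checks
zero_lstm_params <- function(input_dim, u) {
  z <- function() matrix(0, u, input_dim)
  zu <- function() matrix(0, u, u)
  gates <- c("f", "g", "o", "i")
  list(W = setNames(lapply(gates, function(g) z()), gates),
       U = setNames(lapply(gates, function(g) zu()), gates),
       b = setNames(lapply(gates, function(g) rep(0, u)), gates))
}

random_lstm_params <- function(input_dim, u, seed = 1) {
  with_seed(seed, {
    gates <- c("f", "g", "o", "i")
    list(W = setNames(lapply(gates, function(g)
           matrix(rnorm(u * input_dim, sd = 0.5), u, input_dim)), gates),
         U = setNames(lapply(gates, function(g)
           matrix(rnorm(u * u, sd = 0.5), u, u)), gates),
         b = setNames(lapply(gates, function(g) rnorm(u, sd = 0.2)), gates))
  })
}

# small planted-signal corpus prepared end to end for model tests
tiny_prepared_corpus <- function(n_notes = 60, n_labels = 5, seed = 11) {
  spec <- synthetic_spec(n_labels = n_labels, vocab_size = 120,
                         n_notes = n_notes, note_length_mean = 30,
                         labels_per_note_mean = 2)
  corp <- generate_corpus(spec, seed = seed)
  labels <- select_label_space(code_root_counts(corp$diagnoses), n_labels)
  tc <- suppressMessages(
    tokenize_corpus(corp$notes, corp$diagnoses, labels, min_token_freq = 1))
  list(corpus = corp, labels = labels, tokenized = tc,
       split = split_dataset(tc, seed = seed))
}
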