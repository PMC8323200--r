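#' Default run configuration
#'
#' One nested list drives the whole pipeline: input paths, preprocessing,
#' model hyperparameters, decision policy and seed. [read_run_config()] loads
#' a YAML or JSON file over these defaults; command-line flags override file
#' values, and the merged result is persisted next to every artifact so any
#' output is reproducible from its config and seed alone.
#'
#' @param ... named overrides of the defaults
#' @return a `run_config` list
#' @export
run_config <- function(...) {
  cfg <- list(
    paths = list(notes = "notes.csv", diagnoses = "diagnoses.csv",
                 descriptions = "descriptions.csv",
                 embeddings = "embeddings.vec", out_dir = "icdcaps-out"),
    n_labels = 344L,
    preprocess = list(min_token_freq = 3L, max_len = 2500L),
    split = c(0.7, 0.1, 0.2),
    model = list(),             # overrides for model_config()
    policy = list(policy = "threshold", threshold = 0.5, k = 8L),
    bins = list(lo = c(1, 11, 51, 101), hi = c(10, 50, 100, Inf)),
    seed = 1L,
    verbose = FALSE)
  modifyList(cfg, list(...))
}

#' Read a run configuration file (YAML or JSON)
#'
#' @param path config file; extension `.json` selects JSON, anything else is
#'   parsed as YAML
#' @param overrides named list merged over the file values (flags beat file)
#' @return a `run_config` list
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- modifyList(run_config(), vals)
  modifyList(cfg, overrides)
}

persist_config <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(cfg, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Pipeline stage: generate a synthetic corpus
#'
#' @param cfg a `run_config`; `cfg$synthetic` may override [synthetic_spec()]
#'   fields and `embedding_dim`
#' @return file paths, invisibly
#' @export
run_simulate <- function(cfg) {
  out <- cfg$paths$out_dir
  sp_args <- cfg$synthetic %||% list()
  edim <- sp_args$embedding_dim %||% 32L
  sp_args$embedding_dim <- NULL
  spec <- do.call(synthetic_spec, sp_args)
  corpus <- generate_corpus(spec, seed = cfg$seed)
  paths <- write_corpus_csv(corpus, out, embedding_dim = edim,
                            seed = cfg$seed)
  jsonlite::write_json(corpus$signatures,
                       file.path(out, "signatures.json"))
  persist_config(cfg, out)
  if (isTRUE(cfg$verbose))
    message(sprintf("simulated %d notes, %d labels -> %s",
                    spec$n_notes, spec$n_labels, out))
  invisible(paths)
}

#' Pipeline stage: preprocess, select labels, split
#'
#' Reads the three input tables, rolls codes up, selects the label space,
#' tokenizes, and writes JSON-lines corpora for the three splits plus the
#' label order and training label counts.
#'
#' @param cfg a `run_config`
#' @return the `dataset_split`, invisibly
#' @export
run_prepare <- function(cfg) {
  out <- cfg$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  notes <- read_notes(cfg$paths$notes)
  diagnoses <- read_diagnoses(cfg$paths$diagnoses)
  counts <- code_root_counts(diagnoses)
  labels <- select_label_space(counts, min(cfg$n_labels, length(counts)))
  corpus <- tokenize_corpus(notes, diagnoses, labels,
                            min_token_freq = cfg$preprocess$min_token_freq,
                            max_len = cfg$preprocess$max_len)
  split <- split_dataset(corpus, ratios = cfg$split, seed = cfg$seed)
  for (part in c("train", "valid", "test"))
    write_tokenized_corpus(split[[part]],
                           file.path(out, paste0(part, ".jsonl")))
  jsonlite::write_json(as.list(labels), file.path(out, "labels.json"))
  train_counts <- label_counts_of(split$train, labels)
  jsonlite::write_json(as.list(train_counts),
                       file.path(out, "train_label_counts.json"),
                       auto_unbox = TRUE)
  persist_config(cfg, out)
  if (isTRUE(cfg$verbose))
    message(sprintf("prepared %d/%d/%d train/valid/test notes, %d labels",
                    length(split$train), length(split$valid),
                    length(split$test), length(labels)))
  invisible(split)
}

# gold-code occurrences per label within a tokenized corpus
label_counts_of <- function(notes, labels) {
  codes <- unlist(lapply(notes, `[[`, "codes"), use.names = FALSE)
  tab <- table(factor(codes, levels = labels))
  setNames(as.integer(tab), labels)
}

load_prepared <- function(cfg) {
  out <- cfg$paths$out_dir
  need <- file.path(out, c("train.jsonl", "valid.jsonl", "test.jsonl",
                           "labels.json"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing prepared artifact(s): ", paste(missing, collapse = ", "),
         " (run the prepare step first)")
  list(train = read_tokenized_corpus(need[1]),
       valid = read_tokenized_corpus(need[2]),
       test = read_tokenized_corpus(need[3]),
       labels = unlist(jsonlite::fromJSON(need[4])))
}

#' Pipeline stage: train and checkpoint
#'
#' Builds label embeddings from the description table, assembles the model
#' and trains it; the checkpoint file holds the config, vocabulary, label
#' order and parameter arrays, and the training history is written as CSV.
#'
#' @param cfg a `run_config`
#' @return the trained `caps_model`, invisibly
#' @export
run_train <- function(cfg) {
  out <- cfg$paths$out_dir
  prep <- load_prepared(cfg)
  emb <- load_word_vectors(cfg$paths$embeddings)
  descriptions <- read_descriptions(cfg$paths$descriptions)
  margs <- cfg$model %||% list()
  margs$e <- margs$e %||% ncol(emb$vectors)
  margs$seed <- margs$seed %||% cfg$seed
  mcfg <- do.call(model_config, margs)
  label_emb <- build_label_embeddings(descriptions, emb,
                                      labels = prep$labels)
  model <- build_model(mcfg, emb, label_emb)
  model <- train_model(model,
                       list(train = prep$train, valid = prep$valid),
                       verbose = isTRUE(cfg$verbose))
  saveRDS(model, file.path(out, "checkpoint.rds"))
  utils::write.csv(model$history, file.path(out, "history.csv"),
                   row.names = FALSE)
  persist_config(cfg, out)
  invisible(model)
}

#' Pipeline stage: evaluate on the test split
#'
#' @param cfg a `run_config`
#' @return the `metrics_report`, invisibly
#' @export
run_evaluate <- function(cfg) {
  out <- cfg$paths$out_dir
  prep <- load_prepared(cfg)
  model <- load_checkpoint(cfg)
  if (!identical(unname(prep$labels), unname(model$labels)))
    stop("label order mismatch between prepared corpus and checkpoint")
  scores <- predict_scores(model, prep$test)
  gold <- gold_matrix(prep$test, model$labels)
  train_counts <- label_counts_of(prep$train, model$labels)
  bins <- frequency_bins(cfg$bins$lo, cfg$bins$hi)
  report <- metrics_report(scores, gold, train_counts, bins = bins,
                           policy = cfg$policy$policy,
                           threshold = cfg$policy$threshold,
                           k = cfg$policy$k,
                           test_loss = model_loss(model, prep$test),
                           loss_mode = model$config$loss_mode)
  write_metrics_report(report, file.path(out, "metrics.json"))
  persist_config(cfg, out)
  if (isTRUE(cfg$verbose)) print(report)
  invisible(report)
}

load_checkpoint <- function(cfg) {
  path <- file.path(cfg$paths$out_dir, "checkpoint.rds")
  if (!file.exists(path))
    stop("missing checkpoint: ", path, " (run the train step first)")
  readRDS(path)
}

#' Pipeline stage: score notes and export predictions
#'
#' Writes long-format scores (`hadm_id`, `label`, `score`) and the decided
#' code sets as JSON-lines.
#'
#' @param cfg a `run_config`
#' @param notes optional corpus; defaults to the prepared test split
#' @return the score matrix, invisibly
#' @export
run_predict <- function(cfg, notes = NULL) {
  out <- cfg$paths$out_dir
  model <- load_checkpoint(cfg)
  notes <- notes %||% load_prepared(cfg)$test
  scores <- predict_scores(model, notes)
  long <- data.frame(
    hadm_id = rep(rownames(scores), ncol(scores)),
    label = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores), stringsAsFactors = FALSE)
  utils::write.csv(long, file.path(out, "scores.csv"), row.names = FALSE)
  sets <- scores_to_codes(scores, policy = cfg$policy$policy,
                          threshold = cfg$policy$threshold, k = cfg$policy$k)
  lines <- vapply(seq_along(sets), function(i)
    as.character(jsonlite::toJSON(list(hadm_id = rownames(scores)[i],
                                       codes = sets[[i]]))),
    character(1))
  writeLines(lines, file.path(out, "predicted_codes.jsonl"))
  invisible(scores)
}

#' Pipeline stage: routing attributions
#'
#' Writes one attribution CSV over the requested notes and a word-cloud
#' weight CSV per requested label.
#'
#' @param cfg a `run_config`; `cfg$explain$labels` selects labels (default:
#'   all), `cfg$explain$n_notes` caps the notes (default 10)
#' @return attribution records, invisibly
#' @export
run_explain <- function(cfg) {
  out <- cfg$paths$out_dir
  model <- load_checkpoint(cfg)
  notes <- load_prepared(cfg)$test
  n_max <- cfg$explain$n_notes %||% 10L
  notes <- utils::head(notes, n_max)
  recs <- do.call(rbind, lapply(notes, function(n) {
    ex <- explain_note(model, n)
    cbind(hadm_id = n$hadm_id, ex$attribution)
  }))
  utils::write.csv(recs, file.path(out, "attributions.csv"),
                   row.names = FALSE)
  for (lab in (cfg$explain$labels %||% model$labels))
    export_wordcloud_weights(recs, lab,
                             file.path(out, sprintf("wordcloud_%s.csv", lab)))
  invisible(recs)
}

#' Command-line entry point
#'
#' Dispatches `simulate | prepare | train | evaluate | predict | explain`
#' with a config file plus flag overrides (flags beat file values; the merged
#' config is persisted with every artifact). Installed as the
#' `inst/cli/icdcaps` Rscript.
#'
#' @param argv character vector of arguments (default: the process's)
#' @return the stage's value, invisibly
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  cmds <- c("simulate", "prepare", "train", "evaluate", "predict", "explain")
  if (!length(argv) || !argv[1] %in% cmds)
    stop("usage: icdcaps <", paste(cmds, collapse = "|"), "> [options]")
  cmd <- argv[1]
  opts <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "YAML or JSON run configuration"),
    optparse::make_option("--out", type = "character", default = NULL,
                          help = "output directory"),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--notes", type = "character", default = NULL),
    optparse::make_option("--diagnoses", type = "character", default = NULL),
    optparse::make_option("--descriptions", type = "character",
                          default = NULL),
    optparse::make_option("--embeddings", type = "character", default = NULL),
    optparse::make_option("--n-labels", type = "integer", default = NULL,
                          dest = "n_labels"),
    optparse::make_option("--verbose", action = "store_true",
                          default = FALSE)))
  parsed <- optparse::parse_args(opts, args = argv[-1])
  cfg <- if (!is.null(parsed$config)) read_run_config(parsed$config)
         else run_config()
  path_over <- list()
  for (f in c("notes", "diagnoses", "descriptions", "embeddings"))
    if (!is.null(parsed[[f]])) path_over[[f]] <- parsed[[f]]
  if (!is.null(parsed$out)) path_over$out_dir <- parsed$out
  if (length(path_over)) cfg$paths <- modifyList(cfg$paths, path_over)
  if (!is.null(parsed$seed)) cfg$seed <- parsed$seed
  if (!is.null(parsed$n_labels)) cfg$n_labels <- parsed$n_labels
  cfg$verbose <- isTRUE(parsed$verbose) || isTRUE(cfg$verbose)
  stage <- switch(cmd, simulate = run_simulate, prepare = run_prepare,
                  train = run_train, evaluate = run_evaluate,
                  predict = run_predict, explain = run_explain)
  invisible(stage(cfg))
}
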