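#' Train the hybrid capsule coder
#'
#' Minibatch Adam on the configured loss with early stopping on validation
#' loss: training stops once `patience` consecutive epochs fail to improve the
#' best validation loss, and the best-validation parameters are restored.
#' Fully deterministic given the model's config seed. Non-finite losses abort
#' with a diagnostic instead of training onward silently.
#'
#' @param model a `caps_model` from [build_model()]
#' @param split a `dataset_split` of tokenized notes (train and valid must be
#'   non-empty)
#' @param max_epochs,patience,learning_rate,batch_size optional overrides of
#'   the model config
#' @param early_stopping set `FALSE` to always run `max_epochs` epochs
#' @param verbose print per-epoch losses
#' @return the model with trained `params` and a `history` data.frame
#'   (epoch, train_loss, valid_loss)
#' @export
train_model <- function(model, split, max_epochs = NULL, patience = NULL,
                        learning_rate = NULL, batch_size = NULL,
                        early_stopping = TRUE, verbose = FALSE) {
  cfg <- model$config
  max_epochs <- max_epochs %||% cfg$max_epochs
  patience <- patience %||% cfg$patience
  lr <- learning_rate %||% cfg$learning_rate
  bs <- batch_size %||% cfg$batch_size
  if (!length(split$train) || !length(split$valid))
    stop("train and valid sets must be non-empty")

  ec <- engine_cfg(model)
  ids_train <- note_token_ids(model, split$train)
  ids_valid <- note_token_ids(model, split$valid)
  Y_train <- gold_matrix(split$train, model$labels)
  Y_valid <- gold_matrix(split$valid, model$labels)
  n_train <- length(ids_train)

  params <- model$params
  adam <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        valid_loss = numeric(0))

  with_seed(cfg$seed, {
    for (epoch in seq_len(max_epochs)) {
      perm <- sample.int(n_train)
      epoch_loss <- 0
      for (start in seq(1L, n_train, by = bs)) {
        idx <- perm[start:min(start + bs - 1L, n_train)]
        res <- cpp_run_batch(ids_train[idx], Y_train[idx, , drop = FALSE],
                             params, model$emb$vectors, model$Gv,
                             model$label_emb$vectors, ec, TRUE, FALSE)
        if (!is.finite(res$loss_sum))
          stop(sprintf("training diverged (non-finite loss) in epoch %d; %s",
                       epoch, "lower the learning rate"))
        epoch_loss <- epoch_loss + res$loss_sum
        adam <- adam_step(adam, params, res$grads, scale = 1 / length(idx),
                          lr = lr)
        params <- adam$params
      }
      vres <- cpp_run_batch(ids_valid, Y_valid, params, model$emb$vectors,
                            model$Gv, model$label_emb$vectors, ec,
                            FALSE, FALSE)
      valid_loss <- vres$loss_sum / vres$n
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = epoch_loss / n_train,
                                  valid_loss = valid_loss))
      if (verbose)
        message(sprintf("epoch %d: train %.5f valid %.5f", epoch,
                        epoch_loss / n_train, valid_loss))
      if (valid_loss < best$loss - 1e-12) {
        best <- list(loss = valid_loss, params = params, epoch = epoch)
        wait <- 0L
      } else if (early_stopping) {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  model$params <- if (early_stopping) best$params else params
  model$history <- history
  model$best_epoch <- if (early_stopping) best$epoch else nrow(history)
  model
}

adam_init <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zl <- lapply(params, function(p) p * 0)
  list(m = zl, v = zl, t = 0L, beta1 = beta1, beta2 = beta2, eps = eps,
       params = params)
}

# one Adam update; `scale` converts summed batch gradients to means
adam_step <- function(state, params, grads, scale, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] * scale
    dim(g) <- dim(params[[nm]]) # C++ returns column matrices for vectors
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  state$params <- params
  state
}
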