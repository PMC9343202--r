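# Classifier training: weighted cross-entropy, Adam, deterministic
# minibatch schedule, history and checkpoints.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate
#' 0.001, batch size 32, 100 epochs. Class weights default to
#' inverse-frequency (`"auto"`), which is ~1 on balanced data.
#'
#' @param learning_rate Adam step size; 0.01 is accepted but warned
#'   about (observed to collapse training to chance accuracy).
#' @param batch_size minibatch size; the last incomplete batch is kept.
#' @param epochs passes over the training set.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param class_weights `"auto"` or a positive 2-vector
#'   (non-binding, binding).
#' @param seed master seed: parameter initialisation is not included
#'   (the model carries its own seed); per-epoch shuffling is derived
#'   from this seed.
#' @param shuffle reshuffle examples every epoch.
#' @param clip optional gradient-norm clip (off by default).
#' @param beta1,beta2,epsilon Adam moment hyperparameters.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32L, epochs = 100L,
                         optimizer = c("adam", "sgd"), class_weights = "auto",
                         seed = 1L, shuffle = TRUE, clip = 0,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(
    list(
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      epochs = as.integer(epochs), optimizer = optimizer,
      class_weights = class_weights, seed = as.integer(seed),
      shuffle = isTRUE(shuffle), clip = clip,
      beta1 = beta1, beta2 = beta2, epsilon = epsilon
    ),
    class = "train_config"
  )
}

#' Weighted cross-entropy loss from logits
#'
#' `loss = -weights[label] * log softmax(logits)[label]`, computed
#' with the log-sum-exp trick so saturated logits neither overflow nor
#' lose precision. With weights (1, 1) this is exactly the unweighted
#' cross-entropy.
#'
#' @param logits length-2 numeric vector (non-binding, binding).
#' @param label 0 (non-binding) or 1 (binding).
#' @param weights positive 2-vector of class weights.
#' @return The scalar loss.
#' @export
weighted_cross_entropy <- function(logits, label, weights = c(1, 1)) {
  stopifnot(length(logits) == 2L, label %in% c(0L, 1L), all(weights > 0))
  if (any(!is.finite(logits))) stop("non-finite logits")
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  -weights[label + 1L] * (logits[label + 1L] - lse)
}

#' Inverse-frequency class weights
#'
#' `weight[c] = N_total / (2 * N_c)`: mean 1 on balanced data, up-
#' weighting the rarer class otherwise.
#'
#' @param ds a `site_dataset`.
#' @return Numeric 2-vector (non-binding, binding).
#' @export
auto_class_weights <- function(ds) {
  stopifnot(inherits(ds, "site_dataset"))
  n0 <- sum(ds$pairs$label == 0L)
  n1 <- sum(ds$pairs$label == 1L)
  if (n0 == 0L || n1 == 0L) stop("both classes must be present to derive class weights")
  n <- n0 + n1
  c(n / (2 * n0), n / (2 * n1))
}

resolve_class_weights <- function(config, ds) {
  if (identical(config$class_weights, "auto")) auto_class_weights(ds) else {
    w <- as.numeric(config$class_weights)
    stopifnot(length(w) == 2L, all(w > 0))
    w
  }
}

#' Train the classifier
#'
#' Minibatch gradient descent with Adam (or plain SGD) on the weighted
#' cross-entropy, shuffling reseeded per epoch from the master seed.
#' Embedding tables are frozen: the classifier consumes fixed
#' encodings, matching a pretraining-then-classify protocol.
#' Deterministic given (dataset, model seed, config seed).
#'
#' @param dataset a `site_dataset`.
#' @param model a `site_model` (from [init_site_model()] or a
#'   [make_variant()] constructor) whose `dim` matches the tables.
#' @param tables list with `mi2vec` and `m2vec` `embedding_table`s
#'   (the miRNA branch uses mi2vec, the CTS branch m2vec).
#' @param config a [train_config()].
#' @param validation optional `site_dataset` scored after every epoch;
#'   enables the best-validation checkpoint.
#' @param out_dir optional directory for `final.ckpt`,
#'   `best.ckpt` (when validation is given) and `history.tsv`.
#' @return list with `model` (trained), `history` (data.frame: epoch,
#'   loss, train_acc, val_acc, seconds) and `best_model`.
#' @export
train_model <- function(dataset, model, tables, config = train_config(),
                        validation = NULL, out_dir = NULL) {
  stopifnot(inherits(dataset, "site_dataset"), inherits(model, "site_model"),
            inherits(config, "train_config"))
  if (nrow(dataset$pairs) == 0L) stop("empty training dataset")
  if (config$learning_rate >= 0.01) {
    warning("learning rates >= 0.01 have been observed to prevent convergence")
  }
  weights <- resolve_class_weights(config, dataset)
  enc <- encode_dataset(dataset, tables$mi2vec, tables$m2vec)
  enc_val <- if (!is.null(validation)) {
    encode_dataset(validation, tables$mi2vec, tables$m2vec)
  }
  n <- length(enc$labels)
  set.seed(config$seed)
  shuffles <- vapply(seq_len(config$epochs), function(e) {
    if (config$shuffle) sample.int(n) - 1L else seq_len(n) - 1L
  }, integer(n))
  t0 <- proc.time()[["elapsed"]]
  fit <- cpp_model_train(
    enc$mirna, enc$cts, as.integer(enc$labels), model$params, model$config,
    list(
      lr = config$learning_rate, batch = config$batch_size,
      epochs = config$epochs, adam = config$optimizer == "adam",
      beta1 = config$beta1, beta2 = config$beta2, eps = config$epsilon,
      weights = weights, clip = config$clip
    ),
    shuffles,
    if (is.null(enc_val)) NULL else enc_val$mirna,
    if (is.null(enc_val)) NULL else enc_val$cts,
    if (is.null(enc_val)) NULL else as.integer(enc_val$labels)
  )
  elapsed <- proc.time()[["elapsed"]] - t0
  trained <- structure(list(config = model$config, params = fit$params),
                       class = "site_model")
  history <- data.frame(
    epoch = seq_len(config$epochs),
    loss = as.numeric(fit$loss),
    train_acc = as.numeric(fit$train_acc),
    val_acc = if (is.null(enc_val)) NA_real_ else as.numeric(fit$val_acc),
    seconds = elapsed / config$epochs
  )
  if (any(!is.finite(history$loss))) {
    stop(sprintf("non-finite training loss at epoch %d; lower the learning rate",
                 which(!is.finite(history$loss))[1]))
  }
  best_model <- trained
  if (!is.null(enc_val)) {
    best_epoch <- which.max(history$val_acc)
    if (best_epoch < config$epochs && !is.null(fit$best_params)) {
      best_model <- structure(list(config = model$config, params = fit$best_params),
                              class = "site_model")
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_checkpoint(trained, file.path(out_dir, "final.ckpt"))
    if (!is.null(enc_val)) write_checkpoint(best_model, file.path(out_dir, "best.ckpt"))
    write_history(history, file.path(out_dir, "history.tsv"))
  }
  list(model = trained, history = history, best_model = best_model)
}

# timing stays out of the file so identical runs give identical bytes
write_history <- function(history, path, digest = NULL) {
  h <- history[setdiff(names(history), "seconds")]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(digest)) writeLines(paste0("# config_digest: ", digest), con)
  writeLines(paste(names(h), collapse = "\t"), con)
  cols <- lapply(h, function(col) sprintf("%.10g", as.numeric(col)))
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}
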