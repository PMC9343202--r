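# End-to-end orchestration: corpus -> mi2vec/m2vec -> encode -> train
# -> evaluate, behind one reproducible, cached, seeded command surface.

#' Experiment run configuration
#'
#' Collects every stage's settings plus a master seed. Stage seeds are
#' derived deterministically from the master seed (simulation: seed,
#' embeddings: seed + 1, split/training: seed + 2), so one integer
#' reproduces the whole run.
#'
#' @param out_dir run directory (created if needed).
#' @param pairs_path site-pair TSV to analyse; `NULL` to simulate.
#' @param simulate a [synthetic_config()] used when `pairs_path` is
#'   `NULL` (its `rng_seed` is overridden by the master seed).
#' @param mirna_corpus,mrna_corpus FASTA paths for embedding training;
#'   `NULL` with simulation uses the generated companion corpora.
#' @param embedding a [skipgram_config()]; its `dim` fixes the model
#'   input dimension. Set `encoding = "one_hot"` to bypass skip-gram
#'   training and use the orthogonal baseline (dim 4).
#' @param encoding `"word2vec"` or `"one_hot"`.
#' @param model a [model_config()] or [cnn1d_config()]; its `dim` is
#'   overridden to match the encoding.
#' @param train a [train_config()].
#' @param eval_mode `"holdout"` (default: one stratified fold held
#'   out) or `"cv"` (full k-fold cross-validation).
#' @param k folds for splitting/cross-validation.
#' @param threshold decision threshold for the report.
#' @param seed master seed.
#' @return A `run_config`.
#' @export
run_config <- function(out_dir, pairs_path = NULL, simulate = synthetic_config(),
                       mirna_corpus = NULL, mrna_corpus = NULL,
                       embedding = skipgram_config(), encoding = c("word2vec", "one_hot"),
                       model = model_config(), train = train_config(),
                       eval_mode = c("holdout", "cv"), k = 5L, threshold = 0.5,
                       seed = 1L) {
  encoding <- match.arg(encoding)
  eval_mode <- match.arg(eval_mode)
  if (is.null(pairs_path) && is.null(simulate)) {
    stop("config error: either pairs_path or a simulate config is required")
  }
  if (!is.null(pairs_path) && is.null(mirna_corpus) != is.null(mrna_corpus)) {
    stop("config error: provide both corpora or neither")
  }
  if (!is.null(pairs_path) && encoding == "word2vec" && is.null(mirna_corpus)) {
    stop("config error: word2vec encoding over an external pairs file needs corpora")
  }
  structure(
    list(
      out_dir = out_dir, pairs_path = pairs_path, simulate = simulate,
      mirna_corpus = mirna_corpus, mrna_corpus = mrna_corpus,
      embedding = embedding, encoding = encoding, model = model,
      train = train, eval_mode = eval_mode, k = as.integer(k),
      threshold = threshold, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

config_digest <- function(config) {
  drop_out <- config
  drop_out$out_dir <- NULL
  json <- jsonlite::toJSON(strip_classes(drop_out), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

run_log <- function(dir, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = file.path(dir, "log.txt"), append = TRUE)
}

holdout_split <- function(ds, k, seed) {
  ds <- stratified_kfold(ds, k = k, seed = seed)
  test_idx <- which(ds$fold_of[ds$pairs$pair_id] == 0L)
  list(train = subset_pairs(ds, -test_idx), test = subset_pairs(ds, test_idx))
}

resolve_tables <- function(config, ds, dir, digest, force = FALSE) {
  if (config$encoding == "one_hot") {
    oh <- one_hot_table()
    return(list(mi2vec = oh, m2vec = oh))
  }
  mi_path <- file.path(dir, "mi2vec.tsv")
  m_path <- file.path(dir, "m2vec.tsv")
  if (!force && file.exists(mi_path) && file.exists(m_path)) {
    run_log(dir, "embeddings: cached tables found, stage skipped")
    return(list(mi2vec = read_embedding_table(mi_path),
                m2vec = read_embedding_table(m_path)))
  }
  if (!is.null(config$mirna_corpus)) {
    mi_rec <- read_fasta(config$mirna_corpus, "miRNA")
    m_rec <- read_fasta(config$mrna_corpus, "mRNA")
    mi_sent <- build_corpus(mi_rec)
    m_sent <- build_corpus(m_rec)
  } else {
    mi_sent <- build_corpus(attr(ds, "mirna_corpus"))
    m_sent <- build_corpus(attr(ds, "cts_corpus"))
  }
  emb <- config$embedding
  emb$seed <- config$seed + 1L
  run_log(dir, sprintf("embeddings: training mi2vec/m2vec (dim %d, seed %d)",
                       emb$dim, emb$seed))
  mi2vec <- train_skipgram(mi_sent, emb, "miRNA")
  m2vec <- train_skipgram(m_sent, emb, "mRNA")
  write_embedding_table(mi2vec, mi_path, digest = digest)
  write_embedding_table(m2vec, m_path, digest = digest)
  list(mi2vec = mi2vec, m2vec = m2vec)
}

#' Run the full experiment pipeline
#'
#' Stages: (1) load or simulate the site-pair dataset; (2) train or
#' load the embedding tables; (3) split (or assign folds), train the
#' classifier; (4) evaluate and write the report, curves, history and
#' checkpoints. Stages whose outputs already exist in `out_dir` are
#' skipped unless `force = TRUE`. Every artifact embeds the digest of
#' the resolved configuration; two runs with identical config and seed
#' are byte-identical (the timestamped log aside).
#'
#' @param config a [run_config()].
#' @param force re-run stages whose outputs exist.
#' @return The run directory, invisibly; artifacts on disk, and the
#'   evaluation report as attribute `report`.
#' @export
run_experiment <- function(config, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(config)
  snap <- file.path(dir, "config.json")
  jsonlite::write_json(
    c(strip_classes(within(unclass(config), rm(out_dir))),
      list(config_digest = digest)),
    snap, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  run_log(dir, sprintf("run start (config digest %s)", digest))

  # stage 1: dataset
  pairs_file <- file.path(dir, "pairs.tsv")
  if (!is.null(config$pairs_path)) {
    ds <- read_site_pairs(config$pairs_path)
    run_log(dir, sprintf("dataset: %d pairs read from %s (md5 %s)",
                         nrow(ds$pairs), config$pairs_path,
                         unname(tools::md5sum(config$pairs_path))))
  } else {
    sim <- config$simulate
    sim$rng_seed <- config$seed
    ds <- generate_dataset(sim)
    if (force || !file.exists(pairs_file)) {
      write_site_pairs(ds, pairs_file, digest = digest)
      write_corpora(ds, dir)
    } else {
      run_log(dir, "dataset: pairs.tsv exists, simulation stage skipped")
      ds_cached <- read_site_pairs(pairs_file)
      attr(ds_cached, "mirna_corpus") <- attr(ds, "mirna_corpus")
      attr(ds_cached, "cts_corpus") <- attr(ds, "cts_corpus")
      ds <- ds_cached
    }
    run_log(dir, sprintf("dataset: %d simulated pairs (seed %d)",
                         nrow(ds$pairs), config$seed))
  }

  # stage 2: encodings
  tables <- resolve_tables(config, ds, dir, digest, force = force)
  model_cfg <- config$model
  model_cfg$dim <- tables$mi2vec$dim
  if (model_cfg$kind == "cnn1d") {
    model_cfg <- cnn1d_config(dim = tables$mi2vec$dim, filters = model_cfg$filters,
                              kernel = model_cfg$kernel, pool = model_cfg$pool)
  }

  # stages 3-4: train + evaluate
  report_path <- file.path(dir, "report.json")
  if (!force && file.exists(report_path)) {
    run_log(dir, "train/evaluate: report exists, stages skipped")
    report <- jsonlite::fromJSON(report_path)
    out <- invisible(dir)
    attr(out, "report") <- report
    return(out)
  }
  if (config$eval_mode == "cv") {
    run_log(dir, sprintf("cross-validation: k = %d", config$k))
    constructor <- function(dim, hidden1, hidden2, linear1, seed) {
      cfg <- model_cfg
      init_site_model(cfg, seed = seed)
    }
    cv <- cross_validate(ds, constructor, tables, config$train, k = config$k,
                         seed = config$seed + 2L, threshold = config$threshold)
    report <- list(mean = as.list(cv$mean), folds = lapply(cv$folds, unclass))
    write_eval_report(report, report_path, digest = digest)
    run_log(dir, sprintf("cv mean accuracy: %.4f", cv$mean[["acc"]]))
  } else {
    sp <- holdout_split(ds, config$k, config$seed + 2L)
    run_log(dir, sprintf("holdout: %d train / %d test pairs",
                         nrow(sp$train$pairs), nrow(sp$test$pairs)))
    model <- init_site_model(model_cfg, seed = config$seed + 2L)
    tcfg <- config$train
    tcfg$seed <- config$seed + 2L
    fit <- train_model(sp$train, model, tables, tcfg, validation = sp$test)
    write_checkpoint(fit$model, file.path(dir, "final.ckpt"), digest = digest)
    write_checkpoint(fit$best_model, file.path(dir, "best.ckpt"), digest = digest)
    write_history(fit$history, file.path(dir, "history.tsv"), digest = digest)
    scores <- predict_binding(fit$model, encode_dataset(sp$test, tables$mi2vec, tables$m2vec))
    report <- evaluate_scores(scores, sp$test$pairs$label, config$threshold)
    write_eval_report(report, report_path, digest = digest)
    write_curves(scores, sp$test$pairs$label,
                 pr_path = file.path(dir, "pr_curve.tsv"),
                 roc_path = file.path(dir, "roc_curve.tsv"), digest = digest)
    run_log(dir, sprintf("holdout accuracy: %.4f (AUC %.4f)", report$acc, report$auc))
  }
  run_log(dir, "run complete")
  out <- invisible(dir)
  attr(out, "report") <- report
  out
}

eval_one_setting <- function(ds, tables, model_cfg, train_cfg, split, threshold = 0.5,
                             seed = 1L) {
  model_cfg$dim <- tables$mi2vec$dim
  if (model_cfg$kind == "cnn1d") {
    model_cfg <- cnn1d_config(dim = tables$mi2vec$dim, filters = model_cfg$filters,
                              kernel = model_cfg$kernel, pool = model_cfg$pool)
  }
  model <- init_site_model(model_cfg, seed = seed)
  fit <- train_model(split$train, model, tables, train_cfg)
  scores <- predict_binding(fit$model, encode_dataset(split$test, tables$mi2vec, tables$m2vec))
  evaluate_scores(scores, split$test$pairs$label, threshold)
}

write_comparison_tsv <- function(df, path, digest) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_digest: ", digest), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  cols <- lapply(df, function(col) if (is.numeric(col)) sprintf("%.10g", col) else as.character(col))
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Accuracy versus encoding comparison
#'
#' Trains and evaluates one classifier per encoding - skip-gram tables
#' over a grid of dimensions, optionally the one-hot baseline - with a
#' shared dataset, fold split and seeds, mirroring the design of the
#' embedding-dimension experiment. The direction of any difference is
#' reported, not asserted: it is dataset-dependent.
#'
#' @param config a [run_config()]; its `model` field selects the
#'   classifier (`model_config()` for the BiLSTM, [cnn1d_config()] for
#'   the CNN baseline).
#' @param dims integer vector of embedding dimensions (the published
#'   grid is `c(2, 4, 10, 20, 30, 50, 100)`).
#' @param include_one_hot add the one-hot baseline row.
#' @return A data.frame (encoding, dim, acc, sens, spec, f_measure,
#'   ap, auc), also written to `encodings.tsv` in `out_dir` with a
#'   shared-split digest.
#' @export
compare_encodings <- function(config, dims = c(2L, 4L, 10L, 20L, 30L, 50L, 100L),
                              include_one_hot = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(config)
  sim <- config$simulate
  sim$rng_seed <- config$seed
  ds <- if (is.null(config$pairs_path)) generate_dataset(sim) else read_site_pairs(config$pairs_path)
  split <- holdout_split(ds, config$k, config$seed + 2L)
  split_digest <- {
    tmp <- tempfile()
    writeLines(paste(sort(split$test$pairs$pair_id), collapse = ","), tmp)
    on.exit(unlink(tmp), add = TRUE)
    unname(tools::md5sum(tmp))
  }
  rows <- list()
  settings <- c(
    if (include_one_hot) list(list(name = "one_hot", dim = 4L)),
    lapply(dims, function(d) list(name = "word2vec", dim = as.integer(d)))
  )
  for (s in settings) {
    if (s$name == "one_hot") {
      tables <- list(mi2vec = one_hot_table(), m2vec = one_hot_table())
    } else {
      emb <- config$embedding
      emb$dim <- s$dim
      emb$seed <- config$seed + 1L
      tables <- list(
        mi2vec = train_skipgram(build_corpus(attr(ds, "mirna_corpus")), emb, "miRNA"),
        m2vec = train_skipgram(build_corpus(attr(ds, "cts_corpus")), emb, "mRNA")
      )
    }
    rep <- eval_one_setting(ds, tables, config$model, config$train, split,
                            threshold = config$threshold, seed = config$seed + 2L)
    rows[[length(rows) + 1L]] <- data.frame(
      encoding = s$name, dim = s$dim, acc = rep$acc, sens = rep$sens,
      spec = rep$spec, f_measure = rep$f_measure, ap = rep$ap, auc = rep$auc,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "split_digest") <- split_digest
  write_comparison_tsv(out, file.path(dir, "encodings.tsv"), digest)
  out
}

TABLE1_ARCHS <- list(
  c("RNN", "RNN"), c("GRU", "GRU"), c("LSTM", "LSTM"),
  c("LSTM", "BiLSTM"), c("BiLSTM", "LSTM"), c("BiLSTM", "BiLSTM")
)

TABLE2_STRUCTURES <- list(
  c(8, 32, 32), c(16, 32, 32), c(32, 32, 32), c(50, 32, 32),
  c(64, 32, 32), c(128, 32, 32), c(50, 8, 8), c(50, 16, 16),
  c(50, 64, 64), c(50, 128, 128)
)

TABLE3_HYPERS <- list(
  list(lr = 5e-4, batch = 32L), list(lr = 1e-3, batch = 32L),
  list(lr = 5e-3, batch = 32L), list(lr = 1e-2, batch = 32L),
  list(lr = 1e-3, batch = 8L), list(lr = 1e-3, batch = 16L),
  list(lr = 1e-3, batch = 64L), list(lr = 1e-3, batch = 128L)
)

#' Architecture / structure / hyperparameter comparison grids
#'
#' Reproduces the designs of the published ablations on a shared
#' dataset, split and seed, varying one axis only:
#' `axis = "cells"` - the six two-layer recurrent-unit combinations;
#' `axis = "structure"` - the ten layer-size layouts (first hidden,
#' second hidden, first linear; the output layer is always 2);
#' `axis = "hyper"` - the eight (learning rate, batch size) settings.
#'
#' @param config a [run_config()].
#' @param axis which grid to run.
#' @return A data.frame with one row per setting, also written to
#'   `architectures_<axis>.tsv` in `out_dir`.
#' @export
compare_architectures <- function(config, axis = c("cells", "structure", "hyper")) {
  stopifnot(inherits(config, "run_config"))
  axis <- match.arg(axis)
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(config)
  sim <- config$simulate
  sim$rng_seed <- config$seed
  ds <- if (is.null(config$pairs_path)) generate_dataset(sim) else read_site_pairs(config$pairs_path)
  split <- holdout_split(ds, config$k, config$seed + 2L)
  if (config$encoding == "one_hot") {
    tables <- list(mi2vec = one_hot_table(), m2vec = one_hot_table())
  } else {
    emb <- config$embedding
    emb$seed <- config$seed + 1L
    tables <- list(
      mi2vec = train_skipgram(build_corpus(attr(ds, "mirna_corpus")), emb, "miRNA"),
      m2vec = train_skipgram(build_corpus(attr(ds, "cts_corpus")), emb, "mRNA")
    )
  }
  base_model <- config$model
  rows <- list()
  if (axis == "cells") {
    for (a in TABLE1_ARCHS) {
      cfg <- model_config(dim = base_model$dim, hidden1 = base_model$hidden1,
                          hidden2 = base_model$hidden2, linear1 = base_model$linear1,
                          arch = a, pooling = base_model$pooling)
      rep <- eval_one_setting(ds, tables, cfg, config$train, split,
                              threshold = config$threshold, seed = config$seed + 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        layer1 = a[1], layer2 = a[2], acc = rep$acc, f_measure = rep$f_measure,
        stringsAsFactors = FALSE
      )
    }
  } else if (axis == "structure") {
    for (s in TABLE2_STRUCTURES) {
      cfg <- model_config(dim = base_model$dim, hidden1 = s[1], hidden2 = s[2],
                          linear1 = s[3], arch = base_model$arch,
                          pooling = base_model$pooling)
      rep <- eval_one_setting(ds, tables, cfg, config$train, split,
                              threshold = config$threshold, seed = config$seed + 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        hidden1 = s[1], hidden2 = s[2], linear1 = s[3], linear2 = 2L,
        acc = rep$acc, stringsAsFactors = FALSE
      )
    }
  } else {
    for (hset in TABLE3_HYPERS) {
      tcfg <- config$train
      tcfg$learning_rate <- hset$lr
      tcfg$batch_size <- hset$batch
      rep <- eval_one_setting(ds, tables, base_model, tcfg, split,
                              threshold = config$threshold, seed = config$seed + 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        lr = hset$lr, batch_size = hset$batch, acc = rep$acc,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  write_comparison_tsv(out, file.path(dir, sprintf("architectures_%s.tsv", axis)), digest)
  out
}
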