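# The classifier: an LSTM cell, bidirectional/stacked composition,
# the two-branch 50-32-32-2 network, and baseline architectures.
#
# R functions here are the reference surface (single sequences, used
# heavily in tests); batched forward/backward/training runs in C++
# (src/network.cpp) and is cross-checked against these.

CELL_TYPES <- c(RNN = "rnn", GRU = "gru", LSTM = "lstm", BiLSTM = "lstm")

#' Classifier architecture configuration
#'
#' The default is the published two-branch layout: each branch (miRNA
#' and CTS, both padded to 30 nt and embedded in `dim` dimensions)
#' passes through its own first-layer BiLSTM with 50 hidden units; the
#' two 30 x 100 feature maps are concatenated along the time axis into
#' a 60-step map; a second BiLSTM with 32 hidden units reads it; the
#' final forward and backward hidden states (64 values) pass through a
#' 32-unit ReLU linear layer and a 2-unit linear layer, and softmax
#' yields binding/non-binding probabilities - the "50-32-32-2" layout.
#'
#' @param dim embedding dimension of the input encodings.
#' @param hidden1 hidden units of the first (per-branch) recurrent layer.
#' @param hidden2 hidden units of the second (shared) recurrent layer.
#' @param linear1 units of the first linear layer.
#' @param arch length-2 character vector naming the recurrent unit per
#'   layer, each one of `"RNN"`, `"GRU"`, `"LSTM"`, `"BiLSTM"`.
#' @param pooling how the second layer's feature map is summarised
#'   before the linear head: `"final"` (default; last forward and
#'   last backward hidden states, the standard bidirectional summary),
#'   `"max"` (elementwise maximum over the 60 positions) or `"mean"`.
#' @param share_branches if `TRUE` the two branches share one set of
#'   first-layer parameters (default `FALSE`: separate parameters).
#' @return A `model_config`.
#' @export
model_config <- function(dim = 50L, hidden1 = 50L, hidden2 = 32L, linear1 = 32L,
                         arch = c("BiLSTM", "BiLSTM"), share_branches = FALSE,
                         pooling = c("final", "max", "mean")) {
  pooling <- match.arg(pooling)
  stopifnot(length(arch) == 2L)
  if (!all(arch %in% names(CELL_TYPES))) {
    stop(sprintf("unknown architecture '%s'", setdiff(arch, names(CELL_TYPES))[1]))
  }
  structure(
    list(
      kind = "recurrent",
      dim = as.integer(dim), hidden1 = as.integer(hidden1),
      hidden2 = as.integer(hidden2), linear1 = as.integer(linear1),
      arch = arch,
      cell1 = unname(CELL_TYPES[arch[1]]), cell2 = unname(CELL_TYPES[arch[2]]),
      bidir1 = arch[1] == "BiLSTM", bidir2 = arch[2] == "BiLSTM",
      share_branches = isTRUE(share_branches), pooling = pooling
    ),
    class = "model_config"
  )
}

#' 1-d CNN baseline configuration
#'
#' The convolutional baseline used in the encoding-comparison
#' experiments: the two encodings are concatenated along time (60 x
#' dim), passed through two conv-ReLU-maxpool blocks, flattened, and
#' mapped to 2 logits.
#'
#' @param dim embedding dimension.
#' @param filters filter counts of the two convolution blocks.
#' @param kernel 1-d kernel width (time axis).
#' @param pool max-pooling width.
#' @return A `model_config` with `kind = "cnn1d"`.
#' @export
cnn1d_config <- function(dim = 50L, filters = c(32L, 64L), kernel = 5L, pool = 2L) {
  t1 <- 2L * MODEL_LENGTH - kernel + 1L
  p1 <- t1 %/% pool
  t2 <- p1 - kernel + 1L
  p2 <- t2 %/% pool
  stopifnot(t1 >= 1L, t2 >= 1L, p2 >= 1L)
  structure(
    list(
      kind = "cnn1d", dim = as.integer(dim),
      filters = as.integer(filters), kernel = as.integer(kernel),
      pool = as.integer(pool), flat = as.integer(p2 * filters[2])
    ),
    class = "model_config"
  )
}

cell_param_names <- function(cell) {
  switch(cell,
    lstm = c("W_f", "W_i", "W_c", "W_o", "b_f", "b_i", "b_c", "b_o"),
    gru = c("W_z", "W_r", "W_n", "b_z", "b_r", "b_n"),
    rnn = c("W", "b")
  )
}

init_cell_params <- function(cell, hidden, input) {
  fan <- hidden + input
  bound <- 1 / sqrt(fan)
  mk_w <- function() matrix(runif(hidden * fan, -bound, bound), hidden, fan)
  p <- list()
  for (nm in cell_param_names(cell)) {
    if (startsWith(nm, "W")) {
      p[[nm]] <- mk_w()
    } else {
      p[[nm]] <- numeric(hidden)
    }
  }
  if (cell == "lstm") p$b_f <- rep(1, hidden) # open forget gate at init
  p
}

component_names <- function(config) {
  comps <- c("mi_l1_fwd", if (config$bidir1) "mi_l1_bwd")
  if (!config$share_branches) {
    comps <- c(comps, "cts_l1_fwd", if (config$bidir1) "cts_l1_bwd")
  }
  c(comps, "l2_fwd", if (config$bidir2) "l2_bwd")
}

#' Initialise model parameters
#'
#' Weights are uniform in +/- 1/sqrt(fan_in); biases are zero except
#' the LSTM forget-gate bias, initialised to 1. Deterministic given
#' `seed`.
#'
#' @param config a [model_config()] or [cnn1d_config()].
#' @param seed integer seed.
#' @return A `site_model` (config + named parameter list).
#' @export
init_site_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(as.integer(seed))
  params <- list()
  if (config$kind == "recurrent") {
    d1 <- if (config$bidir1) 2L else 1L
    d2 <- if (config$bidir2) 2L else 1L
    for (nm in component_names(config)) {
      lay <- if (grepl("_l1_", nm)) 1L else 2L
      cell <- if (lay == 1L) config$cell1 else config$cell2
      hid <- if (lay == 1L) config$hidden1 else config$hidden2
      inp <- if (lay == 1L) config$dim else d1 * config$hidden1
      params[[nm]] <- init_cell_params(cell, hid, inp)
    }
    pooled <- d2 * config$hidden2
    b1 <- 1 / sqrt(pooled)
    b2 <- 1 / sqrt(config$linear1)
    params$lin1_W <- matrix(runif(config$linear1 * pooled, -b1, b1), config$linear1, pooled)
    params$lin1_b <- numeric(config$linear1)
    params$lin2_W <- matrix(runif(2L * config$linear1, -b2, b2), 2L, config$linear1)
    params$lin2_b <- numeric(2L)
  } else {
    k <- config$kernel
    f1 <- config$filters[1]
    f2 <- config$filters[2]
    bk1 <- 1 / sqrt(k * config$dim)
    bk2 <- 1 / sqrt(k * f1)
    bl <- 1 / sqrt(config$flat)
    params$conv1_W <- matrix(runif(f1 * k * config$dim, -bk1, bk1), f1, k * config$dim)
    params$conv1_b <- numeric(f1)
    params$conv2_W <- matrix(runif(f2 * k * f1, -bk2, bk2), f2, k * f1)
    params$conv2_b <- numeric(f2)
    params$lin_W <- matrix(runif(2L * config$flat, -bl, bl), 2L, config$flat)
    params$lin_b <- numeric(2L)
  }
  structure(list(config = config, params = params), class = "site_model")
}

#' @export
print.site_model <- function(x, ...) {
  cfg <- x$config
  if (cfg$kind == "recurrent") {
    cat(sprintf(
      "<site_model> %s-%s, dim %d, layout %d-%d-%d-2%s\n",
      cfg$arch[1], cfg$arch[2], cfg$dim, cfg$hidden1, cfg$hidden2, cfg$linear1,
      if (cfg$share_branches) " (shared branches)" else ""
    ))
  } else {
    cat(sprintf(
      "<site_model> CNN1d, dim %d, filters %s, kernel %d\n",
      cfg$dim, paste(cfg$filters, collapse = "/"), cfg$kernel
    ))
  }
  invisible(x)
}

#' Constructor for an architecture variant
#'
#' Returns a constructor building the two-branch topology with the
#' named recurrent unit substituted per layer; `c("BiLSTM", "BiLSTM")`
#' reproduces the default model exactly.
#'
#' @param arch length-2 character vector over
#'   `{"RNN", "GRU", "LSTM", "BiLSTM"}`.
#' @return A function `(dim, hidden1, hidden2, linear1, seed,
#'   share_branches)` returning a `site_model`.
#' @export
make_variant <- function(arch = c("BiLSTM", "BiLSTM")) {
  cfg_check <- model_config(arch = arch) # validates the names
  force(cfg_check)
  function(dim = 50L, hidden1 = 50L, hidden2 = 32L, linear1 = 32L,
           seed = 1L, share_branches = FALSE) {
    init_site_model(
      model_config(dim = dim, hidden1 = hidden1, hidden2 = hidden2,
                   linear1 = linear1, arch = arch,
                   share_branches = share_branches),
      seed = seed
    )
  }
}

#' One LSTM cell step
#'
#' The gated recurrence: with z = [h_{t-1}, x_t],
#' f_t = sigma(W_f z + b_f), i_t = sigma(W_i z + b_i),
#' c_temp = tanh(W_c z + b_c), c_t = f_t * c_{t-1} + i_t * c_temp,
#' o_t = sigma(W_o z + b_o), h_t = o_t * tanh(c_t)
#' (all products elementwise).
#'
#' @param x_t input vector at time t.
#' @param state list with `h` and `c` (both length `hidden`); use
#'   zeros at t = 0.
#' @param params list of gate weights `W_f, W_i, W_c, W_o` (each
#'   `hidden x (hidden + input)`) and biases `b_f, b_i, b_c, b_o`.
#' @return Updated state list with `h` and `c`.
#' @export
lstm_cell_step <- function(x_t, state, params) {
  z <- c(state$h, x_t)
  if (ncol(params$W_f) != length(z)) {
    stop(sprintf("LSTM cell expects input of %d, got %d",
                 ncol(params$W_f) - length(state$h), length(x_t)))
  }
  sig <- function(a) 1 / (1 + exp(-a))
  f <- sig(as.numeric(params$W_f %*% z) + params$b_f)
  i <- sig(as.numeric(params$W_i %*% z) + params$b_i)
  g <- tanh(as.numeric(params$W_c %*% z) + params$b_c)
  cc <- f * state$c + i * g
  o <- sig(as.numeric(params$W_o %*% z) + params$b_o)
  list(h = o * tanh(cc), c = cc)
}

lstm_run <- function(X, params) {
  hidden <- length(params$b_f)
  st <- list(h = numeric(hidden), c = numeric(hidden))
  H <- matrix(0, nrow(X), hidden)
  for (t in seq_len(nrow(X))) {
    st <- lstm_cell_step(X[t, ], st, params)
    H[t, ] <- st$h
  }
  H
}

#' Bidirectional LSTM over one feature map
#'
#' Runs one LSTM forward over the rows of `X` and a second LSTM over
#' the reversed rows, re-reverses the backward outputs so they align
#' by position, and concatenates: row t is `[h_fwd_t ; h_bwd_t]`.
#' Both directions start from zero states.
#'
#' @param X a `length x input` numeric matrix.
#' @param fwd,bwd LSTM parameter lists (see [lstm_cell_step()]).
#' @return A `length x (2 * hidden)` matrix.
#' @export
bilstm_forward <- function(X, fwd, bwd) {
  if (!is.matrix(X) || nrow(X) == 0L) stop("empty input sequence")
  Hf <- lstm_run(X, fwd)
  Hb <- lstm_run(X[rev(seq_len(nrow(X))), , drop = FALSE], bwd)
  cbind(Hf, Hb[rev(seq_len(nrow(X))), , drop = FALSE])
}

as_cube <- function(enc) {
  # single encoding matrix -> 30 x d x 1 array
  array(enc, dim = c(nrow(enc), ncol(enc), 1L))
}

#' Forward pass of the two-branch stacked classifier
#'
#' Applies the per-branch first-layer (Bi)LSTMs, concatenates the two
#' feature maps along the time axis, runs the second-layer (Bi)LSTM,
#' pools its final forward and backward hidden states, and applies the
#' two linear layers and softmax.
#'
#' @param enc_mirna,enc_cts `30 x dim` encoding matrices
#'   ([encode_sequence()]).
#' @param model a `site_model` with `kind = "recurrent"`.
#' @return list with `logits` (length 2) and `probs` (non-binding,
#'   binding; sums to 1).
#' @export
stacked_forward <- function(enc_mirna, enc_cts, model) {
  stopifnot(inherits(model, "site_model"), model$config$kind == "recurrent")
  logits <- cpp_model_forward(as_cube(enc_mirna), as_cube(enc_cts),
                              model$params, model$config)[1, ]
  if (any(!is.finite(logits))) stop("non-finite activation in forward pass")
  list(logits = logits, probs = softmax2(logits))
}

#' Forward pass of the CNN1d baseline
#'
#' @param enc_mirna,enc_cts `30 x dim` encoding matrices.
#' @param model a `site_model` with `kind = "cnn1d"`.
#' @return list with `logits` and `probs`.
#' @export
cnn1d_forward <- function(enc_mirna, enc_cts, model) {
  stopifnot(inherits(model, "site_model"), model$config$kind == "cnn1d")
  logits <- cpp_model_forward(as_cube(enc_mirna), as_cube(enc_cts),
                              model$params, model$config)[1, ]
  if (any(!is.finite(logits))) stop("non-finite activation in forward pass")
  list(logits = logits, probs = softmax2(logits))
}

softmax2 <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Encode a dataset for the classifier
#'
#' The miRNA branch is encoded with the mi2vec table and the CTS
#' branch with the m2vec table.
#'
#' @param ds a `site_dataset` (or the result of [dataset_tokens()]).
#' @param table_mirna,table_cts `embedding_table`s of matching `dim`.
#' @return list with arrays `mirna` and `cts` (`30 x dim x n`) and
#'   `labels`.
#' @export
encode_dataset <- function(ds, table_mirna, table_cts = table_mirna) {
  stopifnot(table_mirna$dim == table_cts$dim)
  tok <- if (inherits(ds, "site_dataset")) dataset_tokens(ds) else ds
  d <- table_mirna$dim
  n <- nrow(tok$mirna)
  build <- function(mat, tab) {
    lut <- rbind(tab$input_vectors, tab$pad_vector)
    # (n*30) x d rows -> 30 x d x n
    aperm(array(lut[t(mat), ], dim = c(MODEL_LENGTH, n, d)), c(1, 3, 2))
  }
  list(
    mirna = build(tok$mirna, table_mirna),
    cts = build(tok$cts, table_cts),
    labels = tok$labels
  )
}

#' Predict binding probabilities for an encoded dataset
#'
#' @param model a `site_model`.
#' @param enc the result of [encode_dataset()].
#' @return Numeric vector of binding-class probabilities.
#' @export
predict_binding <- function(model, enc) {
  logits <- cpp_model_forward(enc$mirna, enc$cts, model$params, model$config)
  if (any(!is.finite(logits))) stop("non-finite activation in forward pass")
  p <- exp(logits - apply(logits, 1, max))
  (p / rowSums(p))[, 2]
}

# --- checkpoint format: plain text, bit-exact round trip ----------------

#' Write a model checkpoint
#'
#' A single plain-text archive holding the config and every parameter
#' tensor by name, printed with 17 significant digits (bit-exact
#' round trip).
#'
#' @param model a `site_model`.
#' @param path output path.
#' @param digest optional provenance string.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(model, path, digest = NULL) {
  stopifnot(inherits(model, "site_model"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(digest)) writeLines(paste0("# config_digest: ", digest), con)
  writeLines(paste0("config\t", jsonlite::toJSON(
    unclass(model$config),
    auto_unbox = TRUE
  )), con)
  write_tensor <- function(name, x) {
    if (is.matrix(x)) {
      writeLines(sprintf("tensor\t%s\tmat\t%d\t%d", name, nrow(x), ncol(x)), con)
      for (i in seq_len(nrow(x))) {
        writeLines(paste(sprintf("%.17g", x[i, ]), collapse = "\t"), con)
      }
    } else {
      writeLines(sprintf("tensor\t%s\tvec\t%d", name, length(x)), con)
      writeLines(paste(sprintf("%.17g", x), collapse = "\t"), con)
    }
  }
  walk <- function(prefix, obj) {
    if (is.list(obj)) {
      for (nm in names(obj)) walk(paste0(prefix, if (nzchar(prefix)) "." else "", nm), obj[[nm]])
    } else {
      write_tensor(prefix, obj)
    }
  }
  walk("", model$params)
  invisible(path)
}

#' Read a model checkpoint written by [write_checkpoint()]
#'
#' @param path checkpoint path.
#' @return A `site_model`.
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: '%s'", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "# ")]
  cfg_line <- lines[startsWith(lines, "config\t")][1]
  cfg <- jsonlite::fromJSON(sub("^config\t", "", cfg_line))
  if (!is.null(cfg$arch)) cfg$arch <- as.character(cfg$arch)
  for (nm in intersect(c("dim", "hidden1", "hidden2", "linear1",
                         "filters", "kernel", "pool", "flat"), names(cfg))) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  config <- structure(cfg, class = "model_config")
  params <- list()
  i <- which(startsWith(lines, "tensor\t"))
  for (at in i) {
    hdr <- strsplit(lines[at], "\t", fixed = TRUE)[[1]]
    name <- hdr[2]
    if (hdr[3] == "mat") {
      nr <- as.integer(hdr[4])
      rows <- lines[(at + 1):(at + nr)]
      x <- do.call(rbind, lapply(strsplit(rows, "\t", fixed = TRUE), as.numeric))
    } else {
      x <- as.numeric(strsplit(lines[at + 1], "\t", fixed = TRUE)[[1]])
    }
    # place into nested list by dotted path
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    params <- assign_path(params, parts, x)
  }
  structure(list(config = config, params = params), class = "site_model")
}

assign_path <- function(lst, parts, value) {
  if (length(parts) == 1L) {
    lst[[parts]] <- value
    return(lst)
  }
  if (is.null(lst[[parts[1]]])) lst[[parts[1]]] <- list()
  lst[[parts[1]]] <- assign_path(lst[[parts[1]]], parts[-1], value)
  lst
}

# flatten/unflatten parameter lists (used for finite-difference checks)
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, template) {
  pos <- 0L
  fill <- function(obj) {
    if (is.list(obj)) {
      for (nm in names(obj)) obj[[nm]] <- fill(obj[[nm]])
      obj
    } else {
      n <- length(obj)
      out <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (is.matrix(obj)) {
        matrix(out, nrow(obj), ncol(obj))
      } else {
        out
      }
    }
  }
  fill(template)
}
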