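# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive (scalar loops, brute force) so
# it cannot share a bug with the vectorised / C++ implementation paths.

# -- scalar recurrent-cell oracles ---------------------------------------

sigmoid_s <- function(z) 1 / (1 + exp(-z))

# LSTM step written with explicit scalar loops
scalar_lstm_step <- function(x, h_prev, c_prev, p) {
  H <- length(h_prev)
  z <- c(h_prev, x)
  gate <- function(W, b, act) {
    out <- numeric(H)
    for (r in seq_len(H)) {
      s <- b[r]
      for (k in seq_along(z)) s <- s + W[r, k] * z[k]
      out[r] <- act(s)
    }
    out
  }
  f <- gate(p$W_f, p$b_f, sigmoid_s)
  i <- gate(p$W_i, p$b_i, sigmoid_s)
  g <- gate(p$W_c, p$b_c, tanh)
  cc <- numeric(H)
  hh <- numeric(H)
  o <- gate(p$W_o, p$b_o, sigmoid_s)
  for (r in seq_len(H)) {
    cc[r] <- f[r] * c_prev[r] + i[r] * g[r]
    hh[r] <- o[r] * tanh(cc[r])
  }
  list(h = hh, c = cc)
}

scalar_gru_step <- function(x, h_prev, p) {
  z <- c(h_prev, x)
  zg <- sigmoid_s(as.numeric(p$W_z %*% z) + p$b_z)
  r <- sigmoid_s(as.numeric(p$W_r %*% z) + p$b_r)
  zn <- c(r * h_prev, x)
  n <- tanh(as.numeric(p$W_n %*% zn) + p$b_n)
  (1 - zg) * n + zg * h_prev
}

scalar_rnn_step <- function(x, h_prev, p) {
  tanh(as.numeric(p$W %*% c(h_prev, x)) + p$b)
}

scalar_run <- function(X, p, type) {
  H <- matrix(0, nrow(X), length(p[[length(p)]]))
  h <- numeric(ncol(H))
  cst <- numeric(ncol(H))
  for (t in seq_len(nrow(X))) {
    if (type == "lstm") {
      st <- scalar_lstm_step(X[t, ], h, cst, p)
      h <- st$h
      cst <- st$c
    } else if (type == "gru") {
      h <- scalar_gru_step(X[t, ], h, p)
    } else {
      h <- scalar_rnn_step(X[t, ], h, p)
    }
    H[t, ] <- h
  }
  H
}

rand_cell <- function(type, hidden, input, scale = 0.5) {
  p <- list()
  for (nm in mirsite:::cell_param_names(type)) {
    p[[nm]] <- if (startsWith(nm, "W")) {
      matrix(runif(hidden * (hidden + input), -scale, scale), hidden, hidden + input)
    } else {
      runif(hidden, -scale, scale)
    }
  }
  p
}

# -- brute-force evaluation oracles --------------------------------------

brute_confusion <- function(scores, labels, threshold) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(scores)) {
    pred <- scores[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1L
    if (pred && labels[i] == 0) fp <- fp + 1L
    if (!pred && labels[i] == 0) tn <- tn + 1L
    if (!pred && labels[i] == 1) fn <- fn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# AUC as the all-pairs Mann-Whitney statistic
mw_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# AP by exhaustive enumeration of distinct thresholds, accumulated
# from the low-recall end (independent ordering from the implementation)
enum_ap <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0
  ap <- 0
  for (t in thr) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    r <- tp / sum(labels == 1)
    p <- tp / (tp + fp)
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

# -- fixtures -------------------------------------------------------------

# corpus with strong co-occurrence structure: A pairs with G, C with U
structured_corpus <- function(n_sent = 60, len = 22, seed = 1) {
  set.seed(seed)
  half <- n_sent %/% 2
  c(
    lapply(seq_len(half), function(i) sample(c(1L, 3L), len, replace = TRUE)),
    lapply(seq_len(n_sent - half), function(i) sample(c(2L, 4L), len, replace = TRUE))
  )
}

tiny_dataset <- function(n_pos = 30, n_neg = 30, seed = 1, noise = 0) {
  generate_dataset(synthetic_config(
    n_positive = n_pos, n_negative = n_neg,
    label_noise = noise, rng_seed = seed
  ))
}

table_from_matrix <- function(M, molecule = "miRNA", output = NULL) {
  mirsite:::new_embedding_table(M, output, molecule, ncol(M))
}

# central finite-difference gradient of f at x
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- x
    e[i] <- e[i] + h
    up <- f(e)
    e[i] <- x[i] - h
    (up - f(e)) / (2 * h)
  }, numeric(1))
}
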