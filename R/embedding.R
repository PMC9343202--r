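# Distributed nucleotide representations: skip-gram training on miRNA
# (mi2vec) and mRNA (m2vec) corpora, the one-hot baseline, and
# similarity analytics.

#' Skip-gram training configuration
#'
#' @param dim embedding dimension d; the comparison grid used for the
#'   encoding experiments is {2, 4, 10, 20, 30, 50, 100}, with 50 the
#'   default classifier input.
#' @param window context distance c: positions within `window` of the
#'   centre nucleotide are training contexts.
#' @param min_count minimum token frequency for vocabulary inclusion
#'   (with single-nucleotide tokens and `min_count = 1`, nothing is
#'   excluded).
#' @param epochs passes over the corpus.
#' @param negative_samples negatives k drawn per (centre, context) pair.
#' @param learning_rate initial SGD learning rate, decayed linearly to
#'   1e-4 of its initial value over all updates.
#' @param seed integer seed; training is bit-deterministic given it.
#' @return A `skipgram_config` list.
#' @export
skipgram_config <- function(dim = 50L, window = 5L, min_count = 1L,
                            epochs = 10L, negative_samples = 5L,
                            learning_rate = 0.025, seed = 1L) {
  stopifnot(dim >= 1, window >= 1, epochs >= 1, negative_samples >= 1,
            learning_rate > 0)
  structure(
    list(
      dim = as.integer(dim), window = as.integer(window),
      min_count = as.integer(min_count), epochs = as.integer(epochs),
      negative_samples = as.integer(negative_samples),
      learning_rate = learning_rate, seed = as.integer(seed)
    ),
    class = "skipgram_config"
  )
}

new_embedding_table <- function(input_vectors, output_vectors, molecule, dim) {
  rownames(input_vectors) <- RNA_TOKENS
  if (!is.null(output_vectors)) rownames(output_vectors) <- RNA_TOKENS
  structure(
    list(
      molecule = molecule,
      dim = as.integer(dim),
      input_vectors = input_vectors,
      output_vectors = output_vectors,
      pad_vector = numeric(dim)
    ),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %s, dim %d\n", x$molecule, x$dim))
  invisible(x)
}

#' Turn raw sequence records into a token corpus
#'
#' Each sequence becomes one "sentence" of nucleotide tokens, the unit
#' the skip-gram window slides over. No padding is applied. Sequences
#' that are empty after normalisation (e.g. all ambiguity codes under
#' the `skip` policy) are dropped with a warning.
#'
#' @param records character vector of raw sequences, or a data.frame
#'   from [read_fasta()].
#' @param alphabet an [rna_alphabet()]; the default `skip` policy
#'   tolerates ambiguity codes in public corpora.
#' @return A list of integer token vectors.
#' @export
build_corpus <- function(records, alphabet = rna_alphabet("skip")) {
  if (is.data.frame(records)) records <- records$seq
  if (length(records) == 0L) stop("empty corpus")
  sentences <- lapply(records, function(s) {
    if (!nzchar(s)) return(integer(0))
    normalize_and_tokenize(s, alphabet)$tokens
  })
  empty <- vapply(sentences, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d sentence(s) empty after normalization", sum(empty)))
    sentences <- sentences[!empty]
  }
  if (length(sentences) == 0L) stop("empty corpus")
  sentences
}

#' Enumerate skip-gram (centre, context) pairs of one sentence
#'
#' For each position n the pair (w_n, w_{n+m}) is emitted for every
#' offset m with -c <= m <= c, m != 0 that stays inside the sentence,
#' in deterministic order (n ascending, m ascending).
#'
#' @param sentence integer token vector.
#' @param window context distance c.
#' @return A 2-column integer matrix (`center`, `context`); zero rows
#'   for sentences shorter than 2 tokens.
#' @export
skipgram_pairs <- function(sentence, window = 5L) {
  n <- length(sentence)
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("center", "context")))
  if (n < 2L) return(out)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ctx <- (i - window):(i + window)
    ctx <- ctx[ctx >= 1L & ctx <= n & ctx != i]
    rows[[i]] <- cbind(center = rep(sentence[i], length(ctx)), context = sentence[ctx])
  }
  do.call(rbind, rows)
}

#' Negative-sampling loss and gradients for one skip-gram pair
#'
#' Reference implementation of the negative-sampling surrogate of the
#' skip-gram objective:
#' loss = -log sigma(v'_ctx . v_ctr) - sum_neg log sigma(-v'_neg . v_ctr).
#' Gradients are returned only for the touched vectors: the centre
#' input vector, the context output vector, and each negative's output
#' vector. The C++ trainer applies exactly these updates.
#'
#' @param center,context token indices (1-4).
#' @param table an `embedding_table` with input and output vectors.
#' @param negatives integer vector of sampled negative tokens
#'   (must not contain `context`).
#' @return list with `loss`, `grad_center`, `grad_context`,
#'   `grad_negatives` (one row per negative).
#' @export
skipgram_loss_and_grads <- function(center, context, table, negatives) {
  stopifnot(inherits(table, "embedding_table"), !is.null(table$output_vectors))
  if (context %in% negatives) stop("negatives must exclude the true context token")
  v <- table$input_vectors[center, ]
  vp_ctx <- table$output_vectors[context, ]
  sig <- function(z) 1 / (1 + exp(-z))
  s_pos <- sig(sum(vp_ctx * v))
  loss <- -log(s_pos)
  g_center <- (s_pos - 1) * vp_ctx
  g_ctx <- (s_pos - 1) * v
  g_neg <- matrix(0, nrow = length(negatives), ncol = table$dim)
  for (j in seq_along(negatives)) {
    vp_n <- table$output_vectors[negatives[j], ]
    s_neg <- sig(sum(vp_n * v))
    loss <- loss - log(1 - s_neg)
    g_center <- g_center + s_neg * vp_n
    g_neg[j, ] <- s_neg * v
  }
  list(loss = loss, grad_center = g_center, grad_context = g_ctx,
       grad_negatives = g_neg)
}

#' Full-softmax context distribution over the 4-token vocabulary
#'
#' The exact softmax P(w | centre) = exp(v'_w . v_ctr) / sum_w' exp(...),
#' practical here because the vocabulary has only four nucleotides.
#' Used as a reference for the negative-sampling surrogate.
#'
#' @param table an `embedding_table`.
#' @param center token index (1-4).
#' @return Named numeric vector of 4 probabilities summing to 1.
#' @export
skipgram_softmax <- function(table, center) {
  stopifnot(!is.null(table$output_vectors))
  z <- as.numeric(table$output_vectors %*% table$input_vectors[center, ])
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  setNames(p, RNA_TOKENS)
}

#' Train a skip-gram embedding table on a token corpus
#'
#' Stochastic gradient descent over all (centre, context) pairs with
#' negative sampling from the unigram^(3/4) noise distribution,
#' linearly decaying learning rate, and deterministic seeding. The
#' returned representation is the table of input vectors; output
#' vectors are retained for auditing and the softmax reference.
#'
#' @param corpus list of integer token sentences ([build_corpus()]).
#' @param config a [skipgram_config()].
#' @param molecule `"miRNA"` (mi2vec) or `"mRNA"` (m2vec).
#' @return An `embedding_table` with attribute `epoch_loss` (mean
#'   negative-sampling loss per epoch).
#' @export
train_skipgram <- function(corpus, config = skipgram_config(),
                           molecule = c("miRNA", "mRNA")) {
  molecule <- match.arg(molecule)
  stopifnot(inherits(config, "skipgram_config"))
  if (length(corpus) == 0L) stop("empty corpus")
  counts <- tabulate(unlist(corpus), nbins = 4L)
  vocab <- which(counts >= config$min_count)
  if (length(vocab) == 0L) stop("vocabulary empty after min_count filtering")
  fit <- cpp_skipgram_train(
    lapply(corpus, function(s) as.integer(s[s %in% vocab] - 1L)),
    dim = config$dim, window = config$window, epochs = config$epochs,
    k_neg = config$negative_samples, lr0 = config$learning_rate,
    counts = as.numeric(counts), seed = config$seed
  )
  tab <- new_embedding_table(fit$input_vectors, fit$output_vectors,
                             molecule, config$dim)
  losses <- as.numeric(fit$epoch_loss)
  half <- losses[seq.int(ceiling(length(losses) / 2), length(losses))]
  if (length(half) > 1 && any(diff(half) > 1e-8)) {
    warning("mean skip-gram loss increased during the final half of training")
  }
  attr(tab, "epoch_loss") <- losses
  tab
}

#' One-hot baseline encoder
#'
#' The sparse orthogonal baseline: each nucleotide is a standard basis
#' vector in 4 dimensions, PAD is the zero vector.
#'
#' @param alphabet an [rna_alphabet()] (token order fixes row order).
#' @return An `embedding_table` with `dim = 4`.
#' @export
one_hot_table <- function(alphabet = rna_alphabet()) {
  new_embedding_table(diag(4), NULL, molecule = "miRNA", dim = 4L)
}

#' Encode a padded token sequence as a real matrix
#'
#' Row t is the embedding vector of the t-th nucleotide; PAD rows are
#' the zero vector.
#'
#' @param ts a padded `token_seq`.
#' @param table an `embedding_table`.
#' @return A `padded_length x dim` numeric matrix.
#' @export
encode_sequence <- function(ts, table) {
  stopifnot(inherits(ts, "token_seq"), inherits(table, "embedding_table"))
  if (ts$original_length == 0L) stop("cannot encode an empty sequence")
  lut <- rbind(table$input_vectors, table$pad_vector)
  lut[ts$tokens, , drop = FALSE]
}

#' Pairwise cosine similarity between nucleotide vectors
#'
#' Cosine distance, when asked for, is `1 - similarity`.
#'
#' @param table an `embedding_table`.
#' @param distance if `TRUE` return cosine distance instead.
#' @return A symmetric 4 x 4 matrix (diagonal 1 for similarity).
#' @export
cosine_similarity_matrix <- function(table, distance = FALSE) {
  V <- table$input_vectors
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0)) {
    stop(sprintf("zero-norm vector for token %s", RNA_TOKENS[which(nrm == 0)[1]]))
  }
  U <- V / nrm
  M <- U %*% t(U)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  dimnames(M) <- list(RNA_TOKENS, RNA_TOKENS)
  if (distance) 1 - M else M
}

#' Write an embedding table as tab-separated text
#'
#' Format: a header line `molecule<TAB>dim`, then one line per token
#' `TOKEN<TAB>v1<TAB>...<TAB>vd`. Values are printed with 17
#' significant digits so the round-trip is bit-exact. Output vectors,
#' when present, follow under a `#output` marker line.
#'
#' @param table an `embedding_table`.
#' @param path output path.
#' @param digest optional provenance comment.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(table, path, digest = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(digest)) writeLines(paste0("# config_digest: ", digest), con)
  writeLines(paste(table$molecule, table$dim, sep = "\t"), con)
  fmt <- function(M) {
    vapply(seq_len(nrow(M)), function(i) {
      paste(c(RNA_TOKENS[i], sprintf("%.17g", M[i, ])), collapse = "\t")
    }, character(1))
  }
  writeLines(fmt(table$input_vectors), con)
  if (!is.null(table$output_vectors)) {
    writeLines("#output", con)
    writeLines(fmt(table$output_vectors), con)
  }
  invisible(path)
}

#' Read an embedding table written by [write_embedding_table()]
#'
#' @param path path to the TSV file.
#' @return An `embedding_table`.
#' @export
read_embedding_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("embedding table not found: '%s'", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "# ")]
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  molecule <- hdr[1]
  dim <- as.integer(hdr[2])
  body <- lines[-1]
  out_at <- which(body == "#output")
  parse_block <- function(bl) {
    M <- matrix(0, nrow = 4, ncol = dim)
    for (ln in bl) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      i <- match(parts[1], RNA_TOKENS)
      M[i, ] <- as.numeric(parts[-1])
    }
    M
  }
  if (length(out_at) == 1L) {
    inp <- parse_block(body[seq_len(out_at - 1L)])
    outp <- parse_block(body[-seq_len(out_at)])
  } else {
    inp <- parse_block(body)
    outp <- NULL
  }
  new_embedding_table(inp, outp, molecule, dim)
}
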