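# Synthetic site-pair generator: positives carry a reverse-complement
# match to the miRNA seed region (nucleotides 2-8) inside the CTS,
# negatives are rejection-sampled to lack it. This reproduces the
# statistical structure the classifier is meant to learn - seed-region
# Watson-Crick complementarity - without any database download.

#' Synthetic dataset configuration
#'
#' Defaults emulate site-level interaction data: mature-miRNA lengths
#' 19-26 nt, candidate sites 20-30 nt (the 30-nt model window),
#' seed region = miRNA positions 2-8 (1-based, inclusive), balanced
#' classes, uniform base composition, no label noise.
#'
#' @param n_positive,n_negative class counts (exact).
#' @param mirna_length_range inclusive miRNA length range, nt.
#' @param cts_length_range inclusive CTS length range, nt.
#' @param seed_region 1-based inclusive positions of the seed heptamer.
#' @param label_noise probability in `[0, 1)` of flipping each label.
#' @param base_composition probabilities of A, C, G, U (sums to 1).
#' @param rng_seed integer seed; generation is deterministic given it.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_positive = 1000L, n_negative = 1000L,
                             mirna_length_range = c(19L, 26L),
                             cts_length_range = c(20L, 30L),
                             seed_region = c(2L, 8L),
                             label_noise = 0,
                             base_composition = rep(0.25, 4),
                             rng_seed = 1L) {
  stopifnot(
    n_positive >= 0, n_negative >= 0, n_positive + n_negative >= 2,
    length(mirna_length_range) == 2, length(cts_length_range) == 2,
    mirna_length_range[1] >= seed_region[2],
    cts_length_range[1] >= diff(seed_region) + 1,
    cts_length_range[2] <= MODEL_LENGTH,
    label_noise >= 0, label_noise < 1,
    length(base_composition) == 4, all(base_composition > 0)
  )
  structure(
    list(
      n_positive = as.integer(n_positive), n_negative = as.integer(n_negative),
      mirna_length_range = as.integer(mirna_length_range),
      cts_length_range = as.integer(cts_length_range),
      seed_region = as.integer(seed_region),
      label_noise = label_noise,
      base_composition = base_composition / sum(base_composition),
      rng_seed = as.integer(rng_seed)
    ),
    class = "synthetic_config"
  )
}

#' Reverse complement of an RNA sequence
#'
#' A pairs with U and C with G; the order is reversed (the antiparallel
#' strand a binding site presents to the miRNA). An involution.
#'
#' @param x a `token_seq` without PAD tokens, or a character string.
#' @return Same type as the input.
#' @export
reverse_complement <- function(x) {
  if (is.character(x)) {
    return(detokenize(reverse_complement(normalize_and_tokenize(x))))
  }
  stopifnot(inherits(x, "token_seq"))
  if (any(x$tokens == PAD_INDEX)) stop("reverse_complement: PAD tokens present")
  comp <- c(4L, 3L, 2L, 1L) # A<->U, C<->G
  new_token_seq(rev(comp[x$tokens]), x$original_length)
}

random_seq <- function(len, composition) {
  paste(sample(RNA_TOKENS, len, replace = TRUE, prob = composition), collapse = "")
}

#' Generate one labelled miRNA/CTS pair
#'
#' The miRNA is drawn i.i.d. from the base composition at a uniform
#' length in range. For a positive, the CTS is random background with
#' the reverse complement of the miRNA seed heptamer planted at a
#' uniform offset; for a negative, the CTS is resampled by rejection
#' until it contains no exact reverse complement of the seed. The
#' label is then flipped with probability `label_noise`. Uses the
#' current R RNG state (seed at the dataset level).
#'
#' @param positive logical: construct a seed-matched pair?
#' @param config a [synthetic_config()].
#' @return list with `mirna_seq`, `cts_seq`, `label` and
#'   `constructed_positive`.
#' @export
generate_pair <- function(positive, config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  mlen <- sample(seq(config$mirna_length_range[1], config$mirna_length_range[2]), 1L)
  mirna <- random_seq(mlen, config$base_composition)
  seed7 <- substr(mirna, config$seed_region[1], config$seed_region[2])
  site <- reverse_complement(seed7)
  k <- nchar(site)
  clen <- sample(seq(config$cts_length_range[1], config$cts_length_range[2]), 1L)
  if (positive) {
    cts <- random_seq(clen, config$base_composition)
    off <- sample(seq_len(clen - k + 1L), 1L)
    substr(cts, off, off + k - 1L) <- site
  } else {
    for (try in seq_len(1000L)) {
      cts <- random_seq(clen, config$base_composition)
      if (!grepl(site, cts, fixed = TRUE)) break
      if (try == 1000L) stop("rejection sampling failed after 1000 draws")
    }
  }
  label <- as.integer(positive)
  if (config$label_noise > 0 && runif(1) < config$label_noise) label <- 1L - label
  list(mirna_seq = mirna, cts_seq = cts, label = label,
       constructed_positive = positive)
}

#' Generate a labelled synthetic site-pair dataset
#'
#' Produces exactly `n_positive` seed-matched and `n_negative`
#' unmatched constructions (before label noise), plus companion
#' corpora - all miRNA sequences, and all CTS sequences standing in
#' for the mRNA corpus - so the embedding tables can be pretrained on
#' matched data. Byte-deterministic given `rng_seed`.
#'
#' @param config a [synthetic_config()].
#' @return A `site_dataset` with attributes `mirna_corpus`,
#'   `cts_corpus` (character vectors) and `truth`
#'   (constructed class before noise).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$rng_seed)
  flags <- c(rep(TRUE, config$n_positive), rep(FALSE, config$n_negative))
  pairs <- lapply(flags, generate_pair, config = config)
  ds <- site_dataset(
    pair_id = sprintf("pair_%05d", seq_along(pairs)),
    mirna_seq = vapply(pairs, `[[`, character(1), "mirna_seq"),
    cts_seq = vapply(pairs, `[[`, character(1), "cts_seq"),
    label = vapply(pairs, `[[`, integer(1), "label")
  )
  attr(ds, "mirna_corpus") <- ds$pairs$mirna_seq
  attr(ds, "cts_corpus") <- ds$pairs$cts_seq
  attr(ds, "truth") <- as.integer(flags)
  ds
}

#' Rule-based seed-match detector
#'
#' Predicts binding iff the CTS contains the exact reverse complement
#' of the miRNA seed region. On noise-free synthetic data this rule is
#' the generative definition of the classes, so it scores accuracy 1 -
#' the ceiling a learned model approaches.
#'
#' @param ds a `site_dataset`.
#' @param seed_region 1-based inclusive seed positions.
#' @return Integer vector of predictions (1 = binding).
#' @export
seed_match_detector <- function(ds, seed_region = c(2L, 8L)) {
  stopifnot(inherits(ds, "site_dataset"))
  vapply(seq_len(nrow(ds$pairs)), function(i) {
    seed7 <- substr(ds$pairs$mirna_seq[i], seed_region[1], seed_region[2])
    as.integer(grepl(reverse_complement(seed7), ds$pairs$cts_seq[i], fixed = TRUE))
  }, integer(1))
}

#' Write the companion corpora of a synthetic dataset as FASTA
#'
#' @param ds a dataset from [generate_dataset()].
#' @param dir output directory; writes `mirna_corpus.fa` and
#'   `mrna_corpus.fa`.
#' @return The two paths, invisibly.
#' @export
write_corpora <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mi <- attr(ds, "mirna_corpus")
  m <- attr(ds, "cts_corpus")
  if (is.null(mi) || is.null(m)) stop("dataset carries no companion corpora")
  p1 <- file.path(dir, "mirna_corpus.fa")
  p2 <- file.path(dir, "mrna_corpus.fa")
  write_fasta(mi, sprintf("mir_%05d", seq_along(mi)), p1)
  write_fasta(m, sprintf("cts_%05d", seq_along(m)), p2)
  invisible(c(p1, p2))
}
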