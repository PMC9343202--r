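# Nucleotide alphabet and tokenisation.
#
# The vocabulary is the four RNA bases plus a PAD token used to fill
# sequences to a fixed model length. Token indices are contiguous:
# A=1, C=2, G=3, U=4, PAD=5. DNA input is accepted and normalised
# to RNA (T -> U); case is ignored.

RNA_TOKENS <- c("A", "C", "G", "U")
PAD_INDEX <- 5L
PAD_SYMBOL <- "-"
MODEL_LENGTH <- 30L

#' RNA alphabet with a PAD token
#'
#' Constructs the tokenisation alphabet used throughout the package:
#' the four RNA nucleotides `A, C, G, U` plus a PAD filler token.
#' Lowercase input and DNA `T` are normalised (`t`/`T` become `U`).
#' Characters outside the alphabet (ambiguity codes such as `N`) are
#' handled according to `unknown_policy`.
#'
#' @param unknown_policy how to treat characters outside `ACGUTacgut`:
#'   `"reject"` raises an error naming the offending position (the
#'   default for labelled site pairs), `"skip"` silently drops the
#'   character (appropriate for embedding corpora), `"map_to_random"`
#'   replaces it with a base drawn uniformly at random.
#' @return An object of class `mirsite_alphabet`.
#' @examples
#' ab <- rna_alphabet()
#' normalize_and_tokenize("acgt", ab)
#' @export
rna_alphabet <- function(unknown_policy = c("reject", "skip", "map_to_random")) {
  unknown_policy <- match.arg(unknown_policy)
  structure(
    list(
      tokens = RNA_TOKENS,
      pad_token = PAD_SYMBOL,
      pad_index = PAD_INDEX,
      unknown_policy = unknown_policy
    ),
    class = "mirsite_alphabet"
  )
}

#' @export
print.mirsite_alphabet <- function(x, ...) {
  cat("RNA alphabet {A, C, G, U} + PAD; unknown_policy =", x$unknown_policy, "\n")
  invisible(x)
}

new_token_seq <- function(tokens, original_length) {
  structure(
    list(
      tokens = as.integer(tokens),
      original_length = as.integer(original_length),
      padded_length = length(tokens)
    ),
    class = "token_seq"
  )
}

#' @export
print.token_seq <- function(x, ...) {
  cat(sprintf(
    "<token_seq> %s (original %d nt, padded %d)\n",
    detokenize(x), x$original_length, x$padded_length
  ))
  invisible(x)
}

#' @export
length.token_seq <- function(x) x$padded_length

#' Normalise a raw sequence string and tokenise it
#'
#' Uppercases, maps `T` to `U`, and converts each character to its
#' token index. Unknown characters follow the alphabet's
#' `unknown_policy`.
#'
#' @param seq a single non-empty character string.
#' @param alphabet an [rna_alphabet()] object.
#' @return A `token_seq` (unpadded: `padded_length == original_length`).
#' @export
normalize_and_tokenize <- function(seq, alphabet = rna_alphabet()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("cannot tokenize an empty sequence")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  chars[chars == "T"] <- "U"
  idx <- match(chars, RNA_TOKENS)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    switch(alphabet$unknown_policy,
      reject = stop(sprintf(
        "unknown character '%s' at position %d (unknown_policy = 'reject')",
        chars[bad[1]], bad[1]
      )),
      skip = {
        idx <- idx[-bad]
      },
      map_to_random = {
        idx[bad] <- sample.int(4L, length(bad), replace = TRUE)
      }
    )
  }
  new_token_seq(idx, length(idx))
}

#' Convert a token sequence back to a string
#'
#' PAD positions are stripped, so `detokenize(normalize_and_tokenize(s))`
#' reproduces the normalised form of `s` for pure-ACGU input.
#'
#' @param ts a `token_seq`.
#' @param alphabet an [rna_alphabet()] (only its token symbols are used).
#' @return A character string over `ACGU`.
#' @export
detokenize <- function(ts, alphabet = rna_alphabet()) {
  stopifnot(inherits(ts, "token_seq"))
  real <- ts$tokens[ts$tokens != PAD_INDEX]
  paste(RNA_TOKENS[real], collapse = "")
}

#' Pad a token sequence to a fixed model length
#'
#' Appends PAD tokens on the right so the 5' end (and hence the miRNA
#' seed region, positions 2-8) stays at fixed positions. Idempotent on
#' already-padded input.
#'
#' @param ts a `token_seq`.
#' @param length target length in nt (default 30, the model window).
#' @return A `token_seq` with `padded_length == length`.
#' @export
pad_to_length <- function(ts, length = MODEL_LENGTH) {
  stopifnot(inherits(ts, "token_seq"))
  length <- as.integer(length)
  if (ts$original_length > length) {
    stop(sprintf(
      "sequence of %d nt exceeds the model window of %d nt",
      ts$original_length, length
    ))
  }
  real <- ts$tokens[ts$tokens != PAD_INDEX]
  out <- new_token_seq(c(real, rep(PAD_INDEX, length - base::length(real))), base::length(real))
  out
}
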