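# FASTA corpora and the site-pair TSV exchange format.

#' Read a FASTA file of miRNA or mRNA sequences
#'
#' Reads every record of a (possibly line-wrapped) FASTA file,
#' preserving identifiers verbatim. Records with an empty sequence are
#' skipped with a warning. No alphabet normalisation is applied here;
#' see [normalize_and_tokenize()].
#'
#' @param path path to a FASTA file.
#' @param molecule `"miRNA"` or `"mRNA"`; stored as an attribute on the
#'   result and used to label embedding tables trained from it.
#' @return A data.frame with columns `id` and `seq`, one row per
#'   non-empty record, with attribute `molecule`.
#' @export
read_fasta <- function(path, molecule = c("miRNA", "mRNA")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop(sprintf("FASTA file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop(sprintf("'%s' is empty", path))
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("'%s' is not FASTA: line %d does not start with '>'", path, first))
  }
  set <- Biostrings::readBStringSet(path)
  w <- Biostrings::width(set)
  if (any(w == 0L)) {
    empty <- names(set)[w == 0L]
    warning(sprintf(
      "skipping %d empty FASTA record(s): %s",
      length(empty), paste(empty, collapse = ", ")
    ))
    set <- set[w > 0L]
  }
  if (length(set) == 0L) stop(sprintf("no non-empty records in '%s'", path))
  out <- data.frame(
    id = names(set),
    seq = as.character(set),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "molecule") <- molecule
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs character vector of sequences.
#' @param ids identifiers, same length as `seqs`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, ids, path) {
  stopifnot(length(seqs) == length(ids))
  set <- Biostrings::BStringSet(setNames(as.character(seqs), ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

new_site_dataset <- function(pairs, fold_of = NULL) {
  structure(list(pairs = pairs, fold_of = fold_of), class = "site_dataset")
}

#' Build a site-pair dataset from sequence vectors
#'
#' Normalises every sequence to RNA, validates lengths (<= 30 nt) and
#' labels, and assembles the central `site_dataset` container: one row
#' per (miRNA, candidate target site) pair with a binary binding label.
#'
#' @param pair_id unique identifiers.
#' @param mirna_seq miRNA sequences (1-30 nt).
#' @param cts_seq candidate-target-site sequences (1-30 nt).
#' @param label binary vector; 1 = binding, 0 = non-binding.
#' @return A `site_dataset`.
#' @export
site_dataset <- function(pair_id, mirna_seq, cts_seq, label) {
  n <- length(pair_id)
  stopifnot(length(mirna_seq) == n, length(cts_seq) == n, length(label) == n)
  pair_id <- as.character(pair_id)
  if (anyDuplicated(pair_id)) {
    dup <- pair_id[duplicated(pair_id)][1]
    stop(sprintf("duplicate pair_id '%s'", dup))
  }
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) {
    bad <- pair_id[!(label %in% c(0L, 1L))][1]
    stop(sprintf("label of pair '%s' is not 0/1", bad))
  }
  ab <- rna_alphabet("reject")
  norm <- function(s, what) {
    vapply(seq_along(s), function(i) {
      ts <- tryCatch(normalize_and_tokenize(s[i], ab), error = function(e) {
        stop(sprintf("pair '%s' (%s): %s", pair_id[i], what, conditionMessage(e)), call. = FALSE)
      })
      if (ts$original_length > MODEL_LENGTH) {
        stop(sprintf(
          "pair '%s': %s sequence of %d nt exceeds %d nt",
          pair_id[i], what, ts$original_length, MODEL_LENGTH
        ), call. = FALSE)
      }
      detokenize(ts)
    }, character(1))
  }
  pairs <- data.frame(
    pair_id = pair_id,
    mirna_seq = norm(mirna_seq, "miRNA"),
    cts_seq = norm(cts_seq, "CTS"),
    label = label,
    stringsAsFactors = FALSE
  )
  new_site_dataset(pairs)
}

#' @export
print.site_dataset <- function(x, ...) {
  tab <- table(factor(x$pairs$label, levels = c(0, 1)))
  cat(sprintf(
    "<site_dataset> %d pairs (%d binding, %d non-binding)%s\n",
    nrow(x$pairs), tab[["1"]], tab[["0"]],
    if (is.null(x$fold_of)) "" else sprintf(", %d folds", length(unique(x$fold_of)))
  ))
  invisible(x)
}

#' @export
length.site_dataset <- function(x) nrow(x$pairs)

#' Subset a site dataset by row index
#' @param ds a `site_dataset`.
#' @param idx integer or logical index into the pairs.
#' @return A `site_dataset` with the selected pairs (fold assignments kept).
#' @export
subset_pairs <- function(ds, idx) {
  stopifnot(inherits(ds, "site_dataset"))
  pairs <- ds$pairs[idx, , drop = FALSE]
  rownames(pairs) <- NULL
  fold <- if (is.null(ds$fold_of)) NULL else ds$fold_of[pairs$pair_id]
  new_site_dataset(pairs, fold)
}

#' Read a site-pair TSV file
#'
#' The exchange format is a tab-separated file with header columns
#' `pair_id`, `mirna_seq`, `cts_seq`, `label` (1 = binding). Comment
#' lines starting with `#` are ignored.
#'
#' @param path path to the TSV file.
#' @param alphabet unused beyond validation defaults; sequences are
#'   normalised with a rejecting alphabet because labelled examples
#'   must be clean.
#' @return A `site_dataset`.
#' @export
read_site_pairs <- function(path, alphabet = rna_alphabet("reject")) {
  if (!file.exists(path)) stop(sprintf("site-pair file not found: '%s'", path))
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", stringsAsFactors = FALSE)
  need <- c("pair_id", "mirna_seq", "cts_seq", "label")
  if (!all(need %in% names(tab))) {
    stop(sprintf(
      "site-pair TSV must have columns %s; found %s",
      paste(need, collapse = ", "), paste(names(tab), collapse = ", ")
    ))
  }
  ds <- site_dataset(tab$pair_id, tab$mirna_seq, tab$cts_seq, as.integer(tab$label))
  counts <- table(factor(ds$pairs$label, levels = c(0, 1)))
  message(sprintf(
    "read %d site pairs from '%s' (%s binding, %s non-binding)",
    nrow(ds$pairs), path, counts[["1"]], counts[["0"]]
  ))
  ds
}

#' Write a site-pair TSV file
#'
#' @param ds a `site_dataset`.
#' @param path output path.
#' @param digest optional provenance string written as a `#` comment line.
#' @return `path`, invisibly.
#' @export
write_site_pairs <- function(ds, path, digest = NULL) {
  stopifnot(inherits(ds, "site_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(digest)) writeLines(paste0("# config_digest: ", digest), con)
  writeLines(paste(c("pair_id", "mirna_seq", "cts_seq", "label"), collapse = "\t"), con)
  writeLines(
    paste(ds$pairs$pair_id, ds$pairs$mirna_seq, ds$pairs$cts_seq, ds$pairs$label, sep = "\t"),
    con
  )
  invisible(path)
}

#' Token matrices for a dataset
#'
#' Tokenises and right-pads every sequence to the 30-nt model window,
#' returning dense integer matrices ready for encoding.
#'
#' @param ds a `site_dataset`.
#' @return list with `mirna` and `cts` (n x 30 integer matrices of
#'   token indices, PAD = 5) and `labels`.
#' @export
dataset_tokens <- function(ds) {
  stopifnot(inherits(ds, "site_dataset"))
  tok <- function(seqs) {
    t(vapply(seqs, function(s) {
      pad_to_length(normalize_and_tokenize(s))$tokens
    }, integer(MODEL_LENGTH), USE.NAMES = FALSE))
  }
  list(
    mirna = tok(ds$pairs$mirna_seq),
    cts = tok(ds$pairs$cts_seq),
    labels = ds$pairs$label
  )
}
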