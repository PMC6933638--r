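#' Read RNA sequences from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file and normalizes residues to the
#' RNA alphabet: lowercase is uppercased, `T` becomes `U`, and any character
#' outside `{A,C,G,U}` is stored as `N`. Record ids are preserved verbatim
#' (the full header line up to the first whitespace is the id, matching the
#' usual FASTA convention).
#'
#' Family labels can be attached from a sidecar two-column TSV
#' (`<seq_id>\t<family>`, no header) or, as a fallback, from an `id|family`
#' convention in the FASTA header itself.
#'
#' @param path Path to a FASTA file.
#' @param labels Optional path to a labels TSV. Ids present in the TSV but
#'   absent from the FASTA are skipped with a warning.
#' @return A data frame of class `rna_set` with columns `id`, `residues`,
#'   `family` (`NA` when unlabelled).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), fa)
#' read_rna_fasta(fa)$residues  # "ACGU"
#' @export
read_rna_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- names(set)
  if (is.null(headers)) headers <- character(0)
  ids <- sub("\\s.*$", "", headers)
  residues <- vapply(as.character(set), normalize_residues, character(1),
                     USE.NAMES = FALSE)
  bad <- which(nchar(residues) == 0L)
  if (length(bad)) {
    stop("malformed FASTA: record '", ids[bad[1]], "' has an empty sequence")
  }
  family <- rep(NA_character_, length(ids))
  # header fallback convention: ">id|family"
  piped <- grepl("|", ids, fixed = TRUE)
  if (any(piped)) {
    family[piped] <- sub("^[^|]*\\|", "", ids[piped])
    ids[piped] <- sub("\\|.*$", "", ids[piped])
  }
  x <- rna_set(ids, residues, family)
  if (!is.null(labels)) {
    lab <- utils::read.table(labels, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             col.names = c("id", "family"))
    missing <- setdiff(lab$id, x$id)
    if (length(missing)) {
      warning(length(missing), " label id(s) absent from FASTA, skipped: ",
              paste(utils::head(missing, 5), collapse = ", "))
    }
    hit <- match(x$id, lab$id)
    x$family[!is.na(hit)] <- lab$family[hit[!is.na(hit)]]
  }
  x
}

#' Construct an rna_set from vectors
#'
#' The in-memory representation of a set of RNA sequences: a data frame with
#' `id`, `residues` and `family` columns. Residues are normalized on
#' construction (uppercase, T to U, non-alphabet to N).
#'
#' @param id Character vector of sequence ids.
#' @param residues Character vector of sequences.
#' @param family Optional character vector of family labels (`NA` allowed).
#' @return A data frame of class `rna_set`.
#' @export
rna_set <- function(id, residues, family = NA_character_) {
  stopifnot(length(id) == length(residues))
  residues <- vapply(residues, normalize_residues, character(1),
                     USE.NAMES = FALSE)
  if (length(residues) && any(nchar(residues) < 1L)) {
    stop("all sequences must have length >= 1")
  }
  x <- data.frame(id = as.character(id), residues = residues,
                  family = rep_len(as.character(family), length(id)),
                  stringsAsFactors = FALSE)
  class(x) <- c("rna_set", "data.frame")
  x
}

# uppercase, T->U, anything outside ACGU -> N
normalize_residues <- function(s) {
  s <- chartr("t", "u", toupper(s))
  s <- chartr("T", "U", s)
  gsub("[^ACGU]", "N", s)
}

#' Write an rna_set to FASTA (with optional labels TSV)
#'
#' @param x An `rna_set`.
#' @param path Output FASTA path.
#' @param labels Optional path for a two-column labels TSV; written only for
#'   sequences with a non-missing family.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(x, path, labels = NULL) {
  set <- Biostrings::BStringSet(x$residues)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path)
  if (!is.null(labels)) {
    keep <- !is.na(x$family)
    utils::write.table(x[keep, c("id", "family")], labels, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Remove duplicate sequences
#'
#' Sequences with identical residue strings (after read-time normalization)
#' are reduced to their first occurrence; order is otherwise preserved. The
#' number of removed sequences is attached as attribute `n_removed`.
#'
#' @param x An `rna_set`.
#' @return The deduplicated `rna_set` with attribute `n_removed`.
#' @export
deduplicate_sequences <- function(x) {
  keep <- !duplicated(x$residues)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rna_set", "data.frame")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Assemble a labelled family dataset
#'
#' Drops sequences longer than `max_len` (they are excluded, not truncated)
#' and builds a contiguous class index over the surviving families, assigned
#' in sorted family-name order for reproducibility.
#'
#' @param x An `rna_set`; every sequence must carry a family label.
#' @param max_len Maximum sequence length kept (default 200 nt).
#' @return A `family_dataset`: list with `sequences` (an `rna_set`),
#'   `label_index` (named integer vector, family name to 0-based class id),
#'   `max_len`, and `n_excluded`.
#' @export
build_family_dataset <- function(x, max_len = 200L) {
  if (anyNA(x$family)) stop("all sequences must be labelled")
  len <- nchar(x$residues)
  keep <- len <= max_len
  n_excluded <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("rna_set", "data.frame")
  if (nrow(x) == 0L) stop("no sequences survive the length filter")
  fams <- sort(unique(x$family))
  label_index <- stats::setNames(seq_along(fams) - 1L, fams)
  structure(list(sequences = x, label_index = label_index,
                 max_len = as.integer(max_len), n_excluded = n_excluded),
            class = "family_dataset")
}

#' @export
print.family_dataset <- function(x, ...) {
  cat("family_dataset:", nrow(x$sequences), "sequences,",
      length(x$label_index), "families, max_len", x$max_len, "\n")
  invisible(x)
}

# integer class ids (0-based) for every sequence of a dataset
dataset_labels <- function(ds) {
  unname(ds$label_index[ds$sequences$family])
}
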