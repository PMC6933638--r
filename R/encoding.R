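#' Encode base-pairing probabilities as a thresholded matrix
#'
#' The probability matrix simply carries the base-pairing probability `p` at
#' cell `(i, j)` when `p >= T`, and 0 otherwise. The matrix is symmetric,
#' the diagonal is zero, and rows/columns beyond the sequence length are
#' zero padding (padding always sits at the end).
#'
#' @param bpp A `bppm` from [mccaskill_bppm()] or [read_bpp_file()].
#' @param T Probability threshold below which cells become 0
#'   (default 0.0001).
#' @param L Padded matrix size (default 200); must be >= `bpp$n`.
#' @return An `encoded_input` with an `L` x `L` grid, `kind = "probability"`.
#' @export
encode_probability <- function(bpp, T = 1e-4, L = 200L) {
  stopifnot(T >= 0, T <= 1)
  if (bpp$n > L) stop("sequence length ", bpp$n, " exceeds grid size ", L)
  grid <- matrix(0, L, L)
  keep <- bpp$p >= T
  if (any(keep)) {
    grid[cbind(bpp$i[keep], bpp$j[keep])] <- bpp$p[keep]
    grid[cbind(bpp$j[keep], bpp$i[keep])] <- bpp$p[keep]
  }
  encoded_input(grid, kind = "probability", T = T, L = L)
}

# ordered pair type -> value table (s_i s_j read in row-column order)
.pair_values_ordered <- c(AU = 1/6, UA = 2/6, CG = 3/6, GC = 4/6,
                          GU = 5/6, UG = 6/6)
.pair_values_unordered <- c(AU = 1/3, UA = 1/3, CG = 2/3, GC = 2/3,
                            GU = 3/3, UG = 3/3)

#' Encode base pairs as a categorical pair matrix
#'
#' Cells with pairing probability `p >= T` record the identity of the base
#' pair instead of its probability. With `ordered = TRUE` the six ordered
#' pair readings map to 1/6 (AU), 2/6 (UA), 3/6 (CG), 4/6 (GC), 5/6 (GU),
#' 6/6 (UG); cell `(i, j)` reads the bases in order `(s_i, s_j)` and cell
#' `(j, i)` in order `(s_j, s_i)`, so the ordered matrix is support-symmetric
#' but value-asymmetric. With `ordered = FALSE` the unordered classes map to
#' 1/3 (AU/UA), 2/3 (CG/GC), 3/3 (GU/UG) and the matrix is fully symmetric.
#'
#' @param residues Residue string (or single-row `rna_set`) the `bppm`
#'   belongs to.
#' @param bpp A `bppm`; every stored pair must join canonical or wobble
#'   partners in `residues`.
#' @param T Probability threshold (default 0.0001).
#' @param ordered Use the 6-value ordered table (default) or the 3-value
#'   unordered table.
#' @param L Padded matrix size (default 200).
#' @return An `encoded_input` with kind `"pair"`.
#' @export
encode_pairs <- function(residues, bpp, T = 1e-4, ordered = TRUE, L = 200L) {
  stopifnot(T >= 0, T <= 1)
  residues <- as_residue_string(residues)
  bases <- strsplit(residues, "")[[1]]
  n <- length(bases)
  if (n != bpp$n) stop("sequence length and bppm disagree")
  if (n > L) stop("sequence length ", n, " exceeds grid size ", L)
  tab <- if (ordered) .pair_values_ordered else .pair_values_unordered
  grid <- matrix(0, L, L)
  keep <- bpp$p >= T
  if (any(keep)) {
    i <- bpp$i[keep]; j <- bpp$j[keep]
    fwd <- paste0(bases[i], bases[j])
    rev <- paste0(bases[j], bases[i])
    if (anyNA(tab[fwd])) {
      bad <- which(is.na(tab[fwd]))[1]
      stop("non-canonical pair ", fwd[bad], " at (", i[bad], ", ", j[bad], ")")
    }
    grid[cbind(i, j)] <- unname(tab[fwd])
    grid[cbind(j, i)] <- unname(tab[rev])
  }
  encoded_input(grid, kind = "pair", T = T, ordered = ordered, L = L)
}

#' Encode probability and pair information as a two-channel matrix
#'
#' Channel 1 is the probability matrix, channel 2 the pair matrix, both
#' computed at the same threshold `T`.
#'
#' @inheritParams encode_pairs
#' @return An `encoded_input` with an `L` x `L` x 2 grid, kind `"mixed"`.
#' @export
encode_mixed <- function(residues, bpp, T = 1e-4, ordered = TRUE, L = 200L) {
  pm <- encode_probability(bpp, T = T, L = L)
  xm <- encode_pairs(residues, bpp, T = T, ordered = ordered, L = L)
  grid <- array(0, dim = c(L, L, 2))
  grid[, , 1] <- pm$grid
  grid[, , 2] <- xm$grid
  encoded_input(grid, kind = "mixed", T = T, ordered = ordered, L = L)
}

#' One-hot encode a sequence
#'
#' Row `i` carries a single 1 in the column of base `s_i`, with fixed column
#' order A, C, G, U. Rows for `N` and rows beyond the sequence length are
#' all zero.
#'
#' @param residues Residue string (or single-row `rna_set`).
#' @param L Padded length (default 200).
#' @return An `encoded_input` with an `L` x 4 grid, kind `"onehot"`.
#' @export
encode_onehot <- function(residues, L = 200L) {
  residues <- as_residue_string(residues)
  bases <- strsplit(residues, "")[[1]]
  n <- length(bases)
  if (n > L) stop("sequence length ", n, " exceeds padded length ", L)
  grid <- matrix(0, L, 4, dimnames = list(NULL, c("A", "C", "G", "U")))
  col <- match(bases, c("A", "C", "G", "U"))
  hit <- !is.na(col)
  grid[cbind(which(hit), col[hit])] <- 1
  encoded_input(grid, kind = "onehot", L = L)
}

encoded_input <- function(grid, kind, T = NA_real_, ordered = NA, L) {
  structure(list(grid = grid, kind = kind, T = T, ordered = ordered,
                 L = as.integer(L)), class = "encoded_input")
}

#' @export
print.encoded_input <- function(x, ...) {
  cat("encoded_input:", x$kind, "grid",
      paste(dim(x$grid), collapse = " x "),
      if (!is.na(x$T)) paste0("(T = ", x$T,
                              if (!is.na(x$ordered))
                                paste0(", ", if (x$ordered) "ordered"
                                       else "unordered"), ")"), "\n")
  invisible(x)
}

#' Percentile-based probability thresholds
#'
#' Pools every pairing probability greater than `floor` across a collection
#' of `bppm`s, sorts the pool, and returns the requested percentiles by the
#' nearest-rank convention (percentile 0 is the pooled minimum). This mirrors
#' picking matrix thresholds from the empirical probability distribution
#' rather than linearly spacing them on [0, 1].
#'
#' @param bppms List of `bppm` objects.
#' @param percentiles Numeric vector of percentiles in [0, 100].
#' @param floor Only probabilities strictly greater than this enter the pool
#'   (default 0.0001).
#' @return Numeric vector of threshold values, one per percentile.
#' @export
percentile_thresholds <- function(bppms, percentiles, floor = 1e-4) {
  stopifnot(all(percentiles >= 0), all(percentiles <= 100))
  pool <- sort(unlist(lapply(bppms, function(b) b$p[b$p > floor])))
  if (!length(pool)) stop("no pairing probabilities above the floor")
  m <- length(pool)
  ranks <- pmax(1L, as.integer(ceiling(percentiles / 100 * m)))
  unname(pool[ranks])
}

#' Encode every sequence of a family dataset
#'
#' Convenience wrapper used by training: computes base-pairing probabilities
#' where the encoding needs them (with [mccaskill_bppm()]) and returns the
#' encoded grids together with integer class labels.
#'
#' @param ds A `family_dataset`.
#' @param kind One of `"onehot"`, `"probability"`, `"pair"`, `"mixed"`.
#' @param T Probability threshold for the structural encodings.
#' @param ordered Ordered pair values (default TRUE).
#' @param L Padded size; defaults to the dataset's `max_len`.
#' @param params [fold_params()] for the built-in folding model.
#' @param bppms Optional pre-computed list of `bppm`s (e.g. imported via
#'   [read_bpp_file()]), parallel to the dataset's sequences.
#' @return An `encoded_dataset`: list with `inputs` (list of grids), `labels`
#'   (0-based integer classes), `label_index`, `kind`, `T`, `ordered`, `L`,
#'   `seq_len` (unpadded lengths) and `ids`.
#' @export
encode_dataset <- function(ds, kind = c("onehot", "probability", "pair",
                                        "mixed"),
                           T = 1e-4, ordered = TRUE, L = NULL,
                           params = fold_params(), bppms = NULL) {
  kind <- match.arg(kind)
  if (is.null(L)) L <- ds$max_len
  seqs <- ds$sequences
  if (kind != "onehot" && is.null(bppms)) {
    bppms <- lapply(seqs$residues, mccaskill_bppm, params = params)
  }
  inputs <- lapply(seq_len(nrow(seqs)), function(s) {
    enc <- switch(kind,
      onehot = encode_onehot(seqs$residues[s], L = L),
      probability = encode_probability(bppms[[s]], T = T, L = L),
      pair = encode_pairs(seqs$residues[s], bppms[[s]], T = T,
                          ordered = ordered, L = L),
      mixed = encode_mixed(seqs$residues[s], bppms[[s]], T = T,
                           ordered = ordered, L = L))
    enc$grid
  })
  structure(list(inputs = inputs, labels = dataset_labels(ds),
                 label_index = ds$label_index, kind = kind,
                 T = if (kind == "onehot") NA_real_ else T,
                 ordered = if (kind %in% c("pair", "mixed")) ordered else NA,
                 L = as.integer(L), seq_len = nchar(seqs$residues),
                 ids = seqs$id),
            class = "encoded_dataset")
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat("encoded_dataset:", length(x$inputs), "sequences,", x$kind,
      "encoding, L =", x$L, "\n")
  invisible(x)
}
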