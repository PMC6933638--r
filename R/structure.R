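#' Folding parameters for the built-in partition function
#'
#' The built-in folding model is pair-additive: every nested secondary
#' structure is weighted by the product of Boltzmann factors
#' `exp(-E(pair) / temperature_scale)` of its base pairs, with hairpin loops
#' of at least `min_loop` unpaired bases. Only Watson-Crick (AU/UA, CG/GC)
#' and wobble (GU/UG) pairs are allowed. Defaults make CG the strongest and
#' GU the weakest pair.
#'
#' @param pair_scores Named numeric vector of pair energies (negative =
#'   favourable, arbitrary units) for the unordered pair types `AU`, `CG`,
#'   `GU`.
#' @param min_loop Minimum number of unpaired bases enclosed by a hairpin
#'   (default 3, the standard RNA convention).
#' @param temperature_scale Positive divisor converting energy to the
#'   Boltzmann exponent.
#' @return A `fold_params` list.
#' @export
fold_params <- function(pair_scores = c(AU = -2, CG = -3, GU = -1),
                        min_loop = 3L, temperature_scale = 1) {
  stopifnot(min_loop >= 0, temperature_scale > 0,
            all(c("AU", "CG", "GU") %in% names(pair_scores)))
  structure(list(pair_scores = pair_scores, min_loop = as.integer(min_loop),
                 temperature_scale = temperature_scale),
            class = "fold_params")
}

# Boltzmann weight matrix W[i,j] for all allowed pairs of a sequence
# (0 where pairing is forbidden). 1-based, symmetric.
pair_weight_matrix <- function(bases, params) {
  n <- length(bases)
  key <- c(AU = "AU", UA = "AU", CG = "CG", GC = "CG", GU = "GU", UG = "GU")
  W <- matrix(0, n, n)
  if (n < 2) return(W)
  duo <- outer(bases, bases, paste0)
  type <- key[duo]
  ok <- !is.na(type)
  W[ok] <- exp(-params$pair_scores[type[ok]] / params$temperature_scale)
  # enforce minimum hairpin loop: |j - i| > min_loop
  span <- abs(row(W) - col(W))
  W[span <= params$min_loop] <- 0
  W
}

new_bppm <- function(n, i = integer(0), j = integer(0), p = numeric(0)) {
  structure(list(n = as.integer(n), i = as.integer(i), j = as.integer(j),
                 p = as.numeric(p)), class = "bppm")
}

#' @export
print.bppm <- function(x, ...) {
  cat("bppm: n =", x$n, "with", length(x$p), "pairing entries\n")
  invisible(x)
}

#' Base-pairing probabilities by the McCaskill partition function
#'
#' Computes exact equilibrium base-pairing probabilities under the simplified
#' pair-additive model of [fold_params()]: the Boltzmann-weighted sum over
#' all nested secondary structures (inside recursion), followed by the
#' outside recursion for pair marginals. `N` never pairs. Probabilities are
#' symmetric by construction; entries below `drop_below` are omitted from
#' the sparse result.
#'
#' @param residues A residue string over `{A,C,G,U,N}` (or a single-row
#'   `rna_set`).
#' @param params A [fold_params()] object.
#' @param drop_below Sparsity cutoff for stored entries (default 1e-12).
#' @return A `bppm`: list with `n` and parallel vectors `i < j` (1-based)
#'   and `p`.
#' @export
mccaskill_bppm <- function(residues, params = fold_params(),
                           drop_below = 1e-12) {
  residues <- as_residue_string(residues)
  bases <- strsplit(residues, "")[[1]]
  n <- length(bases)
  W <- pair_weight_matrix(bases, params)
  if (all(W == 0)) return(new_bppm(n))

  # Inside: Q[i,j] = partition function of s[i..j]; empty intervals = 1.
  # Stored padded so Q(i, i-1) and friends read 1.
  qv <- function(Q, i, j) if (j < i) 1 else Q[i, j]
  Q <- matrix(1, n, n)
  for (span in 1:(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      total <- if (j - 1 >= i) Q[i, j - 1] else 1
      ks <- which(W[, j] > 0)
      ks <- ks[ks >= i & ks < j]
      if (length(ks)) {
        # Q[i, k-1]: empty left interval (k = i) contributes 1
        left <- ifelse(ks > i, Q[cbind(rep(i, length(ks)), pmax(ks - 1, 1))], 1)
        inner <- ifelse(ks + 1 <= j - 1,
                        Q[cbind(ks + 1, rep(j - 1, length(ks)))], 1)
        total <- total + sum(left * W[cbind(ks, rep(j, length(ks)))] * inner)
      }
      Q[i, j] <- total
    }
  }
  Ztot <- Q[1, n]

  # Outside: qout[i,j] = partition over structures of the exterior of (i,j),
  # summing over the direct parent pair (k,l) enclosing (i,j).
  # qout(i,j) = Q(1,i-1) Q(j+1,n)
  #           + sum_{k<i, l>j} qout(k,l) W(k,l) Q(k+1,i-1) Q(j+1,l-1)
  pairable <- which(W > 0 & row(W) < col(W), arr.ind = TRUE)
  ord <- order(pairable[, 2] - pairable[, 1], decreasing = TRUE)
  pairable <- pairable[ord, , drop = FALSE]
  G <- matrix(0, n, n)   # qout(k,l) * W(k,l), filled outside-in
  P <- matrix(0, n, n)
  for (r in seq_len(nrow(pairable))) {
    i <- pairable[r, 1]; j <- pairable[r, 2]
    ext <- qv(Q, 1, i - 1) * qv(Q, j + 1, n)
    if (i > 1 && j < n) {
      ks <- 1:(i - 1)
      ls <- (j + 1):n
      Gsub <- G[ks, ls, drop = FALSE]
      if (any(Gsub != 0)) {
        qleft <- vapply(ks, function(k) qv(Q, k + 1, i - 1), numeric(1))
        qright <- vapply(ls, function(l) qv(Q, j + 1, l - 1), numeric(1))
        ext <- ext + drop(crossprod(qleft, Gsub %*% qright))
      }
    }
    G[i, j] <- ext * W[i, j]
    P[i, j] <- ext * W[i, j] * qv(Q, i + 1, j - 1) / Ztot
  }
  nz <- which(P > drop_below & row(P) < col(P), arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  new_bppm(n, nz[, 1], nz[, 2], P[nz])
}

#' Base-pairing probabilities by exhaustive enumeration
#'
#' Test oracle: enumerates every nested secondary structure explicitly,
#' weights each by the product of its pair Boltzmann factors, and tabulates
#' pair marginals. Exponential - refuses sequences longer than `max_n`.
#'
#' @inheritParams mccaskill_bppm
#' @param max_n Length cap on the enumeration (default 22).
#' @return A `bppm`.
#' @export
enumerate_bppm_oracle <- function(residues, params = fold_params(),
                                  max_n = 22L) {
  residues <- as_residue_string(residues)
  bases <- strsplit(residues, "")[[1]]
  n <- length(bases)
  if (n > max_n) stop("enumeration refused for n > ", max_n)
  W <- pair_weight_matrix(bases, params)
  if (all(W == 0)) return(new_bppm(n))

  # enumerate structures over [i..j]; each structure is a list(weight, pairs)
  # with pairs a 2-column matrix
  enum <- function(i, j) {
    if (j - i <= params$min_loop) {
      return(list(list(w = 1, pairs = matrix(integer(0), 0, 2))))
    }
    out <- enum(i, j - 1)                    # j unpaired
    for (k in i:(j - 1)) {
      if (W[k, j] > 0) {
        lefts <- if (k - 1 >= i) enum(i, k - 1) else
          list(list(w = 1, pairs = matrix(integer(0), 0, 2)))
        inners <- enum(k + 1, j - 1)
        for (Lp in lefts) for (Ip in inners) {
          out[[length(out) + 1L]] <- list(
            w = Lp$w * Ip$w * W[k, j],
            pairs = rbind(Lp$pairs, Ip$pairs, c(k, j)))
        }
      }
    }
    out
  }
  structs <- enum(1, n)
  Z <- sum(vapply(structs, `[[`, numeric(1), "w"))
  P <- matrix(0, n, n)
  for (st in structs) {
    if (nrow(st$pairs)) P[st$pairs] <- P[st$pairs] + st$w
  }
  P <- P / Z
  nz <- which(P > 0 & row(P) < col(P), arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  new_bppm(n, nz[, 1], nz[, 2], P[nz])
}

#' Import externally computed base-pairing probabilities
#'
#' Reads the triplet dialect `<i>\t<j>\t<p>` (1-based indices, `#` comments
#' allowed), e.g. converted from an RNAfold dot plot. Entries are reordered
#' to `i < j` and validated.
#'
#' @param path Path to the triplet TSV.
#' @param n Sequence length the probabilities refer to.
#' @return A `bppm`.
#' @export
read_bpp_file <- function(path, n) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(new_bppm(n))
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) stop("malformed triplet line ", bad[1], ": ", lines[bad[1]])
  m <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric field in triplet file")
  i <- as.integer(m[, 1]); j <- as.integer(m[, 2]); p <- m[, 3]
  if (any(i < 1 | i > n | j < 1 | j > n)) stop("index out of [1, n]")
  if (any(i == j)) stop("self-pairing entry (i == j)")
  if (any(p < 0 | p > 1)) stop("probability outside [0, 1]")
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  if (anyDuplicated(paste(i, j))) stop("duplicate (i, j) entry")
  occ <- rowSums(bppm_matrix(new_bppm(n, i, j, p)))
  if (any(occ > 1 + 1e-9)) stop("per-base pairing probability exceeds 1")
  ord <- order(i, j)
  new_bppm(n, i[ord], j[ord], p[ord])
}

#' Dense symmetric matrix view of a bppm
#'
#' @param bpp A `bppm`.
#' @return An `n` x `n` symmetric numeric matrix.
#' @export
bppm_matrix <- function(bpp) {
  M <- matrix(0, bpp$n, bpp$n)
  if (length(bpp$p)) {
    M[cbind(bpp$i, bpp$j)] <- bpp$p
    M[cbind(bpp$j, bpp$i)] <- bpp$p
  }
  M
}

# accept either a plain string or a single-row rna_set
as_residue_string <- function(x) {
  if (inherits(x, "rna_set")) {
    stopifnot(nrow(x) == 1L)
    return(x$residues)
  }
  stopifnot(is.character(x), length(x) == 1L)
  normalize_residues(x)
}
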