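# Synthetic hairpin families: a 5' arm, a loop, and a 3' arm that is the
# reverse complement of the 5' arm (with a configurable fraction of stem
# positions relaxed to G-U wobbles), plus a conserved planted "mature" motif
# inside the 5' arm. Family members are drawn by per-base point substitution.

RNA_BASES <- c("A", "C", "G", "U")

rc_base <- c(A = "U", C = "G", G = "C", U = "A")

#' Design a hairpin family template
#'
#' Builds a family consensus `[5' arm | loop | 3' arm]` where the 3' arm is
#' the reverse complement of the 5' arm, optionally with a fraction of stem
#' positions turned into G-U wobbles (so pair matrices contain 5/6 and 6/6
#' cells). A conserved motif -- the synthetic stand-in for the mature miRNA
#' -- is planted at `motif_offset` within the 5' arm.
#'
#' @param name Family name.
#' @param motif Residue string planted verbatim in the 5' arm.
#' @param arm_len Stem arm length (default 25 nt).
#' @param loop_len Loop length (default 10; must exceed the minimum hairpin
#'   loop of the folding model).
#' @param motif_offset 1-based offset of the motif in the 5' arm.
#' @param mu Per-base substitution probability when drawing members.
#' @param motif_mu Substitution probability inside the motif region
#'   (default `mu / 5`: the mature region is the conserved one).
#' @param wobble_frac Fraction of stem positions relaxed to G-U (default
#'   0.1).
#' @param seed Seed for the (deterministic) consensus design.
#' @return A `family_template`: list with `name`, `consensus`, `motif`,
#'   `motif_offset`, `arm_len`, `loop_len`, `mu`, `motif_mu`.
#' @export
family_template <- function(name, motif, arm_len = 25L, loop_len = 10L,
                            motif_offset = 8L, mu = 0.05,
                            motif_mu = mu / 5, wobble_frac = 0.1,
                            seed = 1L) {
  stopifnot(mu >= 0, mu < 1, nchar(motif) >= 1,
            motif_offset >= 1,
            motif_offset + nchar(motif) - 1L <= arm_len)
  motif <- normalize_residues(motif)
  set.seed(seed)
  arm <- sample(RNA_BASES, arm_len, replace = TRUE)
  arm[motif_offset:(motif_offset + nchar(motif) - 1L)] <-
    strsplit(motif, "")[[1]]
  loop <- sample(RNA_BASES, loop_len, replace = TRUE)
  arm3 <- rev(unname(rc_base[arm]))
  # relax some stem pairs to G-U: where the 5' base is G or U, swap the
  # complement for the wobble partner
  n_wob <- floor(wobble_frac * arm_len)
  if (n_wob > 0) {
    cand <- which(arm %in% c("G", "U"))
    wob <- utils::head(sample(cand), n_wob)
    for (i in wob) {
      arm3[arm_len - i + 1L] <- if (arm[i] == "G") "U" else "G"
    }
  }
  consensus <- paste(c(arm, loop, arm3), collapse = "")
  structure(list(name = name, consensus = consensus, motif = motif,
                 motif_offset = as.integer(motif_offset),
                 arm_len = as.integer(arm_len),
                 loop_len = as.integer(loop_len), mu = mu,
                 motif_mu = motif_mu),
            class = "family_template")
}

#' @export
print.family_template <- function(x, ...) {
  cat("family_template", x$name, ":", nchar(x$consensus), "nt, motif",
      x$motif, "at", x$motif_offset, "\n")
  invisible(x)
}

#' Draw family members from a template
#'
#' Each member substitutes every consensus base independently with
#' probability `mu` (uniform over the three alternatives); positions inside
#' the planted motif use the lower `motif_mu`. No indels, so the motif
#' offset is identical in every member. Deterministic under `seed`.
#'
#' @param template A [family_template()].
#' @param n Number of members.
#' @param seed Integer seed.
#' @return An `rna_set` labelled with the family name.
#' @export
make_family <- function(template, n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  cons <- strsplit(template$consensus, "")[[1]]
  len <- length(cons)
  rate <- rep(template$mu, len)
  mstart <- template$motif_offset
  rate[mstart:(mstart + nchar(template$motif) - 1L)] <- template$motif_mu
  seqs <- vapply(seq_len(n), function(i) {
    b <- cons
    hit <- which(stats::runif(len) < rate)
    for (p in hit) {
      b[p] <- sample(setdiff(RNA_BASES, b[p]), 1L)
    }
    paste(b, collapse = "")
  }, character(1))
  rna_set(sprintf("%s_%03d", template$name, seq_len(n)), seqs,
          template$name)
}

#' Generate out-of-distribution decoy sequences
#'
#' Three decoy processes: `shuffle` permutes the residues of reference
#' sequences (base composition preserved); `random` draws i.i.d. uniform
#' residues with lengths matched to the reference; `cloverleaf` concatenates
#' four short internally reverse-complementary stems with three loops,
#' giving a tRNA-like global shape instead of a single hairpin.
#'
#' @param kind One of `"shuffle"`, `"random"`, `"cloverleaf"`.
#' @param reference An `rna_set`; required for `shuffle` and used for length
#'   matching by `random`.
#' @param n Number of decoys (defaults to `nrow(reference)` when available).
#' @param seed Integer seed.
#' @return An `rna_set` with family label `NA`.
#' @export
make_ood <- function(kind = c("shuffle", "random", "cloverleaf"),
                     reference = NULL, n = NULL, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "shuffle") {
    if (is.null(reference)) stop("shuffle requires a reference dataset")
    if (is.null(n)) n <- nrow(reference)
    src <- reference$residues[rep_len(seq_len(nrow(reference)), n)]
    seqs <- vapply(src, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  } else if (kind == "random") {
    if (is.null(n)) {
      n <- if (is.null(reference)) stop("give n or a reference") else
        nrow(reference)
    }
    lens <- if (is.null(reference)) rep(60L, n) else
      nchar(reference$residues)[rep_len(seq_len(nrow(reference)), n)]
    seqs <- vapply(lens, function(l) {
      paste(sample(RNA_BASES, l, replace = TRUE), collapse = "")
    }, character(1))
  } else {
    if (is.null(n)) n <- if (is.null(reference)) 50L else nrow(reference)
    seqs <- vapply(seq_len(n), function(i) {
      paste(vapply(1:4, function(a) {
        stem <- sample(RNA_BASES, 6L, replace = TRUE)
        loop <- sample(RNA_BASES, if (a < 4) 5L else 0L, replace = TRUE)
        paste(c(stem, rev(unname(rc_base[stem])), loop), collapse = "")
      }, character(1)), collapse = "")
    }, character(1))
  }
  rna_set(sprintf("%s_%03d", kind, seq_len(n)), seqs, NA_character_)
}

#' Add random flanking bases around a sequence
#'
#' Distributes `k` uniform random bases between the 5' and 3' ends (split by
#' a uniform draw), emulating imprecise precursor boundaries. The original
#' sequence stays intact as a contiguous substring.
#'
#' @param x An `rna_set` (all sequences are flanked).
#' @param k Total number of added bases per sequence.
#' @param seed Integer seed.
#' @param max_len Length bound after flanking (default 200).
#' @return The flanked `rna_set`.
#' @export
add_flanks <- function(x, k, seed = 1L, max_len = 200L) {
  stopifnot(k >= 0)
  if (any(nchar(x$residues) + k > max_len)) {
    stop("flanking would exceed ", max_len, " nt")
  }
  set.seed(seed)
  if (k == 0) return(x)
  flanked <- vapply(x$residues, function(s) {
    left <- sample(0:k, 1L)
    paste0(paste(sample(RNA_BASES, left, replace = TRUE), collapse = ""),
           s,
           paste(sample(RNA_BASES, k - left, replace = TRUE), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
  rna_set(x$id, flanked, x$family)
}

#' Generate a labelled multi-family benchmark with decoys
#'
#' Designs `n_families` hairpin templates with independent stems and
#' mutually distinct planted motifs (pairwise Hamming distance at least half
#' the motif length), draws `per_family` members from each, and produces
#' matched out-of-distribution sets: shuffled members, random sequences,
#' cloverleaf decoys, and members of held-out families never included in the
#' labelled dataset.
#'
#' @param n_families Number of trained families (>= 2).
#' @param per_family Members per family (default 60).
#' @param mu Per-base substitution rate (default 0.05).
#' @param seed Integer seed driving the whole benchmark.
#' @param motif_len Planted motif length (default 10).
#' @param arm_len,loop_len Hairpin geometry (defaults 25 / 10).
#' @param n_heldout Number of additional unseen families (default 2).
#' @return A list: `dataset` (a `family_dataset`), `templates`, and `ood`
#'   (list of `rna_set`s: `shuffle`, `random`, `cloverleaf`, `unseen`).
#' @export
make_benchmark <- function(n_families = 10L, per_family = 60L, mu = 0.05,
                           seed = 1L, motif_len = 10L, arm_len = 25L,
                           loop_len = 10L, n_heldout = 2L) {
  stopifnot(n_families >= 2)
  set.seed(seed)
  total <- n_families + n_heldout
  motifs <- character(0)
  tries <- 0L
  while (length(motifs) < total) {
    tries <- tries + 1L
    if (tries > 2000L) stop("motif space exhausted")
    cand <- paste(sample(RNA_BASES, motif_len, replace = TRUE),
                  collapse = "")
    if (all(vapply(motifs, function(m) {
      sum(strsplit(m, "")[[1]] != strsplit(cand, "")[[1]]) >= motif_len / 2
    }, logical(1)))) {
      motifs <- c(motifs, cand)
    }
  }
  templates <- lapply(seq_len(total), function(i) {
    family_template(sprintf("fam%02d", i), motifs[i], arm_len = arm_len,
                    loop_len = loop_len,
                    motif_offset = 1L + (i %% max(1L, arm_len - motif_len)),
                    mu = mu, seed = seed * 1000L + i)
  })
  members <- lapply(seq_len(n_families), function(i) {
    make_family(templates[[i]], per_family, seed = seed * 100L + i)
  })
  labelled <- do.call(rbind, members)
  class(labelled) <- c("rna_set", "data.frame")
  ds <- build_family_dataset(labelled, max_len = 200L)
  unseen <- if (n_heldout > 0) {
    un <- do.call(rbind, lapply(seq_len(n_heldout), function(j) {
      make_family(templates[[n_families + j]], per_family,
                  seed = seed * 100L + n_families + j)
    }))
    un$family <- NA_character_
    class(un) <- c("rna_set", "data.frame")
    un
  }
  ood <- list(
    shuffle = make_ood("shuffle", reference = ds$sequences,
                       seed = seed + 11L),
    random = make_ood("random", reference = ds$sequences, seed = seed + 12L),
    cloverleaf = make_ood("cloverleaf", n = per_family, seed = seed + 13L),
    unseen = unseen)
  list(dataset = ds, templates = templates[seq_len(n_families)], ood = ood)
}
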