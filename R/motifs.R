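#' Maximal convolution responses per (sequence, filter)
#'
#' For a trained one-hot model, scans every sequence with every convolution
#' filter and records the position (leftmost on ties) and value of the
#' maximal pre-pooling activation over valid windows. Windows overlapping
#' the zero-padding tail are excluded.
#'
#' @param classifier A `trained_classifier` with a one-hot model.
#' @param encoded A one-hot `encoded_dataset`.
#' @return A data frame with `seq_id`, `width`, `filter` (index within its
#'   width), `position` (1-based window start) and `activation`.
#' @export
filter_activation_table <- function(classifier, encoded) {
  spec <- classifier$spec
  if (spec$kind != "onehot" || encoded$kind != "onehot") {
    stop("motif extraction is defined for the one-hot model only")
  }
  weights <- classifier$model$weights
  k <- spec$kernels_per_width
  rows <- list()
  for (w in spec$filter_widths) {
    idx <- onehot_im2col_idx(spec$input_len, w)
    Ww <- weights[[paste0("Wconv", w)]]
    bw <- weights[[paste0("bconv", w)]]
    for (s in seq_along(encoded$inputs)) {
      valid <- encoded$seq_len[s] - w + 1L   # windows inside the real sequence
      if (valid < 1L) next
      X <- matrix(encoded$inputs[[s]][idx[seq_len(valid), , drop = FALSE]],
                  valid, ncol(idx))
      A <- sweep_bias(X %*% Ww, bw)
      am <- max.col(t(A), ties.method = "first")
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = encoded$ids[s], width = w, filter = seq_len(k),
        position = am, activation = A[cbind(am, seq_len(k))],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Extract motifs from frequently activated filters
#'
#' Ranks filters by activation frequency -- the fraction of sequences for
#' which the filter's pooled (global-max) activation is positive and ranks
#' within the top `responder_frac` of all filters for that sequence -- and,
#' for each of the `top_k` filters, collects the subsequence under each
#' sequence's maximal window into a position-frequency matrix (no
#' pseudocount; `laplace` adds one). Sequences whose maximal window would
#' overlap padding or an `N` are skipped for that filter.
#'
#' @param classifier A `trained_classifier` with a one-hot model.
#' @param encoded A one-hot `encoded_dataset`, typically one family.
#' @param top_k Number of motifs to return (capped at the filter count).
#' @param widths Optional filter widths to restrict extraction to (e.g. a
#'   single width to mirror per-length motif logos); default all.
#' @param responder_frac Fraction of filters counted as top responders per
#'   sequence (default 0.05).
#' @param laplace Add-one pseudocount for logo rendering (default FALSE).
#' @return A list of `motif_profile`s: `filter_id`, `width`, `pfm`
#'   (width x 4 row-stochastic matrix over A,C,G,U), `support`,
#'   `activation_freq`.
#' @export
extract_motifs <- function(classifier, encoded, top_k = 5L, widths = NULL,
                           responder_frac = 0.05, laplace = FALSE) {
  if (!length(encoded$inputs)) stop("empty sequence set")
  tab <- filter_activation_table(classifier, encoded)
  if (!is.null(widths)) {
    if (!all(widths %in% tab$width)) stop("no filters of the given width")
    tab <- tab[tab$width %in% widths, , drop = FALSE]
  }
  tab$fid <- paste0("w", tab$width, "f", tab$filter)
  n_seq <- length(encoded$ids)
  n_filters <- length(unique(tab$fid))
  top_n <- max(1L, ceiling(responder_frac * n_filters))
  # per sequence: which filters respond positively within the top ranks
  counted <- unlist(lapply(split(tab, tab$seq_id), function(d) {
    d <- d[d$activation > 0, , drop = FALSE]
    if (!nrow(d)) return(character(0))
    d$fid[order(d$activation, decreasing = TRUE)[seq_len(min(top_n, nrow(d)))]]
  }), use.names = FALSE)
  freq <- table(factor(counted, levels = unique(tab$fid))) / n_seq
  # frequency first; mean activation breaks the (common) frequency-1 ties
  mean_act <- vapply(split(tab$activation, tab$fid), mean, numeric(1))
  ranked <- names(freq)[order(-as.numeric(freq), -mean_act[names(freq)])]
  ranked <- ranked[freq[ranked] > 0]
  if (!length(ranked)) stop("no filter attains a positive activation")
  ranked <- utils::head(ranked, min(top_k, n_filters))

  # decode the unpadded one-hot rows back to bases (all-zero row = N -> NA)
  residues <- lapply(seq_len(n_seq), function(s) {
    g <- encoded$inputs[[s]][seq_len(encoded$seq_len[s]), , drop = FALSE]
    base <- c("A", "C", "G", "U")[max.col(g, ties.method = "first")]
    base[rowSums(g) == 0] <- NA_character_
    base
  })

  lapply(ranked, function(fid) {
    d <- tab[tab$fid == fid & tab$activation > 0, , drop = FALSE]
    w <- d$width[1]
    counts <- matrix(0, w, 4, dimnames = list(NULL, c("A", "C", "G", "U")))
    support <- 0L
    for (r in seq_len(nrow(d))) {
      s <- match(d$seq_id[r], encoded$ids)
      kmer <- residues[[s]][d$position[r]:(d$position[r] + w - 1L)]
      if (anyNA(kmer)) next
      counts[cbind(seq_len(w), match(kmer, c("A", "C", "G", "U")))] <-
        counts[cbind(seq_len(w), match(kmer, c("A", "C", "G", "U")))] + 1
      support <- support + 1L
    }
    if (support == 0L) return(NULL)
    if (laplace) counts <- counts + 1
    structure(list(filter_id = fid, width = w,
                   pfm = counts / rowSums(counts), support = support,
                   activation_freq = as.numeric(freq[fid])),
              class = "motif_profile")
  }) -> out
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("motif_profile", x$filter_id, ": width", x$width, ", support",
      x$support, ", consensus", motif_consensus(x), "\n")
  invisible(x)
}

#' Consensus string of a motif profile
#'
#' @param motif A `motif_profile`.
#' @return Character consensus (argmax base per column).
#' @export
motif_consensus <- function(motif) {
  paste(c("A", "C", "G", "U")[max.col(motif$pfm, ties.method = "first")],
        collapse = "")
}

#' Write motifs in MEME minimal format
#'
#' Emits a MEME version 4 minimal motif file with ALPHABET= ACGU, one
#' letter-probability matrix per profile, `nsites` set to the support.
#'
#' @param motifs List of `motif_profile`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 U 0.25", ""), con)
  for (m in motifs) {
    writeLines(c(paste("MOTIF", m$filter_id),
                 sprintf(
                   "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                   m$width, m$support)), con)
    writeLines(apply(m$pfm, 1, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal motif file
#'
#' Parses files produced by [write_meme()] (and other MEME minimal files
#' over a 4-letter alphabet) back into `motif_profile`s.
#'
#' @param path Path to a MEME minimal file.
#' @return List of `motif_profile`s.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  lapply(starts, function(st) {
    name <- sub("^MOTIF\\s+", "", lines[st])
    hdr <- lines[st + 1L]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
    pfm <- do.call(rbind, lapply(lines[(st + 2L):(st + 1L + w)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    colnames(pfm) <- c("A", "C", "G", "U")
    structure(list(filter_id = name, width = w, pfm = pfm,
                   support = nsites, activation_freq = NA_real_),
              class = "motif_profile")
  })
}

#' Information content per motif column
#'
#' @param motif A `motif_profile`.
#' @return Numeric vector, bits per column in [0, 2].
#' @export
motif_information <- function(motif) {
  apply(motif$pfm, 1, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}
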