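# hand-built classifier whose width-4 filter 1 matches "GGGG" exactly
gggg_classifier <- function() {
  spec <- onehot_cnn_spec(classes = 2L, input_len = 12L, filter_widths = 4L,
                          kernels_per_width = 2L, fc_units = 4L)
  model <- build_cnn(spec, seed = 1L)
  W <- matrix(0, 16, 2)
  W[8 + 1:4, 1] <- 1            # rows (offset 1..4, base G)
  model$weights$Wconv4 <- W
  model$weights$bconv4 <- c(0, 0)
  structure(list(model = model, spec = spec,
                 label_map = c(a = 0L, b = 1L),
                 encoding = list(kind = "onehot", L = 12L),
                 threshold = 0.977),
            class = "trained_classifier")
}

encode_as_dataset <- function(residues, L = 12L) {
  x <- rna_set(sprintf("s%d", seq_along(residues)), residues, "a")
  class(x) <- c("rna_set", "data.frame")
  ds <- build_family_dataset(x, max_len = L)
  encode_dataset(ds, "onehot", L = L)
}

test_that("activation table finds the maximal window of a known filter", {
  cls <- gggg_classifier()
  enc <- encode_as_dataset("AAGGGGAA")
  tab <- filter_activation_table(cls, enc)
  match_row <- tab[tab$filter == 1L, ]
  expect_equal(match_row$position, 3L)      # GGGG starts at base 3
  expect_equal(match_row$activation, 4)
  # all-zero filter: activation 0 everywhere, leftmost window by tie rule
  zero_row <- tab[tab$filter == 2L, ]
  expect_equal(zero_row$position, 1L)
  expect_equal(zero_row$activation, 0)
  # windows never overlap the padding tail: 8 - 4 + 1 positions
  expect_true(all(tab$position <= 5L))
  expect_error(filter_activation_table(
    cls, list(kind = "pair")), "one-hot")
})

test_that("a family of identical sequences gives point-mass columns", {
  cls <- gggg_classifier()
  enc <- encode_as_dataset(rep("AAGGGGAAUC", 5))
  mot <- extract_motifs(cls, enc, top_k = 10L)
  expect_true(length(mot) >= 1L)
  for (m in mot) {
    expect_equal(rowSums(m$pfm), rep(1, m$width), ignore_attr = TRUE)
    expect_true(all(apply(m$pfm, 1, max) == 1))     # point mass
    expect_gte(m$support, 1L)
    expect_true(all(motif_information(m) >= 0 & motif_information(m) <= 2))
  }
  # top_k beyond the filter count returns every responding filter
  expect_lte(length(mot), 2L)
})

test_that("trained filters recover a planted conserved motif", {
  rec <- motif_recovery_fit()
  enc_fam <- hairpinCNN:::subset_encoded(rec$enc, rec$enc$labels == 0L)
  mot <- extract_motifs(rec$fit, enc_fam, top_k = 5L, widths = 8L)
  planted <- rec$bench$templates[[1]]$motif
  dists <- vapply(mot, function(m) ham_align(motif_consensus(m), planted),
                  numeric(1))
  expect_lte(min(dists), 2)
  # planted-motif columns carry high information
  best <- mot[[which.min(dists)]]
  expect_gt(mean(motif_information(best)), 1)
})

test_that("MEME round trip preserves the probability matrices", {
  cls <- gggg_classifier()
  enc <- encode_as_dataset(c("AAGGGGAAUC", "AAGGGGAAUC", "CAGGGGAAUC"))
  mot <- extract_motifs(cls, enc, top_k = 2L)
  f <- tempfile(fileext = ".meme")
  write_meme(mot, f)
  lines <- readLines(f)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("^ALPHABET= ACGU", lines)))
  back <- read_meme(f)
  expect_length(back, length(mot))
  for (i in seq_along(mot)) {
    expect_equal(back[[i]]$pfm, mot[[i]]$pfm, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(back[[i]]$support, mot[[i]]$support)
  }
  # empty list still writes a parseable header-only file
  f2 <- tempfile(fileext = ".meme")
  write_meme(list(), f2)
  expect_length(read_meme(f2), 0L)
})
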