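test_that("probability matrix thresholds, symmetrizes and pads", {
  b <- hairpinCNN:::new_bppm(10L, 1L, 9L, 0.9)
  e <- encode_probability(b, T = 1e-4, L = 12L)
  expect_equal(dim(e$grid), c(12L, 12L))
  expect_equal(e$grid[1, 9], 0.9)
  expect_equal(e$grid[9, 1], 0.9)
  expect_equal(sum(e$grid != 0), 2L)
  expect_true(all(e$grid[11:12, ] == 0))  # padding rows at the end

  # p below T zeroes the cell
  b2 <- hairpinCNN:::new_bppm(10L, 1L, 9L, 0.00005)
  expect_true(all(encode_probability(b2, T = 1e-4, L = 12L)$grid == 0))
  expect_true(all(encode_probability(hairpinCNN:::new_bppm(10L),
                                     L = 12L)$grid == 0))
  expect_error(encode_probability(b, L = 5L), "exceeds")
})

test_that("pair matrix applies the ordered and unordered value tables", {
  s <- "AAAAAAAAU"            # A at 1 pairs U at 9
  b <- hairpinCNN:::new_bppm(9L, 1L, 9L, 0.9)
  e <- encode_pairs(s, b, ordered = TRUE, L = 10L)
  expect_equal(e$grid[1, 9], 1 / 6)   # reads (s_i, s_j) = AU
  expect_equal(e$grid[9, 1], 2 / 6)   # reads (s_j, s_i) = UA

  s2 <- "UAAAAAAAG"           # U-G wobble
  e2 <- encode_pairs(s2, b, ordered = FALSE, L = 10L)
  expect_equal(e2$grid[1, 9], 3 / 3)
  expect_equal(e2$grid[9, 1], 3 / 3)  # unordered matrix fully symmetric

  # below threshold -> zero; non-canonical stored pair -> error
  e3 <- encode_pairs(s, hairpinCNN:::new_bppm(9L, 1L, 9L, 1e-5), L = 10L)
  expect_true(all(e3$grid == 0))
  expect_error(encode_pairs("AAAAAAAAC", b, L = 10L), "non-canonical")
})

test_that("ordered pair values collapse onto the unordered classes", {
  set.seed(31)
  tpl <- family_template("f", "ACGUACGUAC", mu = 0.08, seed = 8L)
  seqs <- make_family(tpl, 12L, seed = 9L)
  # {1,2}/6 -> 1/3, {3,4}/6 -> 2/3, {5,6}/6 -> 3/3, exact on sixths
  map63 <- function(v) {
    out <- c(0, 1, 1, 2, 2, 3, 3)[as.integer(round(v * 6)) + 1L] / 3
    array(out, dim(v))
  }
  for (s in seqs$residues) {
    b <- mccaskill_bppm(s)
    eo <- encode_pairs(s, b, ordered = TRUE, L = 64L)
    eu <- encode_pairs(s, b, ordered = FALSE, L = 64L)
    expect_equal(map63(eo$grid), eu$grid, tolerance = 1e-12)
    # support symmetry of the ordered matrix
    expect_equal(eo$grid != 0, t(eo$grid != 0))
  }
})

test_that("mixed matrix stacks probability and pair channels", {
  s <- "GAAACAAAA"
  b <- mccaskill_bppm(s)
  m <- encode_mixed(s, b, L = 16L)
  expect_equal(dim(m$grid), c(16L, 16L, 2L))
  expect_equal(m$grid[, , 1], encode_probability(b, L = 16L)$grid)
  expect_equal(m$grid[, , 2], encode_pairs(s, b, L = 16L)$grid)
  empty <- encode_mixed("AAAAA", mccaskill_bppm("AAAAA"), L = 16L)
  expect_true(all(empty$grid == 0))
})

test_that("one-hot encoding is exact, padded, and invertible", {
  e <- encode_onehot("ACGU", L = 8L)
  expect_equal(e$grid[1:4, ], diag(4), ignore_attr = TRUE)
  expect_true(all(e$grid[5:8, ] == 0))
  expect_true(all(encode_onehot("N", L = 4L)$grid[1, ] == 0))
  expect_true(all(rowSums(e$grid) <= 1))
  # invertibility on the unpadded region
  s <- "GAUCCGUUAG"
  g <- encode_onehot(s, L = 12L)$grid
  rec <- paste(c("A", "C", "G", "U")[max.col(g[1:10, ])], collapse = "")
  expect_equal(rec, s)
  expect_error(encode_onehot("ACGUA", L = 4L), "exceeds")
})

test_that("raising the threshold never adds nonzero cells", {
  set.seed(5)
  tpl <- family_template("f", "GGAUGCAUGG", mu = 0.1, seed = 2L)
  seqs <- make_family(tpl, 8L, seed = 3L)
  bppms <- lapply(seqs$residues, mccaskill_bppm)
  thr <- percentile_thresholds(bppms, c(0, 10, 20, 30, 40))
  expect_true(!is.unsorted(thr))
  for (b in bppms) {
    nz <- vapply(thr, function(T) sum(encode_probability(b, T = T,
                                                         L = 64L)$grid != 0),
                 numeric(1))
    expect_true(all(diff(nz) <= 0))
  }
})

test_that("percentile thresholds follow the nearest-rank convention", {
  mk <- function(p) hairpinCNN:::new_bppm(20L, seq_along(p),
                                          seq_along(p) + 10L, p)
  expect_equal(percentile_thresholds(list(mk(c(0.5, 0.5, 0.5))),
                                     c(0, 50)), c(0.5, 0.5))
  pool <- mk(seq(0.1, 1, 0.1))
  expect_equal(percentile_thresholds(list(pool), 0), 0.1)  # pooled minimum
  expect_equal(percentile_thresholds(list(pool), 40), 0.4)
  # floor excludes values at or below it
  expect_equal(percentile_thresholds(list(pool), 0, floor = 0.1), 0.2)
  expect_error(percentile_thresholds(list(mk(1e-5)), 0), "floor")
})
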