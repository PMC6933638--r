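test_that("templates build reverse-complementary hairpins", {
  tpl <- family_template("f", "ACGUACGUAC", arm_len = 20L, loop_len = 8L,
                         wobble_frac = 0, mu = 0, seed = 2L)
  cons <- strsplit(tpl$consensus, "")[[1]]
  expect_length(cons, 48L)
  arm5 <- cons[1:20]
  arm3 <- cons[29:48]
  rc <- c(A = "U", C = "G", G = "C", U = "A")
  expect_equal(arm3, rev(unname(rc[arm5])))
  expect_equal(substr(tpl$consensus, tpl$motif_offset,
                      tpl$motif_offset + 9L), "ACGUACGUAC")
  # wobbled stems stay pairable (G-U allowed)
  tpl2 <- family_template("g", "ACGUACGUAC", wobble_frac = 0.2, seed = 3L)
  c2 <- strsplit(tpl2$consensus, "")[[1]]
  pairs <- paste0(c2[1:25], rev(c2[36:60]))
  expect_true(all(pairs %in% c("AU", "UA", "CG", "GC", "GU", "UG")))
})

test_that("family draws respect the mutation model and the seed", {
  tpl <- family_template("f", "ACGUACGUAC", mu = 0, seed = 2L)
  fam0 <- make_family(tpl, 5L, seed = 7L)
  expect_true(all(fam0$residues == tpl$consensus))
  expect_equal(fam0$family, rep("f", 5L))

  expect_identical(make_family(tpl, 5L, seed = 7L), fam0)

  tpl2 <- family_template("f", "ACGUACGUAC", mu = 0.05, motif_mu = 0.05,
                          seed = 2L)
  fam <- make_family(tpl2, 400L, seed = 8L)
  len <- nchar(tpl2$consensus)
  dist <- vapply(fam$residues, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(tpl2$consensus, "")[[1]])
  }, numeric(1), USE.NAMES = FALSE)
  se <- sqrt(400 * len * 0.05 * 0.95) / (400 * len)
  expect_lt(abs(mean(dist) / len - 0.05), 3 * se)
})

test_that("decoy generators honor their contracts", {
  ref <- make_family(family_template("f", "ACGUACGUAC", seed = 1L), 6L,
                     seed = 2L)
  shuf <- make_ood("shuffle", reference = ref, seed = 5L)
  comp <- function(s) sort(table(strsplit(s, "")[[1]]))
  for (i in seq_len(nrow(shuf))) {
    expect_equal(comp(shuf$residues[i]), comp(ref$residues[i]))
  }
  expect_error(make_ood("shuffle"), "reference")

  rnd <- make_ood("random", reference = ref, seed = 5L)
  expect_equal(nchar(rnd$residues), nchar(ref$residues))

  clov <- make_ood("cloverleaf", n = 4L, seed = 5L)
  rc <- c(A = "U", C = "G", G = "C", U = "A")
  for (s in clov$residues) {
    expect_lte(nchar(s), 200L)
    b <- strsplit(s, "")[[1]]
    # each arm is stem(6) + reverse-complement(6) + loop
    offs <- cumsum(c(0, 17, 17, 17))
    for (o in offs) {
      stem <- b[(o + 1):(o + 6)]
      expect_equal(b[(o + 7):(o + 12)], rev(unname(rc[stem])))
    }
  }
  expect_true(all(grepl("^[ACGU]+$", c(shuf$residues, rnd$residues,
                                       clov$residues))))
})

test_that("flanking keeps the original sequence intact", {
  x <- make_family(family_template("f", "ACGUACGUAC", seed = 1L), 3L,
                   seed = 2L)
  expect_identical(add_flanks(x, 0L, seed = 3L), x)
  for (k in c(5L, 10L, 15L, 20L)) {
    fl <- add_flanks(x, k, seed = 3L)
    expect_equal(nchar(fl$residues), nchar(x$residues) + k)
    for (i in seq_len(nrow(x))) {
      expect_true(grepl(x$residues[i], fl$residues[i], fixed = TRUE))
    }
  }
  expect_error(add_flanks(x, 150L), "exceed")
})

test_that("benchmarks are labelled, balanced and distinct by design", {
  b <- make_benchmark(n_families = 4L, per_family = 10L, seed = 3L)
  expect_equal(nrow(b$dataset$sequences), 40L)
  expect_true(all(table(b$dataset$sequences$family) == 10L))
  expect_length(b$dataset$label_index, 4L)
  motifs <- vapply(b$templates, `[[`, character(1), "motif")
  for (i in seq_along(motifs)) {
    for (j in seq_len(i - 1L)) {
      d <- sum(strsplit(motifs[i], "")[[1]] != strsplit(motifs[j], "")[[1]])
      expect_gte(d, nchar(motifs[i]) / 2)
    }
  }
  expect_true(all(nchar(b$dataset$sequences$residues) <= 200L))
  # pure function of the seed
  b2 <- make_benchmark(n_families = 4L, per_family = 10L, seed = 3L)
  expect_identical(b2$dataset$sequences, b$dataset$sequences)
})
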