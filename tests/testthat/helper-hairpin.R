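# shared fixtures and slow, memoized model fits

# minimum Hamming distance between the shorter string slid along the longer
ham_align <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  if (length(A) > length(B)) {
    tmp <- A
    A <- B
    B <- tmp
  }
  min(vapply(0:(length(B) - length(A)), function(o) {
    sum(A != B[(1 + o):(o + length(A))])
  }, numeric(1)))
}

# wrap an unlabelled rna_set as a one-class family_dataset so decoys can be
# pushed through encode_dataset / scoring
as_decoy_dataset <- function(x, max_len = 200L) {
  x$family <- "decoy"
  class(x) <- c("rna_set", "data.frame")
  build_family_dataset(x, max_len = max_len)
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# small two-family benchmark + trained one-hot model shared by the
# training / openset unit tests (44 nt hairpins padded to 48)
tiny_benchmark <- function() {
  memo("tiny_benchmark",
       make_benchmark(n_families = 2L, per_family = 50L, mu = 0.05,
                      seed = 42L, arm_len = 18L, loop_len = 8L,
                      motif_len = 8L))
}

tiny_split <- function() {
  memo("tiny_split", {
    enc <- encode_dataset(tiny_benchmark()$dataset, "onehot", L = 48L)
    folds <- hairpinCNN:::stratified_folds(enc$labels, 5L, seed = 3L)
    list(enc = enc,
         train = hairpinCNN:::subset_encoded(enc, folds != 1L),
         test = hairpinCNN:::subset_encoded(enc, folds == 1L))
  })
}

tiny_fit <- function() {
  memo("tiny_fit",
       train_cnn(tiny_split()$train,
                 config = train_config(epochs = 20L, seed = 5L,
                                       patience = 20L)))
}

# ---- acceptance-scale artifacts (10 families, 60 nt hairpins, L = 64) ----

acc_benchmark <- function() {
  memo("acc_benchmark",
       make_benchmark(n_families = 10L, per_family = 60L, mu = 0.05,
                      seed = 7L))
}

acc_onehot <- function() {
  memo("acc_onehot", {
    enc <- encode_dataset(acc_benchmark()$dataset, "onehot", L = 64L)
    folds <- hairpinCNN:::stratified_folds(enc$labels, 5L, seed = 3L)
    train <- hairpinCNN:::subset_encoded(enc, folds != 1L)
    test <- hairpinCNN:::subset_encoded(enc, folds == 1L)
    fit <- train_cnn(train, config = train_config(epochs = 12L, seed = 11L,
                                                  patience = 12L))
    list(enc = enc, train = train, test = test, fit = fit)
  })
}

acc_bppms <- function() {
  memo("acc_bppms",
       lapply(acc_benchmark()$dataset$sequences$residues, mccaskill_bppm))
}

# dedicated plant-and-recover experiment: strongly conserved mature motif
# over a divergent background
motif_recovery_fit <- function() {
  memo("motif_recovery_fit", {
    bench <- make_benchmark(n_families = 2L, per_family = 60L, mu = 0.15,
                            seed = 19L)
    enc <- encode_dataset(bench$dataset, "onehot", L = 64L)
    fit <- train_cnn(enc, config = train_config(epochs = 10L, seed = 5L,
                                                patience = 10L))
    list(bench = bench, enc = enc, fit = fit)
  })
}
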