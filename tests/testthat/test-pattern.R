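test_that("normalised Levenshtein dissimilarity matches independent oracles", {
  expect_equal(levenshtein_phonetic_dissimilarity("g @U", "g @U"), 0)
  expect_equal(levenshtein_phonetic_dissimilarity("g @U", "k i"), 1)
  expect_equal(levenshtein_phonetic_dissimilarity("g @U", "g i"), 0.5)
  # length normalisation uses the longer syllable
  expect_equal(levenshtein_phonetic_dissimilarity(c("a"), c("a", "b", "c")),
               2 / 3)
  expect_error(levenshtein_phonetic_dissimilarity(character(0), "a"),
               class = "cohortpe_bad_syllable")

  # exhaustive recursion over random syllables of length <= 4
  labels <- c("p", "t", "k", "a", "i")
  set.seed(11)
  for (rep in 1:200) {
    a <- sample(labels, sample(1:4, 1), replace = TRUE)
    b <- sample(labels, sample(1:4, 1), replace = TRUE)
    expect_equal(levenshtein_phonetic_dissimilarity(a, b),
                 oracle_levenshtein(a, b) / max(length(a), length(b)))
    # utils::adist agrees after mapping labels to single characters
    expect_equal(
      oracle_levenshtein(a, b),
      as.integer(utils::adist(paste(match(a, labels), collapse = ""),
                              paste(match(b, labels), collapse = ""))))
  }
})

test_that("phonetic RDM covers all pairs symmetrically", {
  s <- small_setup()
  m <- phonetic_rdm(s$design, s$design$syl2)
  expect_s3_class(m, "rdm")
  expect_identical(attr(m, "metric"), "levenshtein")
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
  expect_true(all(m >= 0 & m <= 1))
  i <- 1; j <- 4
  expect_equal(m[i, j],
               levenshtein_phonetic_dissimilarity(s$design$syl2[i],
                                                  s$design$syl2[j]))
})

test_that("Euclidean RDM equals the direct formula", {
  set.seed(21)
  pat <- matrix(rnorm(6 * 5), 6, 5,
                dimnames = list(paste0("it", 1:6), NULL))
  m <- euclidean_rdm(pat)
  expect_equal(unclass(m), oracle_euclidean(pat), ignore_attr = TRUE)
  expect_identical(rownames(m), rownames(pat))
  patbad <- pat; patbad[2, 2] <- Inf
  expect_error(euclidean_rdm(patbad), class = "cohortpe_bad_patterns")
})

test_that("crossnobis distances equal the direct formula and may be negative", {
  set.seed(31)
  folds <- lapply(1:3, function(i) {
    matrix(rnorm(5 * 4), 5, 4, dimnames = list(paste0("it", 1:5), NULL))
  })
  m <- crossnobis_rdm(folds)
  expect_s3_class(m, "rdm")
  expect_identical(attr(m, "metric"), "crossnobis")
  expect_equal(unclass(m), oracle_crossnobis(folds), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
  # pure noise: some cross-validated distances fall below zero
  expect_lt(min(m), 0)

  # with a non-trivial noise covariance
  sigma <- diag(4) * 0.5 + 0.2
  expect_equal(unclass(crossnobis_rdm(folds, sigma)),
               oracle_crossnobis(folds, sigma), ignore_attr = TRUE,
               tolerance = 1e-10)

  expect_error(crossnobis_rdm(folds[1]), class = "cohortpe_bad_patterns")
  expect_error(crossnobis_rdm(list(folds[[1]], folds[[2]][, 1:3])),
               class = "cohortpe_bad_patterns")
  expect_error(crossnobis_rdm(folds, matrix(0, 4, 4)),
               class = "cohortpe_singular_covariance")
})

test_that("shrinkage covariance interpolates toward the diagonal", {
  set.seed(41)
  res <- matrix(rnorm(40 * 6), 40, 6)
  s0 <- shrinkage_covariance(res, lambda = 0)
  expect_equal(unclass(s0), stats::cov(res), ignore_attr = TRUE)
  s1 <- shrinkage_covariance(res, lambda = 1)
  expect_equal(unname(s1[1, 2]), 0)
  expect_equal(diag(s1), diag(stats::cov(res)), ignore_attr = TRUE)
  sauto <- shrinkage_covariance(res)
  lam <- attr(sauto, "lambda")
  expect_gte(lam, 0); expect_lte(lam, 1)
  expect_true(all(eigen(sauto, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("reciprocal-pair mask excludes exactly the cross-Syl2 pairs", {
  s <- small_setup()
  mask <- reciprocal_pair_mask(s$design)
  expect_identical(dim(mask), c(nrow(s$design), nrow(s$design)))
  expect_false(any(diag(mask)))
  expect_equal(mask, t(mask))
  d <- s$design
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(nrow(d))) {
      if (i == j) next
      want <- d$set_id[i] == d$set_id[j] &&
        d$congruency[i] == d$congruency[j] &&
        d$syl2_label[i] != d$syl2_label[j]
      expect_identical(unname(mask[i, j]), want)
    }
  }
  bad <- d
  bad$syl2_label[bad$set_id == 1] <- "onlyone"
  expect_error(reciprocal_pair_mask(bad), class = "cohortpe_bad_design")
  expect_error(reciprocal_pair_mask(d[, c("item_id", "set_id")]),
               class = "cohortpe_bad_design")
})

test_that("RDM correlations are Fisher-transformed Spearman over unmasked pairs", {
  set.seed(51)
  a <- matrix(rnorm(36), 6, 6); a <- a + t(a); diag(a) <- 0
  b <- matrix(rnorm(36), 6, 6); b <- b + t(b); diag(b) <- 0
  keep <- upper.tri(a)
  rho <- stats::cor(a[keep], b[keep], method = "spearman")
  expect_equal(rdm_correlation(a, b), atanh(rho))
  # identical RDMs: rho clipped just below one, finite z
  z <- rdm_correlation(a, a)
  expect_true(is.finite(z))
  expect_equal(z, atanh(1 - 1e-10))
  # masking changes which pairs enter
  mask <- matrix(FALSE, 6, 6); mask[1, 2] <- mask[2, 1] <- TRUE
  keep2 <- keep & !mask
  expect_equal(rdm_correlation(a, b, mask),
               atanh(stats::cor(a[keep2], b[keep2], method = "spearman")))
  allmask <- matrix(TRUE, 6, 6)
  expect_error(rdm_correlation(a, b, allmask),
               class = "cohortpe_too_few_pairs")
})

test_that("condition mean distances aggregate unmasked within-condition pairs", {
  s <- small_setup()
  sim <- run_condition_simulation(s$lexicon, s$evidence, s$design)
  rdm <- sim$rdms$prediction_error
  cm <- condition_mean_distance(rdm, s$design, sim$mask)
  expect_setequal(cm$condition,
                  c("Strong+Match", "Weak+Match",
                    "Strong+Mismatch", "Weak+Mismatch"))
  # agrees with a direct loop
  d <- s$design
  cond <- paste(d$strength, d$congruency, sep = "+")
  for (g in unique(cond)) {
    vals <- c()
    idx <- which(cond == g)
    for (i in idx) for (j in idx) {
      if (i < j && !sim$mask[i, j]) vals <- c(vals, rdm[i, j])
    }
    expect_equal(cm$mean_distance[cm$condition == g], mean(vals))
    expect_equal(cm$n_pairs[cm$condition == g], length(vals))
  }
  # masking away an entire condition's pairs is an error
  expect_error(condition_mean_distance(rdm, s$design,
                                       matrix(TRUE, nrow(d), nrow(d))),
               class = "cohortpe_empty_condition")
})

test_that("pair-level predictors average log item values over unmasked pairs", {
  s <- small_setup()
  vals <- seq(0.1, 0.9, length.out = nrow(s$design))
  mask <- reciprocal_pair_mask(s$design)
  pv <- predictor_pair_values(s$design, vals, mask)
  ut <- which(upper.tri(mask) & !mask, arr.ind = TRUE)
  expect_equal(nrow(pv), nrow(ut))
  expect_equal(pv$value, (log(vals)[ut[, 1]] + log(vals)[ut[, 2]]) / 2)
  expect_error(predictor_pair_values(s$design, vals - 0.1, mask),
               class = "cohortpe_bad_predictor")
})

test_that("RDMs round-trip through delimited text", {
  set.seed(61)
  pat <- matrix(round(rnorm(4 * 3), 6), 4, 3,
                dimnames = list(paste0("it", 1:4), NULL))
  m <- euclidean_rdm(pat)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rdm(m, f)
  m2 <- read_rdm(f)
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE, tolerance = 1e-6)
  expect_identical(rownames(m2), rownames(m))
})
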