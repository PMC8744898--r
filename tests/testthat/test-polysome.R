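test_that("cytoplasmic fraction covers the boundary and symmetric cases", {
  expect_equal(cytoplasmic_fraction(10, 0), 1.0)
  expect_equal(cytoplasmic_fraction(0, 10), 0.0)
  expect_equal(cytoplasmic_fraction(5, 5), 0.5)
  expect_error(cytoplasmic_fraction(0, 0), "not expressed")
  expect_error(cytoplasmic_fraction(-1, 1), "non-negative")
})

test_that("fraction distribution follows the closed form and handles absent CTs", {
  expect_equal(fraction_distribution(rep(20, 4)), rep(0.25, 4))
  expect_equal(fraction_distribution(c(20, 21, 22), 2), c(4, 2, 1) / 7)
  p <- fraction_distribution(c(20, NA, 22))
  expect_equal(p[2], 0)
  expect_equal(sum(p), 1)
  expect_error(fraction_distribution(c(NA_real_, NA_real_)), "all CT")
  expect_error(fraction_distribution(c(20, 21), efficiency = 2.5), "efficiency")
})

test_that("distribution normalizes and is invariant to a global CT shift", {
  set.seed(51)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    ct <- stats::runif(n, 15, 35)
    ct[sample(n, sample(0:(n - 2), 1))] <- NA
    eff <- stats::runif(1, 1.5, 2)
    p <- fraction_distribution(ct, eff)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
    shift <- stats::runif(1, -5, 5)
    expect_equal(fraction_distribution(ct + shift, eff), p)
  }
})

test_that("polysome enrichment scores polysomal mass and calls translation", {
  # all mass in one polysomal fraction
  prof <- fraction_profile("tx", c(NA, NA, NA, 20), polysome_set = 3:4)
  enr <- polysome_enrichment(prof)
  expect_equal(enr$score, 1.0)
  expect_true(enr$translated)
  # uniform mass over 10 fractions, 4 polysomal
  prof <- fraction_profile("tx", rep(20, 10))
  expect_identical(prof$polysome_set, 7:10)
  enr <- polysome_enrichment(prof)
  expect_equal(enr$score, 0.4)
  expect_false(enr$translated)
})

test_that("moving mass into a polysomal fraction never lowers the score", {
  set.seed(52)
  for (i in 1:50) {
    ct <- stats::runif(10, 18, 30)
    prof <- fraction_profile("tx", ct)
    s0 <- polysome_enrichment(prof)$score
    ct2 <- ct
    idx <- sample(7:10, 1)
    ct2[idx] <- ct2[idx] - stats::runif(1, 0, 3)
    s1 <- polysome_enrichment(fraction_profile("tx", ct2))$score
    expect_gte(s1 + 1e-12, s0)
  }
})

test_that("planted polysome enrichment recovers the translated subset", {
  # five assayed transcripts, three planted at 80% polysomal mass
  set.seed(53)
  truth <- synthetic_truth(n_transcripts = 40)
  seqs <- generate_transcript_sequences(truth, background_length = 900)
  tracks <- generate_tracks_and_ct(truth, seqs$transcripts, ct_noise_sd = 0)
  assayed <- setdiff(rownames(tracks$ct), "ACTB_control")
  expect_identical(sort(assayed), truth$exported_ids)
  called <- assayed[vapply(assayed, function(id) {
    prof <- fraction_profile(id, tracks$ct[id, ], polysome_set = tracks$polysome_set)
    polysome_enrichment(prof, 0.5)$translated
  }, logical(1))]
  expect_identical(sort(called), truth$translated_ids)
})

test_that("delta-Ct relative expression matches direct evaluation", {
  expect_equal(relative_expression(20, 20), 1.0)
  expect_equal(relative_expression(21, 20), 0.5)
  expect_error(relative_expression(NA, 20), "absent CT")
  set.seed(54)
  for (i in 1:200) {
    ct_t <- stats::runif(1, 10, 35); ct_r <- stats::runif(1, 10, 35)
    eff <- stats::runif(1, 1.5, 2)
    expect_equal(relative_expression(ct_t, ct_r, eff),
                 exp(-(ct_t - ct_r) * log(eff)), tolerance = 1e-12)
  }
})

test_that("CT tables round-trip through CSV with blanks as missing", {
  ct <- matrix(c(20.5, NA, 22, 19, 21, NA), nrow = 2,
               dimnames = list(c("tx1", "ACTB"), c("F1", "F2", "F3")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(ct, f)
  got <- read_ct_table(f)
  expect_equal(got, ct)
})
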