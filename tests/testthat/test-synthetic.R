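test_that("truth specs enforce the nesting invariant", {
  expect_error(synthetic_truth(n_transcripts = 10, n_exclusive = 12),
               "infeasible")
  expect_error(synthetic_truth(n_exclusive = 5, n_confirmed = 6), "infeasible")
  expect_error(synthetic_truth(n_promoter_open = 10, n_confirmed = 9), "infeasible")
  tr <- synthetic_truth(n_transcripts = 100, seed = 61)
  expect_true(all(tr$translated_ids %in% tr$exported_ids))
  expect_true(all(tr$exported_ids %in% tr$confirmed_ids))
  expect_true(all(tr$confirmed_ids %in% tr$exclusive_ids))
  orf_ids <- names(tr$orf_spec)[vapply(tr$orf_spec,
                                       function(s) length(s$lengths_aa) > 0, logical(1))]
  expect_true(all(tr$exported_ids %in% orf_ids))
  expect_true(all(orf_ids %in% tr$confirmed_ids))
})

test_that("a cohort with all transcripts planted exclusive is wholly exclusive", {
  tr <- synthetic_truth(n_transcripts = 12, n_exclusive = 12, seed = 62)
  cohort <- generate_cohort(tr)
  mat <- cohort$expression
  calls <- find_exclusive_transcripts(mat, samples_with_role(mat, "tumor"),
                                      samples_with_role(mat, "normal_tissue"))
  expect_setequal(calls$transcript_id, tr$transcript_ids)
})

test_that("generators are deterministic per seed", {
  b1 <- generate_bundle(seed = 63, n_transcripts = 80)
  b2 <- generate_bundle(seed = 63, n_transcripts = 80)
  expect_identical(b1$expression$values, b2$expression$values)
  expect_identical(b1$replicate$values, b2$replicate$values)
  expect_identical(b1$sequences, b2$sequences)
  expect_identical(b1$ct, b2$ct)
  expect_identical(b1$truth$translated_ids, b2$truth$translated_ids)
  b3 <- generate_bundle(seed = 64, n_transcripts = 80)
  expect_false(identical(b1$expression$values, b3$expression$values))
})

test_that("sequence planting is scanner-verified: requested ORFs and no others", {
  tr <- synthetic_truth(n_transcripts = 30, seed = 65)
  seqs <- generate_transcript_sequences(tr, background_length = 1200)
  for (id in names(tr$orf_spec)) {
    spec <- tr$orf_spec[[id]]
    found <- find_orfs(seqs$sequences[[id]], 50)
    expect_identical(sort(found$length_aa), sort(spec$lengths_aa))
    # planted lengths are unique per transcript, so kozak classes can be
    # matched up by length
    expect_identical(found$kozak[match(spec$lengths_aa, found$length_aa)],
                     spec$kozak)
  }
  # the flagship transcript carries a weak 52-aa and a strong 68-aa ORF
  flagship <- names(tr$orf_spec)[vapply(tr$orf_spec, function(s)
    identical(s$lengths_aa, c(52L, 68L)), logical(1))]
  expect_length(flagship, 1)
  found <- find_orfs(seqs$sequences[[flagship]], 50)
  expect_identical(found$kozak[match(c(52L, 68L), found$length_aa)],
                   c("weak", "strong"))
  # model anatomy is consistent with the sequence
  m <- seqs$transcripts[[flagship]]
  expect_identical(sum(m$exons$end - m$exons$start), nchar(m$sequence))
})

test_that("infeasible planting requests fail loudly", {
  tr <- synthetic_truth(n_transcripts = 20, seed = 66)
  expect_error(generate_transcript_sequences(tr, background_length = 200),
               "do not fit")
})

test_that("translated-call recovery degrades monotonically with CT noise", {
  noise_levels <- c(0, 1, 3)
  recall <- vapply(noise_levels, function(sd) {
    hits <- 0L; total <- 0L
    for (seed in 1:10) {
      tr <- synthetic_truth(n_transcripts = 30, seed = 100 + seed)
      seqs <- generate_transcript_sequences(tr, background_length = 900)
      tracks <- generate_tracks_and_ct(tr, seqs$transcripts, ct_noise_sd = sd,
                                       seed = 200 + seed)
      for (id in tr$translated_ids) {
        prof <- fraction_profile(id, tracks$ct[id, ],
                                 polysome_set = tracks$polysome_set)
        hits <- hits + polysome_enrichment(prof, 0.5)$translated
        total <- total + 1L
      }
    }
    hits / total
  }, numeric(1))
  expect_equal(recall[1], 1.0)
  expect_gte(recall[1] + 1e-9, recall[2])
  expect_gte(recall[2] + 1e-9, recall[3])
})
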