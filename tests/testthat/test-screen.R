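test_that("classify_expression applies the on/off/ambiguous bands", {
  th <- screen_thresholds(1, 0)
  expect_identical(classify_expression(c(61.3, 0, 0.5, 1), th),
                   c("on", "off", "ambiguous", "on"))
  expect_error(classify_expression(-1, th), "negative")
  expect_error(screen_thresholds(0, 0), "tau_on > tau_off")
  expect_error(screen_thresholds(1, -0.1), "tau_on > tau_off")
})

test_that("exclusivity calls are sorted and respect the thresholds", {
  vals <- matrix(
    c(10, 0, 0,     # exclusive
      10, 0, 0.5,   # ambiguous normal excludes
      10, 2, 0,     # shared
      0.5, 0, 0,    # silent in tumor
      20, 0, 0),    # exclusive, higher FPKM
    nrow = 5, byrow = TRUE,
    dimnames = list(sprintf("tx%d", 1:5), c("tumor", "n1", "n2"))
  )
  meta <- data.frame(sample_id = c("tumor", "n1", "n2"),
                     role = c("tumor", "normal_tissue", "normal_tissue"),
                     tissue = c("t", "a", "b"), stringsAsFactors = FALSE)
  mat <- expression_matrix(vals, meta)
  calls <- find_exclusive_transcripts(mat, "tumor", c("n1", "n2"))
  expect_identical(calls$transcript_id, c("tx5", "tx1"))
  expect_equal(calls$tumor_fpkm, c(20, 10))
  expect_error(find_exclusive_transcripts(mat, "tumor", character(0)), "non-empty")
  expect_error(find_exclusive_transcripts(mat, "nope", "n1"), "unknown sample")
})

test_that("exclusivity filter agrees with the exhaustive per-cell oracle", {
  set.seed(21)
  for (rep in 1:5) {
    mat <- random_expression(200, 17)
    th <- screen_thresholds(stats::runif(1, 0.5, 2), stats::runif(1, 0, 0.3))
    calls <- find_exclusive_transcripts(mat, "tumor",
                                        setdiff(sample_ids(mat), "tumor"), th)
    expect_setequal(calls$transcript_id,
                    exclusive_oracle(mat, "tumor",
                                     setdiff(sample_ids(mat), "tumor"), th))
  }
})

test_that("raising tau_on or lowering tau_off never adds an exclusive transcript", {
  set.seed(22)
  mat <- random_expression(300, 10)
  normals <- setdiff(sample_ids(mat), "tumor")
  base <- find_exclusive_transcripts(mat, "tumor", normals,
                                     screen_thresholds(1, 0.2))$transcript_id
  for (th in list(screen_thresholds(2, 0.2), screen_thresholds(1, 0.1),
                  screen_thresholds(5, 0))) {
    stricter <- find_exclusive_transcripts(mat, "tumor", normals, th)$transcript_id
    expect_true(all(stricter %in% base))
  }
})

test_that("replicate confirmation keeps on transcripts and reports absentees", {
  vals <- matrix(c(10, 0, 20, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("tx1", "tx2"), c("tumor", "n1")))
  meta <- data.frame(sample_id = c("tumor", "n1"),
                     role = c("tumor", "normal_tissue"),
                     tissue = c("t", "a"), stringsAsFactors = FALSE)
  mat <- expression_matrix(vals, meta)
  calls <- find_exclusive_transcripts(mat, "tumor", "n1")
  expect_identical(nrow(calls), 2L)

  # replicate equal to the original: idempotence
  same <- confirm_in_replicate(calls, mat, "tumor")
  expect_identical(same$transcript_id, calls$transcript_id)

  # one transcript off, one absent
  rep_vals <- matrix(c(0.2), nrow = 1, dimnames = list("tx2", "tumor"))
  rep_mat <- expression_matrix(rep_vals, meta[1, , drop = FALSE])
  kept <- confirm_in_replicate(calls, rep_mat, "tumor")
  expect_identical(nrow(kept), 0L)
  expect_identical(attr(kept, "dropped_absent"), "tx1")

  # empty call list passes through
  empty <- confirm_in_replicate(calls[0, ], mat, "tumor")
  expect_identical(nrow(empty), 0L)
  expect_error(confirm_in_replicate(calls, mat, "nope"), "unknown sample")
})
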