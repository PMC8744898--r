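plus_tx <- function(tss = 1000L, id = "txp") {
  transcript_model(id, "chr1", "+",
                   data.frame(start = tss, end = tss + 600L))
}
minus_tx <- function(tss = 1000L, id = "txm") {
  transcript_model(id, "chr1", "-",
                   data.frame(start = tss - 600L + 1L, end = tss + 1L))
}

test_that("promoter windows are strand-aware and clipped at zero", {
  w <- promoter_window(plus_tx(1000L), 500, 100)
  expect_identical(c(w$start, w$end), c(500L, 1100L))
  w <- promoter_window(minus_tx(1000L), 500, 100)
  expect_identical(c(w$start, w$end), c(901L, 1501L))
  w <- promoter_window(plus_tx(100L), 500, 100)
  expect_identical(c(w$start, w$end), c(0L, 200L))
  expect_error(promoter_window(plus_tx(), 0, 0), "not both 0")
})

test_that("window length equals upstream + downstream absent clipping", {
  set.seed(31)
  for (i in 1:200) {
    tss <- sample(5000:50000, 1)
    tx <- if (stats::runif(1) < 0.5) plus_tx(tss) else minus_tx(tss)
    up <- sample(0:2000, 1); down <- sample(0:1000, 1)
    if (up == 0 && down == 0) next
    w <- promoter_window(tx, up, down)
    expect_identical(w$end - w$start, up + down)
  }
})

test_that("count_overlaps uses half-open >=1 bp semantics, ignoring strand and other chromosomes", {
  w <- genomic_intervals("chr1", 10, 20)
  expect_identical(count_overlaps(w, genomic_intervals("chr1", 20, 30)), 0L)
  expect_identical(
    count_overlaps(w, genomic_intervals("chr1", c(19, 0), c(25, 10))), 1L)
  expect_identical(count_overlaps(w, genomic_intervals("chr2", 10, 20)), 0L)
  # symmetry under swapping window and a single track interval
  a <- genomic_intervals("chr1", 15, 40)
  expect_identical(count_overlaps(w, a), count_overlaps(a, w))
})

test_that("count_overlaps matches GenomicRanges on random cases", {
  set.seed(32)
  for (i in 1:1000) {
    w <- random_intervals(1)
    track <- random_intervals(sample(0:20, 1))
    expect_identical(as.integer(count_overlaps(w, track)), granges_count(w, track))
  }
})

test_that("differential openness needs a tumor peak and no normal peak", {
  tx <- plus_tx(1000L)
  inside <- genomic_intervals("chr1", 900, 1100)
  none <- genomic_intervals(character(0), integer(0), integer(0))
  ann <- annotate_promoter(tx, inside, none)
  expect_true(ann$differential_open)
  ann <- annotate_promoter(tx, inside, inside)
  expect_false(ann$differential_open)
  # duplicating a tumor peak changes counts, not the call
  dup <- rbind(inside, inside)
  ann2 <- annotate_promoter(tx, dup, none)
  expect_identical(ann2$tumor_dnase_peaks, 2L)
  expect_true(ann2$differential_open)
})

test_that("CAGE support reflects distance to the TSS", {
  tx <- plus_tx(1000L)
  none <- genomic_intervals(character(0), integer(0), integer(0))
  near <- genomic_intervals("chr1", 1050, 1070)
  far <- genomic_intervals("chr1", 2000, 2020)
  expect_true(annotate_promoter(tx, none, none, cage = near, cage_slack = 100)$cage_supported)
  expect_false(annotate_promoter(tx, none, none, cage = far, cage_slack = 100)$cage_supported)
})

test_that("planted open promoters are recovered exactly", {
  set.seed(33)
  truth <- synthetic_truth(n_transcripts = 60)
  seqs <- generate_transcript_sequences(truth, background_length = 900)
  tracks <- generate_tracks_and_ct(truth, seqs$transcripts)
  confirmed <- seqs$transcripts[truth$confirmed_ids]
  ann <- annotate_promoters(confirmed,
                            tumor_dnase = tracks$tumor_dnase,
                            normal_dnase = tracks$normal_dnase,
                            feature_tracks = tracks$feature_tracks,
                            cage = tracks$cage)
  expect_identical(sort(ann$transcript_id[ann$differential_open]),
                   truth$promoter_open_ids)
  expect_identical(sort(ann$transcript_id[ann$cage_supported]),
                   truth$promoter_open_ids)
})
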