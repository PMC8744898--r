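# Independent oracles used to cross-check the implementation. Each takes a
# deliberately different route from the code under test.

# ORF oracle: enumerate every ATG, walk forward codon by codon to its first
# in-frame stop, then keep the 5'-most ATG per (frame, stop).
orf_oracle <- function(sequence, min_len_aa) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  stops <- c("TAA", "TAG", "TGA")
  atg <- as.integer(gregexpr("ATG", sequence, fixed = TRUE)[[1]])
  atg <- atg[atg > 0] - 1L  # to 0-based
  cand <- list()
  for (a in atg) {
    j <- a + 3L
    while (j + 3L <= n) {
      codon <- substr(sequence, j + 1L, j + 3L)
      if (codon %in% stops) {
        cand[[length(cand) + 1L]] <- data.frame(
          frame = a %% 3L, start_nt = a, end_nt = j + 3L,
          length_aa = (j - a) %/% 3L
        )
        break
      }
      j <- j + 3L
    }
  }
  if (length(cand) == 0) {
    return(data.frame(frame = integer(0), start_nt = integer(0),
                      end_nt = integer(0), length_aa = integer(0)))
  }
  out <- do.call(rbind, cand)
  # 5'-most ATG per (frame, stop)
  out <- out[order(out$start_nt), , drop = FALSE]
  out <- out[!duplicated(out[, c("frame", "end_nt")]), , drop = FALSE]
  out <- out[out$length_aa > min_len_aa, , drop = FALSE]
  out <- out[order(out$start_nt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Interval-overlap oracle via GenomicRanges (1-based closed coordinates).
granges_count <- function(window, track) {
  if (nrow(track) == 0) return(0L)
  w <- GenomicRanges::GRanges(window$chrom,
                              IRanges::IRanges(window$start + 1L, window$end))
  tr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end))
  # chromosomes absent from one side are fine; silence the seqlevel notice
  suppressWarnings(unname(GenomicRanges::countOverlaps(w, tr)))
}

# Exhaustive per-cell application of the exclusivity rule.
exclusive_oracle <- function(mat, tumor, normals, thresholds) {
  keep <- character(0)
  for (id in rownames(mat$values)) {
    tumor_on <- mat$values[id, tumor] >= thresholds$tau_on
    normals_off <- TRUE
    for (s in normals) {
      if (mat$values[id, s] > thresholds$tau_off) normals_off <- FALSE
    }
    if (tumor_on && normals_off) keep <- c(keep, id)
  }
  keep
}

# Random helpers
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(50L, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + width,
                    strand = sample(c("+", "-", "."), n, replace = TRUE),
                    label = sprintf("iv%d", seq_len(n)))
}

random_expression <- function(n_tx, n_samples, p_zero = 0.5) {
  vals <- matrix(ifelse(stats::runif(n_tx * n_samples) < p_zero, 0,
                        stats::rlnorm(n_tx * n_samples, log(5), 1)),
                 nrow = n_tx,
                 dimnames = list(sprintf("tx%03d", seq_len(n_tx)),
                                 c("tumor", sprintf("normal%02d", seq_len(n_samples - 1)))))
  meta <- data.frame(
    sample_id = colnames(vals),
    role = c("tumor", rep("normal_tissue", n_samples - 1)),
    tissue = c("tumor", sprintf("tissue%02d", seq_len(n_samples - 1))),
    stringsAsFactors = FALSE
  )
  expression_matrix(vals, meta)
}

random_nt <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# The published six-candidate FPKM fixture shipped with the package.
table1_matrix <- function() {
  meta <- data.frame(
    sample_id = c("liver", "HepG2"),
    role = c("normal_tissue", "tumor"),
    tissue = c("liver", "liver_tumor"),
    stringsAsFactors = FALSE
  )
  read_expression_table(
    system.file("extdata", "table1_fpkm.tsv", package = "smorfscreen",
                mustWork = TRUE),
    meta
  )
}
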