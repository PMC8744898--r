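test_that("find_orfs handles the minimal worked cases", {
  got <- find_orfs("ATGAAATAA", min_len_aa = 0)
  expect_identical(nrow(got), 1L)
  expect_identical(got$peptide, "MK")
  expect_identical(got$length_aa, 2L)
  expect_identical(got$end_nt - got$start_nt, 3L * (got$length_aa + 1L))

  expect_identical(nrow(find_orfs("CCCCCC", 0)), 0L)
  # no in-frame stop before the end: discarded
  expect_identical(nrow(find_orfs("ATGAAAAAA", 0)), 0L)
  # strict inequality on the length floor
  orf50 <- paste0("ATG", strrep("GCT", 49), "TAA")
  expect_identical(nrow(find_orfs(orf50, 50)), 0L)
  expect_identical(nrow(find_orfs(orf50, 49)), 1L)
  # codons containing N match neither ATG nor stop
  expect_identical(nrow(find_orfs("ATNAAATAA", 0)), 0L)
  expect_error(find_orfs("ATGAXATAA", 0), "illegal character")
})

test_that("ORF enumeration matches the exhaustive per-ATG oracle on random sequences", {
  set.seed(41)
  for (i in 1:300) {
    s <- random_nt(600, p_n = if (i %% 10 == 0) 0.02 else 0)
    min_aa <- sample(c(0L, 5L, 20L, 50L), 1)
    got <- find_orfs(s, min_aa)
    want <- orf_oracle(s, min_aa)
    expect_identical(got[, c("frame", "start_nt", "end_nt", "length_aa")], want)
  }
})

test_that("every reported ORF re-translates to its stored peptide", {
  set.seed(42)
  for (i in 1:50) {
    s <- random_nt(800)
    orfs <- find_orfs(s, 5)
    for (j in seq_len(nrow(orfs))) {
      cds <- substr(s, orfs$start_nt[j] + 1, orfs$end_nt[j])
      expect_identical(translate(cds), orfs$peptide[j])
      expect_identical(nchar(orfs$peptide[j]), orfs$length_aa[j])
      expect_identical(orfs$start_nt[j] %% 3L, orfs$frame[j])
      expect_match(orfs$peptide[j], "^M")
    }
  }
})

test_that("appending a non-coding suffix after the last stop leaves ORFs unchanged", {
  set.seed(43)
  for (i in 1:20) {
    s <- random_nt(300)
    base <- find_orfs(s, 0)
    if (nrow(base) == 0) next
    suffix <- strrep("C", sample(3:30, 1))  # introduces no ATG and no stop
    expect_identical(find_orfs(paste0(s, suffix), 0), base)
  }
})

test_that("kozak_class scores the -3 purine and +4 G positions", {
  expect_identical(kozak_class("GCCACCATGG", 6), "strong")
  expect_identical(kozak_class("CCCCCCATGC", 6), "weak")
  # out-of-range -3 counts as failing; +4 G alone is adequate
  expect_identical(kozak_class("ATGG", 0), "adequate")
  expect_identical(kozak_class("CCCACCATGC", 6), "adequate")
  expect_error(kozak_class("GCCACCAAGG", 6), "no ATG")
})

test_that("translate follows the standard code, N-to-X and stop handling", {
  expect_identical(translate("ATGTAA"), "M")
  expect_identical(translate("ATGAANTAA"), "MX")
  expect_identical(translate("ATGAAA"), "MK")
  expect_error(translate("ATGAA"), "not divisible")
  expect_error(translate("CCCTAA"), "begin with ATG")
  expect_error(translate("ATGTAATAA"), "internal stop")
})

test_that("translate matches the Biostrings oracle on random CDS", {
  set.seed(44)
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"), c("A","C","G","T")),
                  1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  for (i in 1:30) {
    cds <- paste0("ATG",
                  paste(sample(sense, 59, replace = TRUE), collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1))
    oracle <- sub("\\*$", "", as.character(
      Biostrings::translate(Biostrings::DNAString(cds))))
    expect_identical(translate(cds), oracle)
  }
})

test_that("peptide mass is additive and bounded by the extreme residues", {
  expect_equal(peptide_mass("G"), 75.07)
  expect_equal(peptide_mass("GG"), 132.12)
  expect_error(peptide_mass(""), "empty")
  expect_error(peptide_mass("MX"), "outside the standard")
  set.seed(45)
  for (i in 1:50) {
    pep <- paste(sample(names(smorfscreen:::RESIDUE_MASS), 68, replace = TRUE),
                 collapse = "")
    m <- peptide_mass(pep)
    expect_gte(m, 68 * min(smorfscreen:::RESIDUE_MASS) + 18.02 - 0.01)
    expect_lte(m, 68 * max(smorfscreen:::RESIDUE_MASS) + 18.02 + 0.01)
  }
})
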