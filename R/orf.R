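STOP_CODONS <- c("TAA", "TAG", "TGA")

# Average (not monoisotopic) residue masses in daltons, Expasy values.
# Average masses match the kDa scale of SDS-PAGE estimates.
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

check_nt <- function(sequence, what = "sequence") {
  stopifnot(is.character(sequence), length(sequence) == 1)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0) {
    stop(sprintf("illegal character '%s' in %s at offset %d",
                 substr(sequence, bad, bad), what, as.integer(bad)))
  }
  invisible(sequence)
}

#' Enumerate sense-strand open reading frames
#'
#' Scans the three sense-strand frames of a transcript. An ORF runs from
#' the 5'-most ATG to its first in-frame stop codon (TAA/TAG/TGA), giving
#' one ORF per (frame, stop) pair; downstream in-frame ATGs sharing the
#' stop are not counted separately. ORFs whose stop would lie beyond the
#' transcript end are discarded (no read-through), and codons containing N
#' never match ATG or a stop. Only ORFs strictly longer than `min_len_aa`
#' amino acids (the start codon counted, the stop not) are kept — so with
#' the default 50 a 50-aa ORF fails and 52- or 68-aa ORFs pass. Antisense
#' frames are not scanned: the transcript itself is the translated
#' molecule.
#'
#' @param sequence Nucleotide string over `{A,C,G,T,N}`.
#' @param min_len_aa Minimum ORF length in amino acids, exclusive bound.
#' @return `data.frame` sorted by `start_nt` with columns `frame` (0-2),
#'   `start_nt` (0-based offset of the A of ATG), `end_nt` (0-based
#'   exclusive, after the stop codon), `length_aa`, `kozak` (see
#'   [kozak_class()]) and `peptide`.
#' @export
#' @examples
#' find_orfs("ATGAAATAA", min_len_aa = 0)
find_orfs <- function(sequence, min_len_aa = 50L) {
  sequence <- toupper(sequence)
  check_nt(sequence)
  stopifnot(min_len_aa >= 0)
  n <- nchar(sequence)
  empty <- data.frame(frame = integer(0), start_nt = integer(0), end_nt = integer(0),
                      length_aa = integer(0), kozak = character(0), peptide = character(0),
                      stringsAsFactors = FALSE)
  if (n < 6) return(empty)
  hits <- list()
  for (frame in 0:2) {
    codon_starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    if (length(codon_starts) == 0) next
    codons <- substring(sequence, codon_starts, codon_starts + 2L)
    has_n <- grepl("N", codons, fixed = TRUE)
    is_start <- codons == "ATG" & !has_n
    is_stop <- codons %in% STOP_CODONS & !has_n
    open_at <- NA_integer_  # codon index of the 5'-most unmatched ATG
    for (k in seq_along(codons)) {
      if (is_stop[k]) {
        if (!is.na(open_at)) {
          len_aa <- k - open_at
          if (len_aa > min_len_aa) {
            start_nt <- codon_starts[open_at] - 1L  # to 0-based
            end_nt <- codon_starts[k] + 2L
            hits[[length(hits) + 1L]] <- data.frame(
              frame = frame, start_nt = start_nt, end_nt = end_nt,
              length_aa = len_aa,
              kozak = kozak_class(sequence, start_nt),
              peptide = translate(substr(sequence, start_nt + 1L, end_nt)),
              stringsAsFactors = FALSE
            )
          }
          open_at <- NA_integer_
        }
      } else if (is_start[k] && is.na(open_at)) {
        open_at <- k
      }
    }
  }
  if (length(hits) == 0) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start_nt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of transcript sequences for ORFs
#'
#' @param sequences Named character vector of transcript sequences.
#' @param min_len_aa Minimum ORF length in amino acids, exclusive bound.
#' @return `data.frame` with a `transcript_id` column prepended to the
#'   [find_orfs()] columns, transcripts in input order.
#' @export
scan_orfs <- function(sequences, min_len_aa = 50L) {
  per_tx <- lapply(names(sequences), function(id) {
    orfs <- find_orfs(sequences[[id]], min_len_aa)
    if (nrow(orfs)) cbind(transcript_id = id, orfs, stringsAsFactors = FALSE) else NULL
  })
  per_tx <- Filter(Negate(is.null), per_tx)
  if (length(per_tx) == 0) {
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      start_nt = integer(0), end_nt = integer(0),
                      length_aa = integer(0), kozak = character(0),
                      peptide = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, per_tx)
  rownames(out) <- NULL
  out
}

#' Kozak-context class of a start codon
#'
#' The two key positions of the Kozak consensus are a purine (A/G) three
#' bases before the A of the ATG (position -3) and a G immediately after
#' the G of the ATG (position +4). Both satisfied is `strong`, exactly one
#' is `adequate`, neither is `weak`; positions falling outside the sequence
#' count as failing.
#'
#' @param sequence Nucleotide string.
#' @param start_nt 0-based offset of the A of an ATG in `sequence`.
#' @return `"strong"`, `"adequate"` or `"weak"`.
#' @export
#' @examples
#' kozak_class("GCCACCATGG", 6)
kozak_class <- function(sequence, start_nt) {
  sequence <- toupper(sequence)
  check_nt(sequence)
  if (substr(sequence, start_nt + 1L, start_nt + 3L) != "ATG") {
    stop(sprintf("no ATG at offset %d", start_nt))
  }
  minus3 <- if (start_nt >= 3) substr(sequence, start_nt - 2L, start_nt - 2L) else ""
  plus4 <- if (nchar(sequence) >= start_nt + 4L) {
    substr(sequence, start_nt + 4L, start_nt + 4L)
  } else ""
  score <- (minus3 %in% c("A", "G")) + (plus4 == "G")
  c("weak", "adequate", "strong")[score + 1L]
}

#' Translate a coding sequence with the standard genetic code
#'
#' The CDS must start with ATG and be a whole number of codons; a trailing
#' stop codon is dropped from the peptide, an internal stop is an error,
#' and any codon containing N translates to `X`.
#'
#' @param cds Nucleotide string, length divisible by 3, beginning with ATG.
#' @return Amino-acid string.
#' @export
translate <- function(cds) {
  cds <- toupper(cds)
  check_nt(cds, "CDS")
  if (nchar(cds) %% 3 != 0) stop(sprintf("CDS length %d not divisible by 3", nchar(cds)))
  if (nchar(cds) < 3 || substr(cds, 1, 3) != "ATG") stop("CDS must begin with ATG")
  starts <- seq.int(1L, nchar(cds), by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- ifelse(grepl("N", codons, fixed = TRUE), "X", unname(code[codons]))
  is_stop <- !is.na(aa) & aa == "*"
  if (any(is_stop[-length(aa)])) {
    stop(sprintf("internal stop codon at codon %d", which(is_stop)[1]))
  }
  if (is_stop[length(aa)]) aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Predicted average molecular mass of a peptide
#'
#' Sum of average residue masses plus one water (18.02 Da), reported to
#' 0.01 Da. Average rather than monoisotopic masses are used so predictions
#' sit on the same scale as gel-based kDa estimates.
#'
#' @param peptide Amino-acid string over the 20 standard letters
#'   (`X` disallowed).
#' @return Mass in daltons, rounded to 2 decimals.
#' @export
#' @examples
#' peptide_mass("G")  # 75.07
peptide_mass <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1)
  if (!nzchar(peptide)) stop("empty peptide")
  letters <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- setdiff(letters, names(RESIDUE_MASS))
  if (length(bad)) stop(sprintf("letter '%s' outside the standard amino-acid alphabet", bad[1]))
  round(sum(RESIDUE_MASS[letters]) + WATER_MASS, 2)
}
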