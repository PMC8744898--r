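#' Construct a transcript model
#'
#' The genomic anatomy of a transcript: chromosome, strand, ordered disjoint
#' exons (0-based half-open) and optionally its spliced sense-strand
#' sequence. The transcription start site (TSS) is derived from the exons:
#' the first exon start on `+`, the last exon end minus one on `-`.
#'
#' @param id Transcript identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Interval `data.frame` (columns `start`, `end`), sorted by
#'   start and non-overlapping.
#' @param sequence Optional spliced sequence over `{A,C,G,T,N}`; its length
#'   must equal the summed exon length.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(id, chrom, strand, exons, sequence = NULL) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (!strand %in% c("+", "-")) stop(sprintf("transcript '%s': strand must be '+' or '-'", id))
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)), nrow(exons) >= 1)
  exons <- data.frame(start = as.integer(exons$start), end = as.integer(exons$end))
  if (any(exons$end <= exons$start)) stop(sprintf("transcript '%s': empty exon", id))
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(utils::head(exons$end, -1) > utils::tail(exons$start, -1))) {
    stop(sprintf("transcript '%s': exons must be sorted and disjoint", id))
  }
  tss <- if (strand == "+") exons$start[1] else exons$end[nrow(exons)] - 1L
  width <- sum(exons$end - exons$start)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (grepl("[^ACGTN]", sequence)) stop(sprintf("transcript '%s': illegal sequence character", id))
    if (nchar(sequence) != width) {
      stop(sprintf("transcript '%s': sequence length %d != exon span %d",
                   id, nchar(sequence), width))
    }
  }
  structure(
    list(id = id, chrom = chrom, strand = strand, exons = exons,
         tss = tss, sequence = sequence),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s %s:%d-%d (%s), %d exon(s), tss=%d%s\n",
              x$id, x$chrom, x$exons$start[1], x$exons$end[nrow(x$exons)],
              x$strand, nrow(x$exons), x$tss,
              if (is.null(x$sequence)) "" else sprintf(", %d nt", nchar(x$sequence))))
  invisible(x)
}

#' Write / read transcript models as a TSV table
#'
#' A compact text serialization: one row per transcript with exons encoded
#' as comma-separated `start-end` 0-based half-open blocks. Sequences travel
#' separately in FASTA.
#'
#' @param models Named list of `transcript_model` objects.
#' @param path TSV path.
#' @param sequences Optional named character vector of spliced sequences to
#'   attach on read.
#' @return `path` (write) or a named list of `transcript_model` (read).
#' @export
write_transcript_models <- function(models, path) {
  rows <- vapply(models, function(m) {
    sprintf("%s\t%s\t%s\t%s", m$id, m$chrom, m$strand,
            paste(sprintf("%d-%d", m$exons$start, m$exons$end), collapse = ","))
  }, character(1))
  writeLines(c("id\tchrom\tstrand\texons", rows), path)
  invisible(path)
}

#' @rdname write_transcript_models
#' @export
read_transcript_models <- function(path, sequences = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(tab)), function(i) {
    blocks <- strsplit(strsplit(tab$exons[i], ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
    exons <- data.frame(
      start = as.integer(vapply(blocks, `[[`, character(1), 1)),
      end = as.integer(vapply(blocks, `[[`, character(1), 2))
    )
    transcript_model(tab$id[i], tab$chrom[i], tab$strand[i], exons,
                     sequence = if (!is.null(sequences) && tab$id[i] %in% names(sequences))
                       sequences[[tab$id[i]]] else NULL)
  })
  stats::setNames(models, tab$id)
}
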