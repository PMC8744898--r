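#' Read transcript sequences from FASTA
#'
#' Sequences are uppercased and RNA is normalized to DNA (`U -> T`) so RNA
#' and DNA FASTA files are interchangeable. Characters outside
#' `{A,C,G,T,N,U}` are rejected with the record id and 1-based offset of the
#' first offending character.
#'
#' @param path Path to a FASTA file. An empty file yields an empty result.
#' @return A named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  raw_lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(raw_lines)))) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop(sprintf("FASTA record %d has an empty header", which(!nzchar(ids))[1]))
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTNU]", seqs[[i]])
    if (bad > 0) {
      stop(sprintf("illegal character '%s' in record '%s' at offset %d",
                   substr(seqs[[i]], bad, bad), ids[i], as.integer(bad)))
    }
  }
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of nucleotide (or peptide) sequences.
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (length(seqs) && (is.null(names(seqs)) || any(!nzchar(names(seqs))))) {
    stop("every sequence needs a non-empty name")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
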