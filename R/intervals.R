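#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames in 0-based half-open coordinates, the
#' convention of the BED format that carries all interval tracks consumed by
#' the pipeline (DNase peaks, cCREs, CAGE clusters, TF/histone peaks).
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, 0-based exclusive end positions.
#' @param strand Strand symbols, each one of `"+"`, `"-"`, `"."`.
#' @param label Free-text labels (e.g. peak names); `NA` allowed.
#'
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `label`, validated so that `start >= 0` and `end > start` for every row.
#' @export
#' @examples
#' genomic_intervals("chr1", 10, 20)
genomic_intervals <- function(chrom, start, end, strand = ".", label = NA_character_) {
  n <- length(chrom)
  strand <- rep_len(as.character(strand), n)
  label <- rep_len(as.character(label), n)
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    label = as.character(label),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x, context = "interval set") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end", "strand")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop(sprintf("%s lacks column(s): %s", context, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(x$start < 0)
  if (length(bad)) stop(sprintf("%s: negative start at row %d", context, bad[1]))
  bad <- which(x$end <= x$start)
  if (length(bad)) {
    stop(sprintf(
      "%s: end (%d) <= start (%d) at row %d",
      context, x$end[bad[1]], x$start[bad[1]], bad[1]
    ))
  }
  bad <- which(!x$strand %in% c("+", "-", "."))
  if (length(bad)) stop(sprintf("%s: illegal strand '%s' at row %d", context, x$strand[bad[1]], bad[1]))
  invisible(x)
}

#' Read a BED file of genomic intervals
#'
#' Accepts the 3-6 column tab-separated BED dialect with 0-based half-open
#' coordinates. Column 4 becomes `label`, column 6 becomes `strand`; both
#' default to missing/`"."` when absent. Coordinates are validated row by
#' row and errors name the offending line.
#'
#' @param path Path to a BED file.
#' @return A validated interval `data.frame` (see [genomic_intervals()]),
#'   rows in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("BED file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(genomic_intervals(character(0), integer(0), integer(0), character(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  bad <- which(n_col < 3)
  if (length(bad)) {
    stop(sprintf("BED line %d has %d column(s); at least 3 required", bad[1], n_col[bad[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start_chr <- vapply(fields, `[[`, character(1), 2)
  end_chr <- vapply(fields, `[[`, character(1), 3)
  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad <- which(is.na(start) | is.na(end) |
                 start_chr != as.character(start) | end_chr != as.character(end))
  if (length(bad)) {
    stop(sprintf("BED line %d: non-integer coordinates ('%s', '%s')",
                 bad[1], start_chr[bad[1]], end_chr[bad[1]]))
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop(sprintf("BED line %d: end (%d) <= start (%d)", bad[1], end[bad[1]], start[bad[1]]))
  }
  label <- ifelse(n_col >= 4, vapply(fields, function(f) f[min(4, length(f))], character(1)), NA_character_)
  label[label == "."] <- NA_character_
  strand <- ifelse(n_col >= 6, vapply(fields, function(f) f[min(6, length(f))], character(1)), ".")
  genomic_intervals(chrom, start, end, strand, label)
}

#' Write genomic intervals as BED
#'
#' Emits BED6 (`chrom start end name score strand`) with `"."` for missing
#' labels and score 0, so that `read_bed(write_bed(x))` reproduces `x`.
#'
#' @param x Interval data frame (see [genomic_intervals()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "write_bed input")
  label <- ifelse(is.na(x$label), ".", x$label)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, x$start, x$end, label, x$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Count track intervals overlapping a window
#'
#' Overlap is sharing at least one base under 0-based half-open semantics;
#' strand is ignored (accessibility tracks are unstranded) and intervals on
#' other chromosomes contribute zero rather than erroring.
#'
#' @param window A single-row interval data frame.
#' @param track An interval data frame (the annotation track).
#' @return Integer overlap count.
#' @export
#' @examples
#' w <- genomic_intervals("chr1", 10, 20)
#' count_overlaps(w, genomic_intervals("chr1", c(19, 20), c(25, 30)))
count_overlaps <- function(window, track) {
  validate_intervals(window, "window")
  validate_intervals(track, "track")
  if (nrow(window) != 1) stop("window must be a single interval")
  if (nrow(track) == 0) return(0L)
  sum(track$chrom == window$chrom &
        track$start < window$end &
        window$start < track$end)
}
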