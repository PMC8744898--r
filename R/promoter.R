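#' Strand-aware proximal promoter window
#'
#' Builds the promoter interval around a transcript's TSS: `upstream` bases
#' 5' of the TSS and `downstream` bases into the transcript. For a `+`
#' transcript this is `[tss - upstream, tss + downstream)`; for `-` it is
#' the mirror image `[tss - downstream + 1, tss + upstream + 1)`. Windows
#' are clipped at position 0. The 1000/500 default is a conventional
#' proximal-promoter definition.
#'
#' @param transcript A [transcript_model()].
#' @param upstream Bases upstream of the TSS (`>= 0`).
#' @param downstream Bases downstream of the TSS (`>= 0`); not both 0.
#' @return A single-row interval `data.frame` labelled with the transcript id.
#' @export
promoter_window <- function(transcript, upstream = 1000L, downstream = 500L) {
  stopifnot(inherits(transcript, "transcript_model"))
  if (upstream < 0 || downstream < 0 || (upstream == 0 && downstream == 0)) {
    stop("upstream/downstream must be >= 0 and not both 0")
  }
  tss <- transcript$tss
  if (is.null(tss) || is.null(transcript$strand)) {
    stop(sprintf("transcript '%s' lacks tss or strand", transcript$id))
  }
  if (transcript$strand == "+") {
    start <- tss - upstream
    end <- tss + downstream
  } else {
    start <- tss - downstream + 1L
    end <- tss + upstream + 1L
  }
  genomic_intervals(transcript$chrom, max(start, 0L), end,
                    strand = transcript$strand, label = transcript$id)
}

#' Annotate a candidate promoter with chromatin evidence
#'
#' Counts tumor and normal DNase peaks, arbitrary feature tracks (cCREs,
#' histone marks, TF peaks) overlapping the promoter window, and checks
#' whether a CAGE cluster supports the annotated TSS. `differential_open`
#' is true when the tumor carries at least one DNase peak in the window and
#' the matched normal carries none — the chromatin signature of
#' tumor-specific activation. Accessibility is annotated evidence, not a
#' filter: candidates without open promoters stay in the screen.
#'
#' @param transcript A [transcript_model()].
#' @param tumor_dnase,normal_dnase DNase peak tracks (interval data frames).
#' @param feature_tracks Named list of additional tracks to count.
#' @param cage CAGE cluster track, or `NULL` to skip TSS support.
#' @param upstream,downstream Promoter window parameters.
#' @param cage_slack Maximum distance (bp) between a CAGE cluster and the
#'   TSS for the TSS to count as CAGE-supported.
#' @return One-row `data.frame`: `transcript_id`, window coordinates,
#'   `tumor_dnase_peaks`, `normal_dnase_peaks`, `differential_open`,
#'   `cage_supported`, and one `n_<track>` count column per feature track.
#' @export
annotate_promoter <- function(transcript, tumor_dnase, normal_dnase,
                              feature_tracks = list(), cage = NULL,
                              upstream = 1000L, downstream = 500L,
                              cage_slack = 100L) {
  window <- promoter_window(transcript, upstream, downstream)
  n_tumor <- count_overlaps(window, tumor_dnase)
  n_normal <- count_overlaps(window, normal_dnase)
  cage_supported <- FALSE
  if (!is.null(cage) && nrow(cage)) {
    tss_zone <- genomic_intervals(transcript$chrom,
                                  max(transcript$tss - cage_slack, 0L),
                                  transcript$tss + cage_slack + 1L)
    cage_supported <- count_overlaps(tss_zone, cage) >= 1
  }
  out <- data.frame(
    transcript_id = transcript$id,
    chrom = window$chrom, window_start = window$start, window_end = window$end,
    tumor_dnase_peaks = n_tumor,
    normal_dnase_peaks = n_normal,
    differential_open = n_tumor >= 1 && n_normal == 0,
    cage_supported = cage_supported,
    stringsAsFactors = FALSE
  )
  for (nm in names(feature_tracks)) {
    out[[paste0("n_", nm)]] <- count_overlaps(window, feature_tracks[[nm]])
  }
  out
}

#' Annotate promoters for a set of transcripts
#'
#' @param transcripts Named list of [transcript_model()] objects.
#' @inheritParams annotate_promoter
#' @return `data.frame`, one row per transcript (see [annotate_promoter()]).
#' @export
annotate_promoters <- function(transcripts, tumor_dnase, normal_dnase,
                               feature_tracks = list(), cage = NULL,
                               upstream = 1000L, downstream = 500L,
                               cage_slack = 100L) {
  if (length(transcripts) == 0) {
    return(data.frame(transcript_id = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(transcripts, annotate_promoter,
                 tumor_dnase = tumor_dnase, normal_dnase = normal_dnase,
                 feature_tracks = feature_tracks, cage = cage,
                 upstream = upstream, downstream = downstream,
                 cage_slack = cage_slack)
  out <- do.call(rbind, c(rows, list(stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
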