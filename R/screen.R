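#' Expression thresholds for the exclusivity screen
#'
#' Two FPKM cutoffs define the screen: a transcript is "on" at or above
#' `tau_on` and "off" at or below `tau_off`; values in between are
#' ambiguous. The defaults (on at 1 FPKM, off only at exactly 0) are
#' deliberately strict: tumor-exclusive candidates are expected to show
#' zero signal across the normal panel.
#'
#' @param tau_on FPKM at or above which a transcript counts as expressed.
#' @param tau_off FPKM at or below which a transcript counts as silent.
#' @return An object of class `screen_thresholds`.
#' @export
screen_thresholds <- function(tau_on = 1.0, tau_off = 0.0) {
  stopifnot(is.numeric(tau_on), is.numeric(tau_off))
  if (!(tau_on > tau_off) || tau_off < 0) {
    stop("thresholds require tau_on > tau_off >= 0")
  }
  structure(list(tau_on = tau_on, tau_off = tau_off), class = "screen_thresholds")
}

#' Classify an FPKM value as on / off / ambiguous
#'
#' @param fpkm Non-negative numeric vector of FPKM values.
#' @param thresholds A [screen_thresholds()] object.
#' @return Character vector over `{"on","off","ambiguous"}`.
#' @export
#' @examples
#' classify_expression(c(61.3, 0, 0.5), screen_thresholds(1, 0))
classify_expression <- function(fpkm, thresholds = screen_thresholds()) {
  stopifnot(inherits(thresholds, "screen_thresholds"), is.numeric(fpkm))
  if (any(is.na(fpkm))) stop("FPKM must not be missing")
  if (any(fpkm < 0)) stop(sprintf("negative FPKM: %g", fpkm[fpkm < 0][1]))
  ifelse(fpkm >= thresholds$tau_on, "on",
         ifelse(fpkm <= thresholds$tau_off, "off", "ambiguous"))
}

#' Find tumor-exclusive transcripts
#'
#' A transcript is called exclusive when it is "on" in the tumor sample and
#' "off" in every normal sample; an ambiguous value in any normal sample
#' excludes it (conservative: true tumor-exclusive transcripts show zero
#' normal signal). Results are sorted by descending tumor FPKM, ties broken
#' by transcript id.
#'
#' @param matrix An [expression_matrix()].
#' @param tumor_sample Sample id of the tumor column.
#' @param normal_samples Non-empty character vector of normal sample ids.
#' @param thresholds A [screen_thresholds()] object.
#' @return `data.frame` with columns `transcript_id`, `tumor_fpkm`,
#'   `max_normal_fpkm`, `status` (always `"exclusive"`).
#' @export
find_exclusive_transcripts <- function(matrix, tumor_sample, normal_samples,
                                       thresholds = screen_thresholds()) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (length(normal_samples) == 0) stop("normal_samples must be non-empty")
  unknown <- setdiff(c(tumor_sample, normal_samples), sample_ids(matrix))
  if (length(unknown)) stop(sprintf("unknown sample id: %s", unknown[1]))
  if (nrow(matrix$values) == 0) {
    return(data.frame(transcript_id = character(0), tumor_fpkm = numeric(0),
                      max_normal_fpkm = numeric(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  tumor <- matrix$values[, tumor_sample]
  normals <- matrix$values[, normal_samples, drop = FALSE]
  max_normal <- apply(normals, 1, max)
  tumor_on <- classify_expression(tumor, thresholds) == "on"
  all_normals_off <- apply(normals, 1, function(v) {
    all(classify_expression(v, thresholds) == "off")
  })
  keep <- tumor_on & all_normals_off
  out <- data.frame(
    transcript_id = transcript_ids(matrix)[keep],
    tumor_fpkm = unname(tumor[keep]),
    max_normal_fpkm = unname(max_normal[keep]),
    status = rep("exclusive", sum(keep)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$tumor_fpkm, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confirm exclusivity calls in an independent replicate
#'
#' Keeps only calls whose transcript is "on" in the replicate tumor sample.
#' Transcripts absent from the replicate matrix are dropped and reported in
#' the `dropped_absent` attribute of the result.
#'
#' @param calls Output of [find_exclusive_transcripts()].
#' @param replicate An [expression_matrix()] containing `tumor_sample`.
#' @param tumor_sample Sample id of the replicate tumor column.
#' @param thresholds A [screen_thresholds()] object.
#' @return Filtered calls `data.frame`, attribute `dropped_absent` holding
#'   ids missing from the replicate.
#' @export
confirm_in_replicate <- function(calls, replicate, tumor_sample,
                                 thresholds = screen_thresholds()) {
  stopifnot(inherits(replicate, "ExpressionMatrix"))
  if (!tumor_sample %in% sample_ids(replicate)) {
    stop(sprintf("unknown sample id: %s", tumor_sample))
  }
  present <- calls$transcript_id %in% transcript_ids(replicate)
  dropped <- calls$transcript_id[!present]
  kept <- calls[present, , drop = FALSE]
  if (nrow(kept)) {
    rep_fpkm <- replicate$values[kept$transcript_id, tumor_sample]
    kept <- kept[classify_expression(rep_fpkm, thresholds) == "on", , drop = FALSE]
  }
  rownames(kept) <- NULL
  attr(kept, "dropped_absent") <- dropped
  kept
}
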