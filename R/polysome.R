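#' Cytoplasmic fraction of a transcript from compartment FPKMs
#'
#' The exported share of a transcript's steady-state RNA, estimated as
#' `cyt / (cyt + nuc)` from cytoplasmic and nuclear FPKMs. A transcript
#' detected in neither compartment has no defined localization and is an
#' error here; such transcripts are excluded upstream as not expressed.
#'
#' @param fpkm_cyt,fpkm_nuc Non-negative FPKM in the cytoplasmic and
#'   nuclear compartments (vectorized).
#' @return Numeric in `[0, 1]`.
#' @export
#' @examples
#' cytoplasmic_fraction(10, 0)
cytoplasmic_fraction <- function(fpkm_cyt, fpkm_nuc) {
  stopifnot(is.numeric(fpkm_cyt), is.numeric(fpkm_nuc))
  if (any(fpkm_cyt < 0) || any(fpkm_nuc < 0)) stop("FPKM must be non-negative")
  both_zero <- fpkm_cyt == 0 & fpkm_nuc == 0
  if (any(both_zero)) {
    stop("transcript not expressed in either compartment; cytoplasmic fraction undefined")
  }
  fpkm_cyt / (fpkm_cyt + fpkm_nuc)
}

#' RNA distribution across gradient fractions from qPCR CT values
#'
#' Converts per-fraction CT values into the relative RNA mass per fraction.
#' Template abundance scales as `E^(-CT)` for amplification efficiency `E`
#' (2 = perfect doubling per cycle), so the mass in fraction i is
#' `p_i = E^(-ct_i) / sum_j E^(-ct_j)`. A missing CT (no amplification) is
#' treated as zero abundance rather than an imputed limit-of-detection
#' cycle. Adding a constant to every CT leaves the distribution unchanged.
#'
#' @param ct_values Numeric CT vector, `NA` = no amplification; at least
#'   one value must be present.
#' @param efficiency Amplification efficiency per cycle, `1 < E <= 2`.
#' @return Numeric vector of per-fraction masses summing to 1.
#' @export
#' @examples
#' fraction_distribution(c(20, 21, 22))  # 4/7, 2/7, 1/7
fraction_distribution <- function(ct_values, efficiency = 2.0) {
  stopifnot(is.numeric(ct_values))
  if (!(efficiency > 1 && efficiency <= 2)) stop("efficiency must satisfy 1 < E <= 2")
  if (all(is.na(ct_values))) stop("all CT values absent")
  # shift by the minimum CT before exponentiating, for numerical stability
  shifted <- ct_values - min(ct_values, na.rm = TRUE)
  w <- ifelse(is.na(shifted), 0, efficiency^(-shifted))
  w / sum(w)
}

#' A sucrose-gradient fraction profile for one transcript
#'
#' Bundles ordered fraction CT values (gradient top to bottom) with the
#' derived RNA distribution and the set of fractions designated polysomal
#' (by default the bottom 40% of the gradient, where polysome-bound, i.e.
#' actively translated, RNA sediments).
#'
#' @param transcript_id Transcript identifier.
#' @param ct_values Numeric CT per fraction, `NA` = no amplification.
#' @param fraction_labels Optional labels, gradient top to bottom.
#' @param efficiency Amplification efficiency per cycle.
#' @param polysome_set Integer indices of polysomal fractions; default the
#'   bottom 40% (see [default_polysome_set()]).
#' @return An object of class `fraction_profile` with the computed
#'   `distribution`.
#' @export
fraction_profile <- function(transcript_id, ct_values,
                             fraction_labels = NULL, efficiency = 2.0,
                             polysome_set = default_polysome_set(length(ct_values))) {
  if (is.null(fraction_labels)) {
    fraction_labels <- if (!is.null(names(ct_values))) names(ct_values)
    else sprintf("F%d", seq_along(ct_values))
  }
  stopifnot(length(fraction_labels) == length(ct_values))
  polysome_set <- as.integer(polysome_set)
  if (any(polysome_set < 1 | polysome_set > length(ct_values))) {
    stop("polysome_set indices outside the fraction range")
  }
  structure(
    list(transcript_id = transcript_id,
         fraction_labels = fraction_labels,
         ct_values = unname(ct_values),
         efficiency = efficiency,
         distribution = fraction_distribution(ct_values, efficiency),
         polysome_set = polysome_set),
    class = "fraction_profile"
  )
}

#' Default polysomal fraction set: the bottom of the gradient
#'
#' @param n_fractions Number of gradient fractions (top to bottom).
#' @param bottom_prop Proportion of the gradient bottom taken as polysomal.
#' @return Integer indices of the polysomal fractions.
#' @export
default_polysome_set <- function(n_fractions, bottom_prop = 0.4) {
  stopifnot(n_fractions >= 1, bottom_prop > 0, bottom_prop <= 1)
  k <- max(1L, floor(n_fractions * bottom_prop))
  seq.int(n_fractions - k + 1L, n_fractions)
}

#' Polysome enrichment score and translation call
#'
#' The score is the RNA mass falling in the polysomal fractions; a
#' transcript is called translated when at least `cutoff` of its RNA
#' sediments there.
#'
#' @param profile A [fraction_profile()].
#' @param cutoff Minimum polysomal mass for a translated call.
#' @return List with `score` in `[0, 1]` and logical `translated`.
#' @export
polysome_enrichment <- function(profile, cutoff = 0.5) {
  stopifnot(inherits(profile, "fraction_profile"))
  if (length(profile$polysome_set) == 0) stop("empty polysome_set")
  score <- sum(profile$distribution[profile$polysome_set])
  list(score = score, translated = score >= cutoff)
}

#' Relative expression by the delta-Ct method
#'
#' Expression of a target standardized to a reference gene (GAPDH in a
#' typical qRT-PCR design): `E^(-(ct_target - ct_reference))`. Knockdown
#' ratios between conditions are ratios of these levels.
#'
#' @param ct_target,ct_reference CT values (vectorized; no `NA`).
#' @param efficiency Amplification efficiency per cycle.
#' @return Fold level relative to the reference.
#' @export
#' @examples
#' relative_expression(21, 20)  # 0.5
relative_expression <- function(ct_target, ct_reference, efficiency = 2.0) {
  if (any(is.na(ct_target)) || any(is.na(ct_reference))) stop("absent CT value")
  if (!(efficiency > 1 && efficiency <= 2)) stop("efficiency must satisfy 1 < E <= 2")
  efficiency^(-(ct_target - ct_reference))
}

#' Read a qPCR CT table
#'
#' Comma-separated: one row per transcript (including any control such as
#' Actin), one column per gradient fraction ordered top to bottom, blank
#' cells meaning no amplification.
#'
#' @param path CSV path.
#' @return Numeric matrix, rownames = transcript ids, `NA` for blanks.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("CT table not found: %s", path))
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop(sprintf("duplicate transcript id '%s'", ids[duplicated(ids)][1]))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a qPCR CT table
#' @param ct Numeric matrix (rownames = transcripts, columns = fractions).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  tab <- data.frame(transcript_id = rownames(ct), ct,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
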