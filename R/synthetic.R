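#' Truth labels for a synthetic screening cohort
#'
#' Draws the nested sets of planted signals that the screen funnel should
#' recover: tumor-exclusive transcripts, the subset confirmed in a
#' replicate, those carrying a qualifying small ORF, those exported to the
#' cytoplasm, those enriched on polysomes, and those with a tumor-open
#' promoter. The defaults mirror a 12 / 9 / 6 / 5 / 3 funnel with 7 of 9
#' confirmed promoters differentially open. Nesting is enforced:
#' translated within exported within ORF-bearing within confirmed within
#' exclusive.
#'
#' @param n_transcripts Cohort size.
#' @param n_exclusive,n_confirmed,n_orf,n_exported,n_translated Funnel
#'   sizes, each at most the previous.
#' @param n_promoter_open Confirmed transcripts with a tumor-only open
#'   promoter (at most `n_confirmed`).
#' @param flagship_orf_lengths,flagship_orf_kozak ORF lengths (aa) and
#'   Kozak classes planted in the first ORF-bearing transcript; the default
#'   plants a weak 52-aa and a strong 68-aa ORF.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_transcripts = 500L, n_exclusive = 12L,
                            n_confirmed = 9L, n_orf = 6L, n_exported = 5L,
                            n_translated = 3L, n_promoter_open = 7L,
                            flagship_orf_lengths = c(52L, 68L),
                            flagship_orf_kozak = c("weak", "strong"),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- c(n_transcripts, n_exclusive, n_confirmed, n_orf, n_exported, n_translated)
  if (any(diff(sizes) > 0) || any(sizes < 0)) {
    stop("infeasible truth spec: require n_transcripts >= n_exclusive >= n_confirmed >= n_orf >= n_exported >= n_translated >= 0")
  }
  if (n_promoter_open > n_confirmed) stop("infeasible truth spec: n_promoter_open > n_confirmed")
  stopifnot(length(flagship_orf_lengths) == length(flagship_orf_kozak))
  ids <- sprintf("SYNTX%05d.1", seq_len(n_transcripts))
  exclusive <- sort(sample(ids, n_exclusive))
  confirmed <- sort(sample(exclusive, n_confirmed))
  orf_ids <- sort(sample(confirmed, n_orf))
  exported <- sort(sample(orf_ids, n_exported))
  translated <- sort(sample(exported, n_translated))
  promoter_open <- sort(sample(confirmed, n_promoter_open))
  orf_spec <- stats::setNames(vector("list", n_exclusive), exclusive)
  for (id in exclusive) {
    orf_spec[[id]] <- list(lengths_aa = integer(0), kozak = character(0))
  }
  for (i in seq_along(orf_ids)) {
    if (i == 1) {
      orf_spec[[orf_ids[i]]] <- list(lengths_aa = as.integer(flagship_orf_lengths),
                                     kozak = flagship_orf_kozak)
    } else {
      k <- sample(1:3, 1)
      orf_spec[[orf_ids[i]]] <- list(
        lengths_aa = sort(sample(51:80, k)),
        kozak = sample(c("strong", "adequate", "weak"), k, replace = TRUE)
      )
    }
  }
  structure(
    list(transcript_ids = ids, exclusive_ids = exclusive,
         confirmed_ids = confirmed, orf_spec = orf_spec,
         exported_ids = exported, translated_ids = translated,
         promoter_open_ids = promoter_open, seed = seed),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  n_orf <- sum(vapply(x$orf_spec, function(s) length(s$lengths_aa) > 0, logical(1)))
  cat(sprintf(
    "synthetic_truth: %d transcripts; funnel %d exclusive / %d confirmed / %d with ORF / %d exported / %d translated; %d open promoters\n",
    length(x$transcript_ids), length(x$exclusive_ids), length(x$confirmed_ids),
    n_orf, length(x$exported_ids), length(x$translated_ids),
    length(x$promoter_open_ids)))
  invisible(x)
}

# Tissues of a typical normal-tissue RNA-seq panel plus liver.
default_tissue_panel <- function() {
  c("liver", "adipose", "adrenal", "brain", "breast", "colon", "foreskin",
    "heart", "kidney", "lung", "ovary", "placenta", "prostate",
    "skeletal_muscle", "testis", "thyroid", "leukocyte")
}

#' Generate a synthetic expression cohort with planted exclusive transcripts
#'
#' Emulates the statistical structure of the tumor-vs-normal-panel FPKM
#' design: planted exclusive transcripts are expressed in the tumor sample
#' (log-normal FPKM, median ~30, matching the 13.7-104.9 range typical of
#' retained candidates) and exactly zero across all normal tissues;
#' background transcripts are expressed in at least one normal tissue.
#' Leakage noise flips a normal-tissue cell of an exclusive transcript to a
#' small positive value with the given probability. Nuclear and cytoplasmic
#' compartment samples split the tumor signal according to each
#' transcript's planted export status. A replicate matrix re-draws tumor
#' values, zeroing the exclusive transcripts not in the confirmed set.
#'
#' @param truth A [synthetic_truth()].
#' @param tissues Normal-tissue labels (one sample per tissue).
#' @param tumor_sample Sample id of the tumor column.
#' @param leakage Probability that a normal-tissue cell of an exclusive
#'   transcript leaks a small positive FPKM.
#' @param sdlog Log-scale dispersion of expressed FPKMs.
#' @param meanlog Log-scale mean of expressed FPKMs.
#' @param exported_cyt_range,retained_cyt_range Ranges of the cytoplasmic
#'   fraction drawn for planted exported and non-exported transcripts.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return List with `expression` and `replicate` (both
#'   [expression_matrix()]) and the `truth` passed in.
#' @export
generate_cohort <- function(truth, tissues = default_tissue_panel(),
                            tumor_sample = "tumor_line",
                            leakage = 0, sdlog = 0.6, meanlog = log(30),
                            exported_cyt_range = c(0.7, 0.95),
                            retained_cyt_range = c(0.0, 0.1),
                            seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  if (length(tissues) == 0) stop("tissue panel must be non-empty")
  if (leakage < 0 || leakage > 1) stop("leakage must be in [0, 1]")
  ids <- truth$transcript_ids
  n <- length(ids)
  samples <- c(tumor_sample, tissues, "nuclear", "cytoplasmic")
  vals <- matrix(0, nrow = n, ncol = length(samples),
                 dimnames = list(ids, samples))
  is_excl <- ids %in% truth$exclusive_ids

  draw_fpkm <- function(k) pmax(stats::rlnorm(k, meanlog, sdlog), 1.01)

  # tumor column
  vals[is_excl, tumor_sample] <- draw_fpkm(sum(is_excl))
  bg <- which(!is_excl)
  bg_on_tumor <- bg[stats::runif(length(bg)) < 0.5]
  vals[bg_on_tumor, tumor_sample] <- draw_fpkm(length(bg_on_tumor))

  # normal panel: background expressed in >= 1 tissue, exclusives zero
  for (i in bg) {
    k <- 1 + stats::rbinom(1, length(tissues) - 1, 0.25)
    cols <- sample(tissues, k)
    vals[i, cols] <- stats::rlnorm(k, log(10), sdlog)
  }
  if (leakage > 0) {
    excl_idx <- which(is_excl)
    flip <- matrix(stats::runif(length(excl_idx) * length(tissues)) < leakage,
                   nrow = length(excl_idx))
    leak_vals <- matrix(stats::runif(length(excl_idx) * length(tissues), 0.05, 0.9),
                        nrow = length(excl_idx))
    vals[excl_idx, tissues] <- ifelse(flip, leak_vals, 0)
  }

  # compartment split of the tumor signal
  tumor_on <- vals[, tumor_sample] > 0
  frac <- stats::runif(n, 0.2, 0.8)
  frac[ids %in% truth$exported_ids] <-
    stats::runif(sum(ids %in% truth$exported_ids),
                 exported_cyt_range[1], exported_cyt_range[2])
  retained <- is_excl & !(ids %in% truth$exported_ids)
  frac[retained] <- stats::runif(sum(retained),
                                 retained_cyt_range[1], retained_cyt_range[2])
  vals[tumor_on, "cytoplasmic"] <- vals[tumor_on, tumor_sample] * frac[tumor_on]
  vals[tumor_on, "nuclear"] <- vals[tumor_on, tumor_sample] * (1 - frac[tumor_on])

  meta <- data.frame(
    sample_id = samples,
    role = c("tumor", rep("normal_tissue", length(tissues)), "nuclear", "cytoplasmic"),
    tissue = c("liver_tumor", tissues, "liver_tumor", "liver_tumor"),
    stringsAsFactors = FALSE
  )

  # replicate: independent tumor re-measurement; non-confirmed planted
  # exclusives fail to reproduce
  rep_vals <- matrix(0, nrow = n, ncol = 1, dimnames = list(ids, tumor_sample))
  rep_on <- ids %in% truth$confirmed_ids
  rep_vals[rep_on, 1] <- draw_fpkm(sum(rep_on))
  rep_bg <- which(!is_excl & tumor_on)
  rep_vals[rep_bg, 1] <- draw_fpkm(length(rep_bg))
  rep_meta <- meta[meta$sample_id == tumor_sample, , drop = FALSE]

  list(
    expression = expression_matrix(vals, meta),
    replicate = expression_matrix(rep_vals, rep_meta),
    truth = truth
  )
}

# One planted ORF block: in-frame terminator, Kozak context, ATG..stop.
# Returns list(block = nucleotide string, atg_offset = 0-based offset of
# the A of ATG within the block).
build_orf_block <- function(length_aa, kozak) {
  codons_all <- c(t(outer(c("A", "C", "G", "T"),
                          c(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))),
                          paste0)))
  sense_codons <- setdiff(codons_all, STOP_CODONS)
  minus3 <- switch(kozak,
    strong = sample(c("A", "G"), 1),
    adequate = if (stats::runif(1) < 0.5) sample(c("A", "G"), 1) else sample(c("C", "T"), 1),
    weak = sample(c("C", "T"), 1),
    stop(sprintf("unknown kozak class '%s'", kozak))
  )
  plus4_is_g <- switch(kozak,
    strong = TRUE,
    adequate = !(minus3 %in% c("A", "G")),
    weak = FALSE
  )
  second_pool <- if (plus4_is_g) {
    grep("^G", sense_codons, value = TRUE)
  } else {
    grep("^[ACT]", sense_codons, value = TRUE)
  }
  ctx <- paste0(minus3, paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE), collapse = ""))
  body <- c("ATG", sample(second_pool, 1),
            sample(sense_codons, length_aa - 2, replace = TRUE),
            sample(STOP_CODONS, 1))
  # leading in-frame TAA terminates any upstream in-frame ATG before this ORF
  list(block = paste0("TAA", ctx, paste(body, collapse = "")),
       atg_offset = 6L)
}

random_background <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
}

# Build one transcript sequence containing exactly the requested ORFs
# (scanner-verified; rejection sampling with a bounded retry budget).
build_planted_sequence <- function(lengths_aa, kozak, background_length,
                                   min_len_aa = 50L, max_tries = 100L) {
  stopifnot(length(lengths_aa) == length(kozak))
  if (length(lengths_aa) && any(lengths_aa <= min_len_aa)) {
    stop("planted ORF lengths must exceed min_len_aa")
  }
  block_nt <- 6L + 3L * (lengths_aa + 1L)  # TAA + ctx + ORF + stop
  spare <- background_length - sum(block_nt)
  if (spare < 10L * (length(lengths_aa) + 1L)) {
    stop("requested ORFs do not fit in background_length")
  }
  for (try in seq_len(max_tries)) {
    gaps <- if (length(lengths_aa)) {
      g <- stats::runif(length(lengths_aa) + 1L)
      floor(g / sum(g) * spare)
    } else spare
    blocks <- lapply(seq_along(lengths_aa), function(i) build_orf_block(lengths_aa[i], kozak[i]))
    pieces <- character(0)
    expected <- data.frame(start_nt = integer(0), length_aa = integer(0),
                           kozak = character(0), stringsAsFactors = FALSE)
    pos <- 0L
    for (i in seq_along(blocks)) {
      bg <- random_background(gaps[i])
      pieces <- c(pieces, bg, blocks[[i]]$block)
      pos <- pos + gaps[i]
      expected <- rbind(expected, data.frame(
        start_nt = pos + blocks[[i]]$atg_offset,
        length_aa = lengths_aa[i], kozak = kozak[i],
        stringsAsFactors = FALSE
      ))
      pos <- pos + nchar(blocks[[i]]$block)
    }
    pieces <- c(pieces, random_background(background_length - pos))
    sequence <- paste(pieces, collapse = "")
    found <- find_orfs(sequence, min_len_aa)
    ok <- nrow(found) == nrow(expected) &&
      (nrow(found) == 0 ||
         (all(found$start_nt == expected$start_nt) &&
            all(found$length_aa == expected$length_aa) &&
            all(found$kozak == expected$kozak)))
    if (ok) return(sequence)
  }
  stop(sprintf("failed to plant ORFs within %d attempts; relax the spec or lengthen the background",
               max_tries))
}

#' Generate transcript sequences with planted small ORFs
#'
#' Builds one spliced sequence per entry of the truth's ORF spec, embedding
#' each requested ORF with its requested Kozak class and a background that
#' introduces no additional ORF exceeding `min_len_aa`. Every product is
#' verified by running [find_orfs()] on it and resampled on violation
#' (bounded retries, then a hard error). Background composition is AT-rich
#' so spurious long ORFs are rare. Transcript models are laid out along a
#' toy chromosome with two exons each.
#'
#' @param truth A [synthetic_truth()].
#' @param background_length Transcript length in nt.
#' @param min_len_aa ORF length floor the planting is verified against.
#' @param max_tries Rejection-sampling budget per transcript.
#' @param chrom Toy chromosome name.
#' @param spacing Genomic spacing between transcript starts (bp).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return List with `sequences` (named character) and `transcripts`
#'   (named list of [transcript_model()]).
#' @export
generate_transcript_sequences <- function(truth, background_length = 1500L,
                                          min_len_aa = 50L, max_tries = 100L,
                                          chrom = "chrS", spacing = 20000L,
                                          seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  ids <- names(truth$orf_spec)
  seqs <- character(0)
  models <- list()
  for (i in seq_along(ids)) {
    spec <- truth$orf_spec[[ids[i]]]
    seqs[[ids[i]]] <- build_planted_sequence(spec$lengths_aa, spec$kozak,
                                             background_length, min_len_aa, max_tries)
    offset <- (i - 1L) * spacing + 5000L
    exon1 <- ceiling(background_length * 0.4)
    exons <- data.frame(
      start = c(offset, offset + exon1 + 800L),
      end = c(offset + exon1, offset + exon1 + 800L + (background_length - exon1))
    )
    strand <- if (i %% 2 == 0) "-" else "+"
    models[[ids[i]]] <- transcript_model(ids[i], chrom, strand, exons,
                                         sequence = seqs[[ids[i]]])
  }
  list(sequences = seqs, transcripts = models)
}

#' Generate chromatin tracks and a polysome qPCR CT table
#'
#' Plants the evidence the annotation and translation stages look for:
#' transcripts with an open promoter receive a tumor-only DNase peak inside
#' the default promoter window plus a CAGE cluster at the TSS (and cCRE /
#' H3K4me3 marks); normal DNase peaks fall elsewhere. The CT table is
#' constructed by inverting the fraction-distribution formula from a target
#' mass vector (translated transcripts place `polysomal_target` of their
#' mass in the polysomal fractions, others `background_target`) around a
#' global offset cycle, then adding Gaussian CT noise. An Actin positive
#' control row is included.
#'
#' @param truth A [synthetic_truth()].
#' @param transcripts Named list of [transcript_model()] objects.
#' @param n_fractions Number of gradient fractions (`>= 4`).
#' @param ct_noise_sd Gaussian CT noise, in cycles.
#' @param ct_offset Offset cycle the mass vector is inverted around.
#' @param efficiency Amplification efficiency used for the inversion.
#' @param upstream,downstream,cage_slack Promoter window geometry the
#'   planted peaks are placed within.
#' @param polysomal_target Polysomal mass planted for translated
#'   transcripts (`>= 0.7` keeps the planting recoverable at the default
#'   0.5 translation cutoff).
#' @param background_target Polysomal mass planted for non-translated
#'   transcripts.
#' @param control_id Row name of the positive-control mRNA.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return List with `tumor_dnase`, `normal_dnase`, `cage`,
#'   `feature_tracks` (named list of interval data frames), `ct` (matrix)
#'   and `polysome_set`.
#' @export
generate_tracks_and_ct <- function(truth, transcripts, n_fractions = 10L,
                                   ct_noise_sd = 0, ct_offset = 20,
                                   efficiency = 2.0,
                                   upstream = 1000L, downstream = 500L,
                                   cage_slack = 100L,
                                   polysomal_target = 0.8,
                                   background_target = 0.1,
                                   control_id = "ACTB_control",
                                   seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_fractions < 4) stop("n_fractions must be >= 4")
  if (!is.null(seed)) set.seed(seed)

  peak_in_window <- function(window, width = 200L) {
    lo <- window$start
    hi <- max(window$end - width, lo + 1L)
    s <- lo + sample.int(max(hi - lo, 1L), 1) - 1L
    genomic_intervals(window$chrom, s, s + width, label = window$label)
  }

  tumor_rows <- list(); normal_rows <- list(); cage_rows <- list()
  ccre_rows <- list(); h3k4_rows <- list()
  ccre_ids <- truth$promoter_open_ids[seq_len(min(5L, length(truth$promoter_open_ids)))]
  for (id in truth$confirmed_ids) {
    m <- transcripts[[id]]
    if (is.null(m)) next
    window <- promoter_window(m, upstream, downstream)
    if (id %in% truth$promoter_open_ids) {
      tumor_rows[[id]] <- peak_in_window(window)
      cage_rows[[id]] <- genomic_intervals(
        m$chrom, max(m$tss - 20L, 0L), m$tss + 20L, label = id)
      h3k4_rows[[id]] <- peak_in_window(window, 400L)
      if (id %in% ccre_ids) ccre_rows[[id]] <- peak_in_window(window, 150L)
    }
    # normal accessibility sits far from every candidate promoter
    far <- window$end + 10000L
    normal_rows[[id]] <- genomic_intervals(m$chrom, far, far + 200L)
  }
  bind_track <- function(rows) {
    if (length(rows) == 0) {
      genomic_intervals(character(0), integer(0), integer(0), character(0), character(0))
    } else {
      out <- do.call(rbind, rows); rownames(out) <- NULL; out
    }
  }

  polysome_set <- default_polysome_set(n_fractions)
  assayed <- truth$exported_ids
  ct <- matrix(NA_real_, nrow = length(assayed) + 1L, ncol = n_fractions,
               dimnames = list(c(assayed, control_id),
                               sprintf("F%d", seq_len(n_fractions))))
  target_mass <- function(poly_mass) {
    p <- numeric(n_fractions)
    p[polysome_set] <- poly_mass / length(polysome_set)
    p[-polysome_set] <- (1 - poly_mass) / (n_fractions - length(polysome_set))
    p
  }
  for (id in assayed) {
    p <- target_mass(if (id %in% truth$translated_ids) polysomal_target else background_target)
    ct[id, ] <- ct_offset - log(p) / log(efficiency) +
      stats::rnorm(n_fractions, 0, ct_noise_sd)
  }
  ct[control_id, ] <- ct_offset - log(target_mass(0.9)) / log(efficiency) +
    stats::rnorm(n_fractions, 0, ct_noise_sd)

  list(
    tumor_dnase = bind_track(tumor_rows),
    normal_dnase = bind_track(normal_rows),
    cage = bind_track(cage_rows),
    feature_tracks = list(ccre = bind_track(ccre_rows), h3k4me3 = bind_track(h3k4_rows)),
    ct = ct,
    polysome_set = polysome_set
  )
}

#' Generate a complete synthetic input bundle
#'
#' One call producing everything the screen consumes — expression and
#' replicate matrices, transcript sequences and models, chromatin tracks,
#' and the polysome CT table — with truth labels attached. The defaults
#' plant the 12 / 9 / 6 / 5 / 3 funnel with zero noise, so the pipeline
#' run end-to-end recovers the planted truth exactly.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_transcripts Cohort size.
#' @param leakage Normal-panel leakage probability (see
#'   [generate_cohort()]).
#' @param ct_noise_sd Gaussian CT noise in cycles (see
#'   [generate_tracks_and_ct()]).
#' @param ... Passed to [synthetic_truth()].
#' @return A bundle list: `expression`, `replicate`, `sequences`,
#'   `transcripts`, `tracks`, `ct`, `polysome_set`, `truth`.
#' @export
generate_bundle <- function(seed = 1L, n_transcripts = 500L,
                            leakage = 0, ct_noise_sd = 0, ...) {
  set.seed(seed)
  truth <- synthetic_truth(n_transcripts = n_transcripts, ...)
  cohort <- generate_cohort(truth, leakage = leakage)
  seqs <- generate_transcript_sequences(truth)
  tracks <- generate_tracks_and_ct(truth, seqs$transcripts, ct_noise_sd = ct_noise_sd)
  list(
    expression = cohort$expression,
    replicate = cohort$replicate,
    sequences = seqs$sequences,
    transcripts = seqs$transcripts,
    tracks = tracks[c("tumor_dnase", "normal_dnase", "cage", "feature_tracks")],
    ct = tracks$ct,
    polysome_set = tracks$polysome_set,
    truth = truth
  )
}
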