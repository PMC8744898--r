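FUNNEL_STAGES <- c("exclusive", "confirmed", "has_orf", "exported", "translated")

#' Configuration of a full screen run
#'
#' Collects every tunable of the pipeline in one object. All values are
#' config-exposed versions of the stage defaults: expression thresholds
#' (on at 1 FPKM, off at exactly 0), a 1000/500 bp proximal promoter
#' window, 100 bp CAGE slack, a strict >50 aa ORF floor, a 0.2 cytoplasmic
#' fraction export floor, the bottom 40% of gradient fractions as the
#' polysomal set, a 0.5 polysomal-mass translation cutoff and perfect
#' amplification efficiency 2.
#'
#' @param tau_on,tau_off FPKM thresholds (see [screen_thresholds()]).
#' @param upstream,downstream Promoter window in bp.
#' @param cage_slack CAGE-to-TSS tolerance in bp.
#' @param min_len_aa ORF length floor (exclusive).
#' @param export_threshold Minimum cytoplasmic fraction for an export call.
#' @param translation_cutoff Minimum polysomal mass for a translated call.
#' @param efficiency qPCR amplification efficiency per cycle.
#' @param stages Named logical vector enabling the optional stages
#'   `confirm`, `orf`, `export`, `translation`; a disabled stage is
#'   recorded as not evaluated and filters nothing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(tau_on = 1.0, tau_off = 0.0,
                            upstream = 1000L, downstream = 500L,
                            cage_slack = 100L, min_len_aa = 50L,
                            export_threshold = 0.2,
                            translation_cutoff = 0.5,
                            efficiency = 2.0,
                            stages = c(confirm = TRUE, orf = TRUE,
                                       export = TRUE, translation = TRUE)) {
  defaults <- c(confirm = TRUE, orf = TRUE, export = TRUE, translation = TRUE)
  defaults[names(stages)] <- stages
  structure(
    list(thresholds = screen_thresholds(tau_on, tau_off),
         upstream = upstream, downstream = downstream,
         cage_slack = cage_slack, min_len_aa = min_len_aa,
         export_threshold = export_threshold,
         translation_cutoff = translation_cutoff,
         efficiency = efficiency, stages = defaults),
    class = "pipeline_config"
  )
}

kozak_rank <- function(k) match(k, c("weak", "adequate", "strong"))

#' Run the full micropeptide candidate screen
#'
#' Applies the funnel in fixed order: tumor-exclusive expression, replicate
#' confirmation, qualifying-ORF filter, cytoplasmic export, polysome
#' translation evidence. Promoter chromatin annotation is computed for all
#' confirmed candidates but never used as a hard filter — candidates with
#' closed promoters stay in. Transcripts absent from the CT table are
#' treated as lacking translation evidence, and transcripts expressed in
#' neither compartment fail export as not expressed. The run is
#' deterministic given its inputs.
#'
#' @param bundle Input bundle: `expression` (with tumor, normal-tissue and
#'   optionally nuclear/cytoplasmic samples), optional `replicate`,
#'   `sequences`, `transcripts`, `tracks`
#'   (`tumor_dnase`/`normal_dnase`/`cage`/`feature_tracks`), `ct` and
#'   `polysome_set` — as produced by [generate_bundle()] or
#'   [read_bundle()].
#' @param config A [pipeline_config()].
#' @return An object of class `screen_result`: `records` (one row per
#'   exclusive transcript, accumulating all stage verdicts, a
#'   `stage_reached` label and the `final_candidate` flag), `funnel`
#'   (named count vector over executed stages) and `promoter` (the
#'   annotation table, evidence only).
#' @export
run_screen <- function(bundle, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  mat <- bundle$expression
  stopifnot(inherits(mat, "ExpressionMatrix"))
  tumor <- samples_with_role(mat, "tumor")
  if (length(tumor) != 1) stop("expression matrix must contain exactly one tumor sample")
  normals <- samples_with_role(mat, "normal_tissue")
  if (length(normals) == 0) stop("expression matrix contains no normal_tissue samples")

  calls <- find_exclusive_transcripts(mat, tumor, normals, config$thresholds)
  records <- data.frame(
    transcript_id = calls$transcript_id,
    tumor_fpkm = calls$tumor_fpkm,
    max_normal_fpkm = calls$max_normal_fpkm,
    stringsAsFactors = FALSE
  )
  n0 <- nrow(records)
  records$confirmed <- rep(NA, n0)
  records$n_qualifying_orfs <- rep(NA_integer_, n0)
  records$max_orf_aa <- rep(NA_integer_, n0)
  records$best_kozak <- rep(NA_character_, n0)
  records$cytoplasmic_fraction <- rep(NA_real_, n0)
  records$exported <- rep(NA, n0)
  records$polysome_score <- rep(NA_real_, n0)
  records$translated <- rep(NA, n0)
  funnel <- c(exclusive = nrow(records))
  alive <- records$transcript_id

  # replicate confirmation
  if (config$stages[["confirm"]] && !is.null(bundle$replicate)) {
    rep_tumor <- samples_with_role(bundle$replicate, "tumor")
    if (length(rep_tumor) != 1) stop("replicate matrix must contain exactly one tumor sample")
    kept <- confirm_in_replicate(calls, bundle$replicate, rep_tumor, config$thresholds)
    records$confirmed <- records$transcript_id %in% kept$transcript_id
    alive <- intersect(alive, kept$transcript_id)
    funnel["confirmed"] <- length(alive)
  }

  # promoter annotation: evidence for every surviving candidate, not a filter
  promoter <- NULL
  if (!is.null(bundle$tracks) && !is.null(bundle$transcripts)) {
    annotatable <- bundle$transcripts[intersect(alive, names(bundle$transcripts))]
    promoter <- annotate_promoters(
      annotatable,
      tumor_dnase = bundle$tracks$tumor_dnase,
      normal_dnase = bundle$tracks$normal_dnase,
      feature_tracks = bundle$tracks$feature_tracks,
      cage = bundle$tracks$cage,
      upstream = config$upstream, downstream = config$downstream,
      cage_slack = config$cage_slack
    )
  }

  # qualifying-ORF filter
  if (config$stages[["orf"]]) {
    seqs <- bundle$sequences[intersect(alive, names(bundle$sequences))]
    orfs <- scan_orfs(seqs, config$min_len_aa)
    for (id in alive) {
      mine <- orfs[orfs$transcript_id == id, , drop = FALSE]
      i <- match(id, records$transcript_id)
      records$n_qualifying_orfs[i] <- nrow(mine)
      if (nrow(mine)) {
        records$max_orf_aa[i] <- max(mine$length_aa)
        records$best_kozak[i] <- mine$kozak[which.max(kozak_rank(mine$kozak))]
      }
    }
    alive <- alive[records$n_qualifying_orfs[match(alive, records$transcript_id)] >= 1]
    funnel["has_orf"] <- length(alive)
  }

  # cytoplasmic export
  if (config$stages[["export"]]) {
    nuc <- samples_with_role(mat, "nuclear")
    cyt <- samples_with_role(mat, "cytoplasmic")
    if (length(nuc) != 1 || length(cyt) != 1) {
      stop("export stage needs exactly one nuclear and one cytoplasmic sample")
    }
    for (id in alive) {
      i <- match(id, records$transcript_id)
      v_cyt <- mat$values[id, cyt]; v_nuc <- mat$values[id, nuc]
      if (v_cyt == 0 && v_nuc == 0) {
        records$exported[i] <- FALSE  # not expressed in either compartment
      } else {
        records$cytoplasmic_fraction[i] <- cytoplasmic_fraction(v_cyt, v_nuc)
        records$exported[i] <- records$cytoplasmic_fraction[i] >= config$export_threshold
      }
    }
    alive <- alive[records$exported[match(alive, records$transcript_id)]]
    funnel["exported"] <- length(alive)
  }

  # polysome translation evidence
  if (config$stages[["translation"]]) {
    if (is.null(bundle$ct)) stop("translation stage enabled but no CT table in bundle")
    pset <- if (!is.null(bundle$polysome_set)) bundle$polysome_set
    else default_polysome_set(ncol(bundle$ct))
    for (id in alive) {
      i <- match(id, records$transcript_id)
      if (id %in% rownames(bundle$ct) && !all(is.na(bundle$ct[id, ]))) {
        prof <- fraction_profile(id, bundle$ct[id, ],
                                 efficiency = config$efficiency,
                                 polysome_set = pset)
        enr <- polysome_enrichment(prof, config$translation_cutoff)
        records$polysome_score[i] <- enr$score
        records$translated[i] <- enr$translated
      } else {
        records$translated[i] <- FALSE  # never detected on the gradient
      }
    }
    alive <- alive[records$translated[match(alive, records$transcript_id)]]
    funnel["translated"] <- length(alive)
  }

  executed <- FUNNEL_STAGES[FUNNEL_STAGES %in% names(funnel)]
  records$stage_reached <- vapply(records$transcript_id, function(id) {
    reached <- "exclusive"
    i <- match(id, records$transcript_id)
    for (st in executed[-1]) {
      passed <- switch(st,
        confirmed = isTRUE(records$confirmed[i]),
        has_orf = isTRUE(records$n_qualifying_orfs[i] >= 1),
        exported = isTRUE(records$exported[i]),
        translated = isTRUE(records$translated[i])
      )
      if (!passed) break
      reached <- st
    }
    reached
  }, character(1))
  records$final_candidate <- records$stage_reached == executed[length(executed)]
  if (!is.null(promoter) && nrow(promoter)) {
    keep <- c("transcript_id", "differential_open", "cage_supported")
    records <- merge(records, promoter[, keep, drop = FALSE],
                     by = "transcript_id", all.x = TRUE, sort = FALSE)
  } else {
    records$differential_open <- rep(NA, nrow(records))
    records$cage_supported <- rep(NA, nrow(records))
  }
  records <- records[order(-records$tumor_fpkm, records$transcript_id), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, funnel = funnel, promoter = promoter),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result funnel:\n")
  for (nm in names(x$funnel)) cat(sprintf("  %-10s %d\n", nm, x$funnel[[nm]]))
  cat(sprintf("final candidates: %d\n", sum(x$records$final_candidate)))
  invisible(x)
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Write a screen report
#'
#' Emits three artifacts under `dir`: `report.json` (machine-readable,
#' schema-versioned, round-trippable via [read_report()]), `records.tsv`
#' (one row of evidence per transcript) and `funnel.txt` (plain-text stage
#' counts).
#'
#' @param result A `screen_result` from [run_screen()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "screen_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(json = file.path(dir, "report.json"),
             tsv = file.path(dir, "records.tsv"),
             funnel = file.path(dir, "funnel.txt"))
  payload <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    funnel = as.list(result$funnel),
    records = result$records
  )
  jsonlite::write_json(payload, paths[["json"]], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  utils::write.table(result$records, paths[["tsv"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c("stage\tcount",
               sprintf("%s\t%d", names(result$funnel), result$funnel)),
             paths[["funnel"]])
  invisible(paths)
}

#' Read a screen report back from JSON
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return A `screen_result` with the same `records` and `funnel`.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema_version, REPORT_SCHEMA_VERSION)) {
    stop(sprintf("unsupported report schema '%s'", payload$schema_version))
  }
  records <- as.data.frame(payload$records, stringsAsFactors = FALSE)
  funnel <- unlist(payload$funnel)
  structure(list(records = records, funnel = funnel, promoter = NULL),
            class = "screen_result")
}
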