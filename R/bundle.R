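#' Write a screen input bundle to a directory
#'
#' Serializes everything [run_screen()] consumes into the pipeline's
#' external formats: FPKM matrices and sample metadata as TSV, transcript
#' sequences as FASTA, transcript models as a block-encoded TSV, interval
#' tracks as BED, the polysome CT table as CSV, and the truth labels (when
#' present) as JSON.
#'
#' @param bundle A bundle list (see [generate_bundle()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_table(bundle$expression, file.path(dir, "expression.tsv"))
  write_sample_meta(bundle$expression$sample_meta, file.path(dir, "sample_meta.tsv"))
  if (!is.null(bundle$replicate)) {
    write_expression_table(bundle$replicate, file.path(dir, "replicate.tsv"))
    write_sample_meta(bundle$replicate$sample_meta, file.path(dir, "replicate_meta.tsv"))
  }
  if (!is.null(bundle$sequences)) {
    write_fasta(bundle$sequences, file.path(dir, "transcripts.fa"))
  }
  if (!is.null(bundle$transcripts)) {
    write_transcript_models(bundle$transcripts, file.path(dir, "transcript_models.tsv"))
  }
  if (!is.null(bundle$tracks)) {
    write_bed(bundle$tracks$tumor_dnase, file.path(dir, "tumor_dnase.bed"))
    write_bed(bundle$tracks$normal_dnase, file.path(dir, "normal_dnase.bed"))
    write_bed(bundle$tracks$cage, file.path(dir, "cage.bed"))
    for (nm in names(bundle$tracks$feature_tracks)) {
      write_bed(bundle$tracks$feature_tracks[[nm]],
                file.path(dir, sprintf("feature_%s.bed", nm)))
    }
  }
  if (!is.null(bundle$ct)) {
    write_ct_table(bundle$ct, file.path(dir, "ct.csv"))
    jsonlite::write_json(list(polysome_set = bundle$polysome_set),
                         file.path(dir, "polysome_set.json"), digits = NA)
  }
  if (!is.null(bundle$truth)) {
    truth <- bundle$truth
    jsonlite::write_json(
      list(transcript_ids = truth$transcript_ids,
           exclusive_ids = truth$exclusive_ids,
           confirmed_ids = truth$confirmed_ids,
           exported_ids = truth$exported_ids,
           translated_ids = truth$translated_ids,
           promoter_open_ids = truth$promoter_open_ids,
           orf_spec = truth$orf_spec,
           seed = truth$seed),
      file.path(dir, "truth.json"), digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a screen input bundle from a directory
#'
#' Inverse of [write_bundle()]; files not present are left `NULL` in the
#' returned bundle, and the corresponding stages are simply not fed.
#'
#' @param dir Directory written by [write_bundle()] (or assembled by hand
#'   in the same layout).
#' @return A bundle list consumable by [run_screen()].
#' @export
read_bundle <- function(dir) {
  path <- function(f) file.path(dir, f)
  have <- function(f) file.exists(path(f))
  if (!have("expression.tsv") || !have("sample_meta.tsv")) {
    stop(sprintf("bundle at '%s' lacks expression.tsv / sample_meta.tsv", dir))
  }
  bundle <- list(
    expression = read_expression_table(path("expression.tsv"),
                                       read_sample_meta(path("sample_meta.tsv")))
  )
  if (have("replicate.tsv")) {
    bundle$replicate <- read_expression_table(path("replicate.tsv"),
                                              read_sample_meta(path("replicate_meta.tsv")))
  }
  if (have("transcripts.fa")) bundle$sequences <- read_fasta(path("transcripts.fa"))
  if (have("transcript_models.tsv")) {
    bundle$transcripts <- read_transcript_models(path("transcript_models.tsv"),
                                                 sequences = bundle$sequences)
  }
  if (have("tumor_dnase.bed")) {
    features <- list()
    for (f in list.files(dir, pattern = "^feature_.*\\.bed$")) {
      nm <- sub("^feature_(.*)\\.bed$", "\\1", f)
      features[[nm]] <- read_bed(path(f))
    }
    bundle$tracks <- list(
      tumor_dnase = read_bed(path("tumor_dnase.bed")),
      normal_dnase = read_bed(path("normal_dnase.bed")),
      cage = if (have("cage.bed")) read_bed(path("cage.bed")),
      feature_tracks = features
    )
  }
  if (have("ct.csv")) {
    bundle$ct <- read_ct_table(path("ct.csv"))
    if (have("polysome_set.json")) {
      bundle$polysome_set <- unlist(
        jsonlite::read_json(path("polysome_set.json"), simplifyVector = TRUE)$polysome_set)
    }
  }
  if (have("truth.json")) {
    tr <- jsonlite::read_json(path("truth.json"), simplifyVector = TRUE)
    orf_spec <- lapply(tr$orf_spec, function(s) {
      list(lengths_aa = as.integer(unlist(s$lengths_aa)),
           kozak = as.character(unlist(s$kozak)))
    })
    bundle$truth <- structure(
      list(transcript_ids = tr$transcript_ids,
           exclusive_ids = tr$exclusive_ids,
           confirmed_ids = tr$confirmed_ids,
           orf_spec = orf_spec,
           exported_ids = tr$exported_ids,
           translated_ids = tr$translated_ids,
           promoter_open_ids = tr$promoter_open_ids,
           seed = tr$seed),
      class = "synthetic_truth")
  }
  bundle
}
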