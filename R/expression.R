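#' Construct an FPKM expression matrix with sample metadata
#'
#' The central expression container: a transcripts-by-samples matrix of
#' non-negative FPKM values plus per-sample metadata assigning each sample a
#' role (`tumor`, `normal_tissue`, `nuclear`, `cytoplasmic`) and a tissue
#' label. FPKMs arrive pre-normalized; no normalization is performed here.
#'
#' @param values Numeric matrix, rows = transcripts (rownames required),
#'   columns = samples (colnames required). All values must be `>= 0`.
#' @param sample_meta `data.frame` with columns `sample_id`, `role`,
#'   `tissue`; every column of `values` must have a metadata row.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, sample_meta) {
  stopifnot(is.matrix(values), is.numeric(values) || length(values) == 0)
  if (nrow(values) > 0 && is.null(rownames(values))) stop("values needs transcript rownames")
  if (ncol(values) > 0 && is.null(colnames(values))) stop("values needs sample colnames")
  if (anyDuplicated(rownames(values))) {
    stop(sprintf("duplicate transcript id: %s", rownames(values)[duplicated(rownames(values))][1]))
  }
  if (anyDuplicated(colnames(values))) {
    stop(sprintf("duplicate sample id: %s", colnames(values)[duplicated(colnames(values))][1]))
  }
  if (any(is.na(values))) stop("FPKM values must not be missing")
  if (length(values) && any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative FPKM at transcript '%s', sample '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  stopifnot(is.data.frame(sample_meta), all(c("sample_id", "role", "tissue") %in% names(sample_meta)))
  roles <- c("tumor", "normal_tissue", "nuclear", "cytoplasmic")
  bad <- setdiff(sample_meta$role, roles)
  if (length(bad)) stop(sprintf("unknown sample role '%s'", bad[1]))
  orphan <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(orphan)) stop(sprintf("sample '%s' has no metadata", orphan[1]))
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values, sample_meta = sample_meta), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d transcripts x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$sample_meta$role)),
                              table(x$sample_meta$role)), collapse = ", "), "\n")
  invisible(x)
}

#' Transcript and sample accessors
#' @param x An `ExpressionMatrix`.
#' @return Character vector of ids.
#' @export
transcript_ids <- function(x) {
  rn <- rownames(x$values)
  if (is.null(rn)) character(0) else rn
}

#' @rdname transcript_ids
#' @export
sample_ids <- function(x) {
  cn <- colnames(x$values)
  if (is.null(cn)) character(0) else cn
}

#' Sample ids carrying a given role
#' @param x An `ExpressionMatrix`.
#' @param role One of `tumor`, `normal_tissue`, `nuclear`, `cytoplasmic`.
#' @export
samples_with_role <- function(x, role) {
  x$sample_meta$sample_id[x$sample_meta$role == role]
}

#' Read a tab-separated FPKM table
#'
#' Expects a header row, transcript ids in the first column and one numeric
#' column per sample. Cell-level validation reports the offending
#' transcript/sample on failure.
#'
#' @param path Path to the TSV file.
#' @param sample_meta Sample metadata `data.frame` (see
#'   [expression_matrix()]); must cover every sample column.
#' @return An `ExpressionMatrix` with column order preserved from the file.
#' @export
read_expression_table <- function(path, sample_meta) {
  if (!file.exists(path)) stop(sprintf("expression table not found: %s", path))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 1) stop("expression table needs a transcript id column")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate transcript id '%s' in %s", ids[duplicated(ids)][1], path))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (any(is.na(vals))) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric FPKM at transcript '%s', sample '%s'",
                 ids[idx[1]], colnames(vals)[idx[2]]))
  }
  expression_matrix(vals, sample_meta)
}

#' Write an `ExpressionMatrix` as TSV
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @param id_column Name used for the transcript id column header.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, id_column = "transcript_id") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  tab <- data.frame(id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[1] <- id_column
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read sample metadata tables
#' @param meta Sample metadata `data.frame`.
#' @param path TSV path.
#' @return `path` (write) or the metadata `data.frame` (read).
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
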