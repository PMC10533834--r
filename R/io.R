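#' Write a count dataset as a 10x-style triplet
#'
#' Writes `matrix.mtx` (Matrix Market, 1-based coordinates), `features.tsv`,
#' `barcodes.tsv` and a `metadata.tsv` with cell_id, genotype, replicate and
#' any ground-truth labels.
#'
#' @param dataset a [count_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts_10x <- function(dataset, dir) {
  stopifnot(inherits(dataset, "count_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(dataset$counts, sparse = TRUE),
                   "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(gene_id = dataset$gene_ids,
               mito = as.integer(dataset$mito_flags)),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(dataset$cell_ids, file.path(dir, "barcodes.tsv"))
  md <- data.frame(cell_id = dataset$cell_ids,
                   genotype = dataset$genotype,
                   replicate = dataset$replicate,
                   true_cluster = if (is.null(dataset$true_cluster))
                     NA else dataset$true_cluster,
                   true_phase = if (is.null(dataset$true_phase))
                     NA else dataset$true_phase)
  utils::write.table(md, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style triplet written by [write_counts_10x()]
#'
#' @param dir directory containing matrix.mtx, features.tsv, barcodes.tsv and
#'   metadata.tsv.
#' @return A [count_dataset()].
#' @export
read_counts_10x <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             header = FALSE,
                             colClasses = c("character", "integer"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  md <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                          header = TRUE, colClasses = "character")
  dimnames(m) <- list(feats[[1]], barcodes)
  storage.mode(m) <- "integer"
  tc <- suppressWarnings(as.integer(md$true_cluster))
  count_dataset(m, mito_flags = feats[[2]] == 1L,
                genotype = md$genotype, replicate = md$replicate,
                true_cluster = if (all(is.na(tc))) NULL else tc,
                true_phase = if (all(is.na(md$true_phase))) NULL else
                  md$true_phase)
}

#' Write / read an intensity stack as multi-page TIFF (z-major)
#'
#' Intensities are stored as 16-bit samples, so integer-valued stacks in
#' [0, 65535] round-trip exactly.
#'
#' @param stack 3-D array `(z, y, x)` of non-negative intensities.
#' @param path TIFF file path.
#' @return `path` invisibly, or the 3-D array on read.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3, all(stack >= 0), all(stack <= 65535))
  pages <- lapply(seq_len(dim(stack)[1]), function(z) stack[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  out <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) out[z, , ] <- round(pages[[z]] * 65535)
  out
}

#' Write / read an eye trace as CSV
#'
#' Columns: time, angle_left, angle_right, phase.
#'
#' @param trace an `eye_trace` (see [generate_eye_trace()]).
#' @param path CSV path.
#' @param expected_direction stimulus-consistent saccade sign used on read.
#' @return `path` invisibly, or an `eye_trace` on read.
#' @export
write_eye_trace <- function(trace, path) {
  utils::write.csv(data.frame(time = trace$time,
                              angle_left = trace$angle_left,
                              angle_right = trace$angle_right,
                              phase = trace$phase),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_eye_trace
#' @export
read_eye_trace <- function(path, expected_direction = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(time = df$time, angle_left = df$angle_left,
                 angle_right = df$angle_right, phase = df$phase,
                 expected_direction = expected_direction,
                 truth_saccades = NULL),
            class = "eye_trace")
}

#' Write a JSON run manifest
#'
#' Records the configuration snapshot, per-stage seeds and package version so
#' a run is reproducible byte-for-byte.
#'
#' @param manifest named list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest$package_version <-
    as.character(utils::packageVersion("visdevstats"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
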