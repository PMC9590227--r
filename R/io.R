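#' Write a probes-by-arrays matrix as TSV
#'
#' Header row of array IDs, first column `probe_id`.
#'
#' @param x numeric matrix with dimnames, or a `beta_matrix`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  if (inherits(x, "beta_matrix")) x <- x$values
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probes-by-arrays TSV matrix
#'
#' @param path file written by [write_matrix_tsv()] (or any TSV with a
#'   `probe_id` first column and array columns).
#' @return numeric matrix with probe rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read a sample sheet as CSV
#'
#' @param sheet data frame with the fixed column set (array_id, subject_id,
#'   replicate_pair_id, chip, position, plate, well, age, survival_time,
#'   event, ...).
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df
}

#' Write a manifest as TSV
#'
#' @param manifest an `array_manifest`.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_manifest_tsv <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest_tsv
#' @export
read_manifest_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  df$is_negative_control <- as.logical(df$is_negative_control)
  rownames(df) <- df$probe_id
  class(df) <- c("array_manifest", "data.frame")
  df
}
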