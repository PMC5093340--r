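# Internal coordinate convention: 0-based half-open [start, end).
# All file I/O (GTF, SEG: 1-based inclusive on disk) converts at the boundary.

#' @keywords internal
.gap_bp <- function(s1, e1, s2, e2) {
  # gap between [s1,e1) and [s2,e2); 0 on overlap or bookended ranges
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

#' @keywords internal
.models_granges <- function(models) {
  GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$start + 1L, end = models$end),
    gene_id = models$gene_id
  )
}

# Validation failures carry their own condition class so callers (and the
# CLI, which maps them to exit code 1) can tell them from runtime errors.
#' @keywords internal
.stopf <- function(fmt, ...) {
  stop(structure(
    class = c("lncscreen_validation", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)))
}

#' @keywords internal
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
.check_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x)))
    .stopf("%s must be a matrix with row and column names", what)
  invisible(x)
}

# Split a comma-joined biotype field back into a character vector
#' @keywords internal
.split_biotypes <- function(x) strsplit(x, ",", fixed = TRUE)

#' Write a data frame as TSV
#'
#' Plain tab-separated output with a header line, no quoting, no row names.
#' Used for all tabular result files so outputs diff cleanly.
#'
#' @param x data frame
#' @param path output path
#' @param header_lines optional character vector of `# `-prefixed comment
#'   lines written above the header (e.g. the run-config hash)
#' @return `path`, invisibly
#' @export
write_tsv <- function(x, path, header_lines = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by this package
#'
#' @param path file path
#' @param ... passed to [utils::read.delim()]
#' @return data frame
#' @export
read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read a genes-by-samples matrix from TSV
#'
#' First column holds gene identifiers; remaining columns are samples.
#'
#' @param path file path
#' @return numeric matrix with gene rownames and sample colnames
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @keywords internal
.write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write_tsv(df, path)
}
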