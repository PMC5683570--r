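#' Construct a count matrix container
#'
#' Bundles an integer feature-by-sample count matrix with its assay class.
#' Counts must be non-negative integers; feature and sample identifiers must
#' be unique, non-empty strings. Matching of identifiers throughout the
#' package is exact and case-sensitive.
#'
#' @param counts Numeric matrix of non-negative integral counts with rownames
#'   (feature IDs) and colnames (sample IDs).
#' @param feature_class `"mirna"` or `"mrna"`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer-valued matrix) and `feature_class`.
#' @examples
#' m <- matrix(c(1, 2, 0, 5, 10, 0), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' cm <- count_matrix(m, "mrna")
#' @export
count_matrix <- function(counts, feature_class = c("mirna", "mrna")) {
  feature_class <- match.arg(feature_class)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  obj <- structure(list(counts = counts, feature_class = feature_class),
                   class = "count_matrix")
  validate_count_matrix(obj)
  obj
}

validate_count_matrix <- function(x) {
  counts <- x$counts
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry feature and sample identifiers")
  bad <- which(counts < 0 | counts != round(counts) | !is.finite(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  if (anyDuplicated(rownames(counts)))
    stop(sprintf("duplicate feature identifier: '%s'",
                 rownames(counts)[duplicated(rownames(counts))][1]))
  if (anyDuplicated(colnames(counts)))
    stop(sprintf("duplicate sample identifier: '%s'",
                 colnames(counts)[duplicated(colnames(counts))][1]))
  invisible(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %s: %d features x %d samples\n",
              x$feature_class, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from TSV or Matrix Market files
#'
#' The TSV layout has a header row whose first cell is `feature_id` and whose
#' remaining cells are sample IDs; each following row is one feature. A
#' sparse alternative is a Matrix Market coordinate file (1-based indices)
#' with sidecar files `features.txt` and `samples.txt` (one ID per line) in
#' the same directory; pass the `.mtx` path and set `format = "mtx"`.
#' Row and column order are preserved from the files.
#'
#' @param path Path to the `.tsv` (or `.mtx`) file.
#' @param feature_class `"mirna"` or `"mrna"`.
#' @param format `"tsv"` (default) or `"mtx"`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, feature_class = c("mirna", "mrna"),
                              format = c("tsv", "mtx")) {
  feature_class <- match.arg(feature_class)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    feats <- readLines(file.path(dir, "features.txt"))
    samps <- readLines(file.path(dir, "samples.txt"))
    if (length(feats) != nrow(m) || length(samps) != ncol(m))
      stop("sidecar ID files do not match matrix dimensions")
    dimnames(m) <- list(feats, samps)
    return(count_matrix(m, feature_class))
  }
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count TSV needs a feature_id column plus samples")
  feats <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric count at feature '%s', column '%s'",
                 feats[bad[1, 1]], colnames(df)[-1][bad[1, 2]]))
  }
  rownames(m) <- feats
  count_matrix(m, feature_class)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_matrix()]: writing then reading reproduces the
#' object exactly.
#'
#' @param x A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or validate a sample sheet
#'
#' A sample sheet maps each sample ID to its `group` (`"tumor"` or
#' `"normal"`) and an optional `batch` label. IDs must be unique.
#'
#' @param path TSV with columns `sample_id`, `group` and optionally `batch`.
#' @return A `data.frame` with class `sample_sheet` prepended.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  as_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param df Data frame with the sample-sheet columns.
#' @export
as_sample_sheet <- function(df) {
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("sample sheet needs 'sample_id' and 'group' columns")
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         df$sample_id[duplicated(df$sample_id)][1])
  if (!all(df$group %in% c("tumor", "normal")))
    stop("group must be 'tumor' or 'normal'")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet to TSV
#'
#' @param x A sample sheet.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

check_sheet_matches <- function(matrix, sheet) {
  missing <- setdiff(sheet$sample_id, colnames(matrix$counts))
  if (length(missing) > 0)
    stop("sample sheet references samples absent from the count matrix: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
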