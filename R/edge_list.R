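#' Construct a typed regulatory edge list
#'
#' Two edge types are supported: `mirna_target` (a miRNA repressing a gene,
#' e.g. an experimentally validated interaction) and `tf_gene` (a
#' transcription factor regulating a gene). Self-edges are forbidden for
#' `mirna_target`, and no (source, target, edge_type) triple may repeat.
#'
#' @param df Data frame with columns `source`, `target`, `edge_type` and
#'   optionally `evidence`.
#' @return A `data.frame` with class `edge_list` prepended.
#' @export
edge_list <- function(df) {
  need <- c("source", "target", "edge_type")
  if (!all(need %in% names(df)))
    stop("edge list needs columns source, target, edge_type")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in need) df[[col]] <- as.character(df[[col]])
  bad <- setdiff(unique(df$edge_type), c("mirna_target", "tf_gene"))
  if (length(bad) > 0)
    stop("unknown edge_type: ", paste(bad, collapse = ", "))
  self <- df$edge_type == "mirna_target" & df$source == df$target
  if (any(self))
    stop("self-edge not allowed for mirna_target: ", df$source[self][1])
  key <- paste(df$source, df$target, df$edge_type, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate edge (%s, %s, %s)", d$source, d$target,
                 d$edge_type))
  }
  rownames(df) <- NULL
  class(df) <- c("edge_list", "data.frame")
  df
}

#' Read a regulatory edge list from TSV
#'
#' @param path TSV with columns `source`, `target`, `edge_type` and
#'   optionally `evidence`.
#' @return An [edge_list()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  edge_list(read.delim(path, header = TRUE, stringsAsFactors = FALSE))
}

#' Write a regulatory edge list to TSV
#'
#' @param x An [edge_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  stopifnot(inherits(x, "edge_list"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
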