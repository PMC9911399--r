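#' Read and write package tables as TSV
#'
#' Plain tab-separated interchange for the main tabular objects:
#' landscapes (`variant`, `kd_nM`, `mode`), count tables (`variant` plus
#' one column per library, control first) and affinity tables.
#'
#' @param x object to write.
#' @param path file path.
#' @return Readers return the corresponding object; writers return
#'   `path` invisibly.
#' @name hitseq_io
NULL

#' @rdname hitseq_io
#' @export
write_landscape <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname hitseq_io
#' @export
read_landscape <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant", "kd_nM") %in% names(x)))
  class(x) <- c("affinity_landscape", "data.frame")
  attr(x, "params") <- list(mode = "file", cognate_motifs = character(0))
  x
}

#' @rdname hitseq_io
#' @param use which count matrix to write: `"raw"` or `"umi"`.
#' @export
write_count_table <- function(x, path, use = c("raw", "umi")) {
  use <- match.arg(use)
  m <- if (use == "raw") x$counts else x$umi_counts
  df <- data.frame(variant = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname hitseq_io
#' @param control_label control library; defaults to the first count
#'   column.
#' @export
read_count_table <- function(path, control_label = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$variant
  if (is.null(control_label)) control_label <- colnames(m)[1]
  structure(list(counts = m, umi_counts = NULL, totals = colSums(m),
                 control_label = control_label,
                 rejected = c(rejected = NA, unassigned = NA,
                              unknown_kmer = NA)),
            class = "count_table")
}

#' @rdname hitseq_io
#' @export
write_affinity_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname hitseq_io
#' @param reference reference variant recorded in the table attributes.
#' @export
read_affinity_table <- function(path, reference = "UGCAUGU") {
  as_affinity_table(read.delim(path, stringsAsFactors = FALSE),
                    reference = reference)
}
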