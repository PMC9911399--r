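#' RNA and DNA k-mer utilities
#'
#' `all_kmers()` enumerates every k-mer over a nucleotide alphabet in
#' lexicographic order; `rna_to_dna()` / `dna_to_rna()` interconvert the
#' RNA alphabet used internally (A, C, G, U) and the DNA alphabet found in
#' sequencing reads (A, C, G, T).
#'
#' @param k k-mer length (positive integer).
#' @param alphabet character vector of single letters; defaults to the RNA
#'   alphabet `c("A","C","G","U")`.
#' @return `all_kmers()`: a character vector of length `length(alphabet)^k`
#'   with all distinct k-mers in lexicographic order.
#' @examples
#' length(all_kmers(7))   # 16384
#' length(all_kmers(5))   # 1024
#' @export
all_kmers <- function(k, alphabet = RNA_BASES) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L)
    stop("'k' must be a positive integer")
  grids <- rep(list(alphabet), k)
  m <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reversed input + reversed
  # columns gives lexicographic order
  do.call(paste0, rev(m))
}

#' @rdname all_kmers
#' @export
RNA_BASES <- c("A", "C", "G", "U")

#' @rdname all_kmers
#' @export
DNA_BASES <- c("A", "C", "G", "T")

#' @rdname all_kmers
#' @param x character vector of sequences.
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname all_kmers
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

## assert sequences use only the given alphabet; names the first bad symbol
check_alphabet <- function(x, alphabet = RNA_BASES, what = "sequence") {
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]), alphabet)
  if (length(bad))
    stop(sprintf("invalid symbol '%s' in %s (alphabet: %s)",
                 bad[[1]], what, paste(alphabet, collapse = "")))
  invisible(x)
}

## vectorized Hamming distance between equal-length strings and a template
hamming_to <- function(x, template) {
  n <- nchar(template)
  d <- integer(length(x))
  for (p in seq_len(n))
    d <- d + (substr(x, p, p) != substr(template, p, p))
  d
}
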