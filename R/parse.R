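#' Parse randomized-library reads into UMI, index and 7-mer
#'
#' Splits each read according to the construct layout (UMI at positions
#' 1-2, index at 3-5, constant region at 6-29, randomized 7-mer at 30-36)
#' and accepts a read iff the constant region matches the expected
#' sequence within `max_mismatch` substitutions (Hamming distance, no
#' gaps). The 7-mer is taken verbatim: substitution errors inside the
#' randomized window cannot be detected because its true sequence is
#' unknown.
#'
#' @param reads character vector of DNA reads.
#' @param layout a [construct_layout()].
#' @param max_mismatch maximum substitutions tolerated in the constant
#'   region (default 1).
#' @return data.frame with one row per read: `umi`, `index`, `kmer` (DNA),
#'   `constant_mismatches`, `accepted` (logical) and `reason` (`""`,
#'   `"too_short"`, `"constant_mismatch"` or `"bad_kmer"`).
#' @export
parse_construct <- function(reads, layout = construct_layout(),
                            max_mismatch = 1L) {
  n <- length(reads)
  u0 <- layout$umi_len
  i0 <- u0 + layout$index_len
  c0 <- i0 + nchar(layout$constant5)
  k0 <- c0 + layout$random_len
  too_short <- nchar(reads) < k0

  umi <- substr(reads, 1L, u0)
  index <- substr(reads, u0 + 1L, i0)
  const <- substr(reads, i0 + 1L, c0)
  kmer <- substr(reads, c0 + 1L, k0)

  mm <- rep.int(NA_integer_, n)
  exact <- const == layout$constant5 & !too_short
  mm[exact] <- 0L
  chk <- which(!exact & !too_short)
  if (length(chk))
    mm[chk] <- hamming_to(const[chk], layout$constant5)

  bad_kmer <- !too_short & grepl("[^ACGT]", kmer)
  accepted <- !too_short & mm <= max_mismatch & !bad_kmer
  reason <- character(n)
  reason[too_short] <- "too_short"
  reason[!too_short & mm > max_mismatch] <- "constant_mismatch"
  reason[bad_kmer & !(!too_short & mm > max_mismatch)] <- "bad_kmer"

  data.frame(umi = umi, index = index, kmer = kmer,
             constant_mismatches = mm, accepted = accepted,
             reason = reason, stringsAsFactors = FALSE)
}

#' Assign parsed reads to concentration libraries by index barcode
#'
#' @param parsed data.frame from [parse_construct()].
#' @param index_table named character vector mapping library labels to
#'   3-nt index barcodes (default [hitseq_indexes()]).
#' @return `parsed` with an added `library` column (factor with the
#'   libraries of `index_table` as levels; `NA` for unmatched indices);
#'   the number of unassigned accepted reads is in
#'   `attr(, "unassigned")`.
#' @export
demultiplex <- function(parsed, index_table = hitseq_indexes()) {
  if (anyDuplicated(index_table))
    stop("index barcodes must be unique")
  lib <- names(index_table)[match(parsed$index, index_table)]
  parsed$library <- factor(lib, levels = names(index_table))
  attr(parsed, "unassigned") <- sum(is.na(lib) & parsed$accepted)
  parsed
}

#' UMI-collapsed and raw per-variant counts per library
#'
#' Tallies accepted reads per (variant, library) cell in two ways: raw
#' read counts, and UMI-collapsed counts where identical (UMI, 7-mer)
#' pairs within a library collapse to one molecule. With a 2-nt UMI only
#' 16 distinct UMIs exist, so UMI-collapsed counts saturate at 16 per
#' variant and library; a warning is issued when a substantial fraction of
#' cells is near saturation, and downstream depletion analysis defaults to
#' raw counts for this reason (see [normalize_counts()]).
#'
#' @param parsed demultiplexed data.frame from [demultiplex()].
#' @param variants row universe; defaults to all 16,384 RNA 7-mers.
#'   Variants never observed get zero counts.
#' @param control_label library label of the no-protein control (default
#'   the first level).
#' @return A list of class `"count_table"`: `counts` (raw read counts,
#'   variants x libraries), `umi_counts` (UMI-collapsed), `totals`,
#'   `control_label`, and `rejected` (tally of rejected/unassigned reads).
#' @export
dedup_and_count <- function(parsed, variants = all_kmers(7L),
                            control_label = NULL) {
  libs <- levels(parsed$library)
  if (is.null(libs)) stop("reads must be demultiplexed first")
  if (is.null(control_label)) control_label <- libs[1]
  if (!control_label %in% libs) stop("unknown control library")
  variants_dna <- rna_to_dna(variants)

  ok <- parsed$accepted & !is.na(parsed$library)
  vi <- match(parsed$kmer[ok], variants_dna)
  drop <- is.na(vi)  # sequencing errors can create kmers outside the universe
  li <- as.integer(parsed$library[ok])[!drop]
  vi <- vi[!drop]
  umi <- parsed$umi[ok][!drop]

  nv <- length(variants); nl <- length(libs)
  raw <- matrix(0L, nv, nl, dimnames = list(variants, libs))
  umi_m <- matrix(0L, nv, nl, dimnames = list(variants, libs))
  for (j in seq_len(nl)) {
    sel <- li == j
    raw[, j] <- tabulate(vi[sel], nbins = nv)
    first <- !duplicated(paste0(umi[sel], "|", vi[sel]))
    umi_m[, j] <- tabulate(vi[sel][first], nbins = nv)
  }
  n_umis <- 4^nchar(parsed$umi[1])
  if (any(raw > 0) && mean(umi_m[raw > 0] >= n_umis * 0.75) > 0.1)
    warning(sprintf(
      "UMI-collapsed counts are close to the %d-UMI saturation ceiling in >10%% of occupied cells; use raw counts for quantification",
      n_umis))

  structure(list(counts = raw, umi_counts = umi_m,
                 totals = colSums(raw), control_label = control_label,
                 rejected = c(rejected = sum(!parsed$accepted),
                              unassigned = sum(parsed$accepted &
                                                 is.na(parsed$library)),
                              unknown_kmer = sum(drop))),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("HiTS-Eq count table: %d variants x %d libraries (control: %s)\n",
              nrow(x$counts), ncol(x$counts), x$control_label))
  cat("  library totals:", paste(x$totals, collapse = ", "), "\n")
  cat("  rejected:", paste(names(x$rejected), x$rejected, sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Control-normalized read frequencies
#'
#' Converts counts into depletion/enrichment values relative to the
#' no-protein control: `normalized(v, E) = [count(v,E)/total(E)] /
#' [count(v,0)/total(0)]` with a pseudocount added to every cell before
#' forming ratios. Values < 1 indicate depletion of the variant from the
#' unbound pool (binding), values > 1 enrichment.
#'
#' @param table a [dedup_and_count()] count table.
#' @param pseudocount added to all cells (default 0.5, the standard
#'   half-integer correction); must be > 0.
#' @param use `"raw"` (default) or `"umi"`: which count matrix to
#'   normalize. Raw counts are the default because the 2-nt UMI space (16
#'   UMIs) saturates at realistic depths.
#' @return Numeric matrix (variants x libraries) of normalized reads; the
#'   control column is identically 1.
#' @export
normalize_counts <- function(table, pseudocount = 0.5,
                             use = c("raw", "umi")) {
  use <- match.arg(use)
  if (pseudocount <= 0) stop("'pseudocount' must be > 0")
  m <- if (use == "raw") table$counts else table$umi_counts
  if (is.null(m))
    stop("this count table carries no UMI-collapsed counts")
  m <- m + pseudocount
  freq <- sweep(m, 2L, colSums(m), "/")
  out <- freq / freq[, table$control_label]
  attr(out, "control_label") <- table$control_label
  out
}
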