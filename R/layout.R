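#' Read layout of the randomized-library sequencing construct
#'
#' Describes how a 50-nt single-end read of the randomized RNA pool is laid
#' out: a 2-nt unique molecular identifier (UMI), a 3-nt library index, a
#' 24-nt constant region (the DNA transcript of the 5' flank of the RNA
#' substrate), the randomized 7-mer, and the beginning of the 3' constant
#' flank. Read positions 6-29 therefore carry the constant region used for
#' alignment, and positions 30-36 the 7-mer.
#'
#' @param umi_len UMI length, nt (default 2).
#' @param index_len index length, nt (default 3).
#' @param constant5 DNA sequence of the 5' constant region (default the
#'   24-nt flank `GGGAGACCGGAATTCAGATTGTCC`).
#' @param random_len length of the randomized segment, nt (default 7).
#' @param constant3 DNA sequence of the 3' constant flank.
#' @param read_len total read length, nt (default 50).
#' @return A list of class `"construct_layout"`.
#' @examples
#' lay <- construct_layout()
#' nchar(lay$constant5)  # 24
#' @export
construct_layout <- function(umi_len = 2L, index_len = 3L,
                             constant5 = "GGGAGACCGGAATTCAGATTGTCC",
                             random_len = 7L,
                             constant3 = "TTAAATCCCGTCGTAGCCACCA",
                             read_len = 50L) {
  check_alphabet(c(constant5, constant3), DNA_BASES, "constant region")
  stopifnot(umi_len >= 0, index_len >= 0, random_len >= 1,
            read_len >= umi_len + index_len + nchar(constant5) + random_len)
  structure(list(umi_len = as.integer(umi_len),
                 index_len = as.integer(index_len),
                 constant5 = constant5,
                 random_len = as.integer(random_len),
                 constant3 = constant3,
                 read_len = as.integer(read_len)),
            class = "construct_layout")
}

#' Default library index barcodes
#'
#' The eight 3-nt index barcodes used to multiplex libraries from different
#' protein concentrations, in library order.
#'
#' @param n number of indices to return (at most 8).
#' @return Named character vector; names are library labels `lib1..libn`.
#' @export
hitseq_indexes <- function(n = 8L) {
  idx <- c("ATC", "GAT", "CGA", "TCC", "CAC", "TGT", "ACT", "GTA")
  if (n > length(idx))
    stop("at most ", length(idx), " index barcodes are defined")
  structure(idx[seq_len(n)], names = paste0("lib", seq_len(n)))
}

#' Default protein concentration series
#'
#' A no-protein control followed by seven points log-spaced from 20 nM to
#' 19,740 nM (the top concentration of the wild-type titration).
#'
#' @return Numeric vector of length 8, in nM, first element 0.
#' @export
default_concs <- function() {
  c(0, signif(20 * (19740 / 20)^((0:6) / 6), 4))
}

#' Simulation settings for a HiTS-Eq experiment
#'
#' @param protein_concs protein concentrations, nM; must be sorted
#'   ascending with the no-protein control (0) first.
#' @param total_rna total RNA pool concentration, nM (spread evenly over
#'   the 16,384 variants; default 1 nM as in the assay).
#' @param depth number of source molecules sampled per concentration.
#' @param pcr_duplication mean PCR duplicates per molecule (geometric
#'   duplication; 1 = no duplication).
#' @param error_rate per-base substitution probability in reads.
#' @param seed integer seed; simulation output is deterministic given it.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(protein_concs = default_concs(),
                              total_rna = 1, depth = 1e6,
                              pcr_duplication = 1, error_rate = 0.001,
                              seed = NULL) {
  if (any(protein_concs < 0))
    stop("protein concentrations must be nonnegative")
  if (is.unsorted(protein_concs))
    stop("'protein_concs' must be sorted ascending")
  if (protein_concs[1] != 0)
    stop("the first concentration must be the no-protein control (0)")
  if (depth < 0) stop("'depth' must be nonnegative")
  if (error_rate < 0 || error_rate >= 1)
    stop("'error_rate' must be in [0, 1)")
  if (pcr_duplication < 1)
    stop("'pcr_duplication' is a mean number of copies and must be >= 1")
  structure(list(protein_concs = protein_concs, total_rna = total_rna,
                 depth = as.integer(depth),
                 pcr_duplication = pcr_duplication,
                 error_rate = error_rate, seed = seed),
            class = "simulation_config")
}

## canonical column label for a protein concentration
conc_label <- function(conc) as.character(signif(conc, 6))
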