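#' Simulate a complete HiTS-Eq experiment to a count table
#'
#' Runs the full simulated experiment — equilibrium partitioning of the
#' pool, read sampling with UMIs, PCR duplication and sequencing errors,
#' construct parsing, demultiplexing and counting — one library at a time
#' (to bound memory), and returns the assembled count table. Per-library
#' randomness is derived from `config$seed` (library j uses
#' `seed + j`), so the result is deterministic given the seed.
#'
#' @param landscape a [make_landscape()] ground-truth landscape.
#' @param config a [simulation_config()].
#' @param layout a [construct_layout()].
#' @return A `"count_table"`; the true sampled molecule counts are in
#'   `attr(, "molecules")` and the protein concentrations in
#'   `attr(, "concs")`.
#' @seealso [estimate_affinities()] for the downstream estimate.
#' @export
simulate_hitseq <- function(landscape, config = simulation_config(),
                            layout = construct_layout()) {
  comp <- simulate_equilibrium(landscape, config)
  n_lib <- ncol(comp)
  indexes <- hitseq_indexes(n_lib)
  variants <- landscape$variant
  nv <- length(variants)

  raw <- matrix(0L, nv, n_lib, dimnames = list(variants, names(indexes)))
  umi_m <- raw
  molecules <- raw
  rejected <- c(rejected = 0L, unassigned = 0L, unknown_kmer = 0L)
  for (j in seq_len(n_lib)) {
    cfg_j <- config
    if (!is.null(config$seed)) cfg_j$seed <- config$seed + j
    rs <- sample_reads(comp[, j, drop = FALSE], layout, cfg_j,
                       indexes = indexes[j])
    molecules[, j] <- rs$molecules[, 1]
    parsed <- demultiplex(parse_construct(rs$reads[[1]], layout), indexes)
    ct <- suppressWarnings(dedup_and_count(parsed, variants = variants))
    raw[, j] <- ct$counts[, j]
    umi_m[, j] <- ct$umi_counts[, j]
    rejected <- rejected + ct$rejected
  }
  out <- structure(list(counts = raw, umi_counts = umi_m,
                        totals = colSums(raw),
                        control_label = names(indexes)[1],
                        rejected = rejected),
                   class = "count_table")
  attr(out, "molecules") <- molecules
  attr(out, "concs") <- config$protein_concs
  out
}

#' Estimate relative affinities from a count table
#'
#' Convenience wrapper: control-normalizes the counts
#' ([normalize_counts()]) and runs the competitive-binding estimator
#' ([relative_affinity()]).
#'
#' @param counts a `"count_table"`.
#' @param concs protein concentrations per library; defaults to
#'   `attr(counts, "concs")`.
#' @param ... passed to [relative_affinity()] (`reference`,
#'   `ref_k_half`, `estimator`).
#' @param pseudocount,use passed to [normalize_counts()].
#' @return An `"affinity_table"`.
#' @export
estimate_affinities <- function(counts, concs = attr(counts, "concs"),
                                pseudocount = 0.5, use = "raw", ...) {
  if (is.null(concs))
    stop("protein concentrations must be supplied")
  nrm <- normalize_counts(counts, pseudocount = pseudocount, use = use)
  relative_affinity(nrm, concs, ...)
}
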