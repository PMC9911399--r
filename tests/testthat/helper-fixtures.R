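# shared fixtures: exact (noise-free) intermediates for oracle tests

# control-normalized frequencies computed from exact free-fraction
# expectations, no sampling, no pseudocount
exact_normalized <- function(landscape, concs) {
  comp <- simulate_equilibrium(
    landscape, simulation_config(protein_concs = concs, depth = 1))
  freq <- sweep(comp, 2L, colSums(comp), "/")
  freq / freq[, 1]
}

# minimal two-species "landscape" data.frame
two_species <- function(kd1 = 1.6, kd2 = 16, names = c("UGCAUGU", "UGAAUGU")) {
  data.frame(variant = names, kd_nM = c(kd1, kd2),
             stringsAsFactors = FALSE)
}

# hand-built read from layout components
build_read <- function(umi = "AA", index = "ATC", kmer = "ACGTACG",
                       layout = construct_layout()) {
  tail_len <- layout$read_len - (nchar(umi) + nchar(index) +
                                   nchar(layout$constant5) + nchar(kmer))
  paste0(umi, index, layout$constant5, kmer,
         substr(layout$constant3, 1, tail_len))
}

# random additive 5-mer affinity table: ln ka = X beta + intercept
additive_5mer_table <- function(beta_sd = 0.3, intercept = -2,
                                baseline = "GCAUG", seed = 1,
                                couplings = NULL, noise_sd = 0) {
  set.seed(seed)
  k5 <- all_kmers(5L)
  X <- encode_variants(k5, baseline, pairwise = !is.null(couplings))
  pos <- attr(X, "positional")
  beta <- setNames(rnorm(ncol(X), 0, 0), colnames(X))
  beta[pos$col] <- rnorm(nrow(pos), 0, beta_sd)
  if (!is.null(couplings))
    beta[couplings$col] <- couplings$value
  y <- drop(X %*% beta) + intercept + rnorm(length(k5), 0, noise_sd)
  list(table = data.frame(kmer5 = k5, ka_rel = exp(y),
                          stringsAsFactors = FALSE),
       beta = beta, intercept = intercept, X = X)
}
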