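#' Equilibrium composition of the unbound RNA pool
#'
#' Computes the expected unbound (free) concentration of every library
#' variant at each protein concentration under a competitive binding
#' scheme with protein in excess: the free fraction of a variant with
#' dissociation constant Kd at protein concentration E is
#' `Kd / (Kd + E)` (pseudo-first-order binding). Because the total RNA
#' (~1 nM) is spread over 16,384 species while protein is in the nM-uM
#' range, ligand depletion of the protein is negligible and this
#' free-fraction model is exact for the simulated assay. Compositions are
#' expectations: no sampling noise is added at this stage.
#'
#' @param landscape an [make_landscape()] object (or data.frame with
#'   columns `variant`, `kd_nM`).
#' @param config a [simulation_config()].
#' @return Numeric matrix (variants x concentrations) of unbound
#'   concentrations in nM; rownames are variants, colnames the
#'   concentration labels. At E = 0 the column equals the initial
#'   composition.
#' @examples
#' ls <- make_landscape(seed = 1)
#' comp <- simulate_equilibrium(ls, simulation_config(depth = 1000))
#' @export
simulate_equilibrium <- function(landscape, config = simulation_config()) {
  stopifnot(all(c("variant", "kd_nM") %in% names(landscape)))
  if (any(landscape$kd_nM <= 0))
    stop("all dissociation constants must be positive")
  concs <- config$protein_concs
  if (any(concs < 0)) stop("negative protein concentration")
  s0 <- config$total_rna / nrow(landscape)
  free <- outer(landscape$kd_nM, concs,
                function(kd, e) kd / (kd + e)) * s0
  dimnames(free) <- list(landscape$variant, conc_label(concs))
  free
}
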