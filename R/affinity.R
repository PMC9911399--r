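#' Relative binding affinities from depletion of the unbound pool
#'
#' Estimates a relative association constant for every library variant
#' from control-normalized unbound-pool frequencies at a series of protein
#' concentrations, using the competitive binding scheme: for two species
#' with dissociation constants K1 (reference) and K2 at protein
#' concentration E,
#' `S1/S2 = (S1,0/S2,0) * (1 + E/K2) / (1 + E/K1)`.
#' Solving for the variant's dissociation constant with concentrations
#' expressed in units of the reference K (so K1 = 1, e = E/`ref_k_half`)
#' gives `K2,rel = e / (R*(1 + e) - 1)` where
#' `R = [S1/S1,0] / [S2/S2,0]` is the ratio of control-normalized
#' frequencies (reference over variant). The reported `ka_rel` is the
#' reciprocal relative dissociation constant, so that the reference is 1
#' and higher affinity means larger `ka_rel`.
#'
#' Because the assay's protein concentrations far exceed the reference K,
#' `e >> 1` and the estimate is insensitive to the exact `ref_k_half`
#' (changing it twofold moves `ka_rel` by well under 1% in the default
#' design). Per-concentration estimates whose denominator
#' `R*(1+e) - 1` is not positive carry no information (the variant is
#' depleted at or below the detection limit) and are dropped; a variant
#' with no informative concentration is flagged `below_detection` with
#' `ka_rel = 0`.
#'
#' @param normalized matrix from [normalize_counts()] (variants x
#'   libraries, control column included).
#' @param concs numeric protein concentrations (nM), one per column of
#'   `normalized`; the control is the entry equal to 0.
#' @param reference reference variant (RNA alphabet); default the cognate
#'   7-mer `UGCAUGU`.
#' @param ref_k_half absolute K of the reference variant, nM (default
#'   1.6 nM, the cognate half-saturation constant); only used to express
#'   `E` in reference-K units.
#' @param estimator how to combine per-concentration estimates:
#'   `"median"` (default), `"mean"`, or `"global"` (least-squares fit of
#'   the depletion-ratio curve across all concentrations).
#' @return A data.frame of class `"affinity_table"` with columns
#'   `variant`, `ka_rel`, `n_informative`, `below_detection`. The
#'   per-concentration estimate matrix is in `attr(, "per_conc")`;
#'   `attr(, "reference")` and `attr(, "ref_k_half")` record the
#'   normalization.
#' @seealso [true_affinity()] for ground-truth tables,
#'   [aggregate_5mer()], [fit_pwm()].
#' @export
relative_affinity <- function(normalized, concs, reference = "UGCAUGU",
                              ref_k_half = 1.6,
                              estimator = c("median", "mean", "global")) {
  estimator <- match.arg(estimator)
  if (length(concs) != ncol(normalized))
    stop("'concs' must match the columns of 'normalized'")
  if (!reference %in% rownames(normalized))
    stop("reference variant '", reference, "' not present")
  if (ref_k_half <= 0) stop("'ref_k_half' must be positive")
  nz <- which(concs > 0)
  if (!length(nz)) stop("no nonzero protein concentrations")

  e <- concs[nz] / ref_k_half
  nref <- normalized[reference, nz]
  # R = normalized reference frequency over normalized variant frequency
  ratio <- matrix(nref, nrow(normalized), length(nz), byrow = TRUE) /
    normalized[, nz, drop = FALSE]
  denom <- sweep(ratio, 2L, 1 + e, "*") - 1
  ka_conc <- sweep(denom, 2L, e, "/")   # per-concentration ka_rel
  ka_conc[denom <= 0] <- NA_real_
  colnames(ka_conc) <- conc_label(concs[nz])

  n_inf <- rowSums(!is.na(ka_conc))
  ka <- switch(estimator,
    median = apply(ka_conc, 1L, median, na.rm = TRUE),
    mean   = rowMeans(ka_conc, na.rm = TRUE),
    global = global_ka_fit(normalized[, nz, drop = FALSE] /
                             matrix(nref, nrow(normalized), length(nz),
                                    byrow = TRUE), e))
  below <- n_inf == 0L
  ka[below] <- 0
  ka[is.na(ka)] <- 0
  ka[rownames(normalized) == reference] <- 1

  out <- data.frame(variant = rownames(normalized), ka_rel = ka,
                    n_informative = n_inf, below_detection = below,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "per_conc") <- ka_conc
  attr(out, "reference") <- reference
  attr(out, "ref_k_half") <- ref_k_half
  attr(out, "estimator") <- estimator
  class(out) <- c("affinity_table", "data.frame")
  out
}

## least-squares fit of ln depletion-ratio curves, one 1-D search per variant
## q: matrix of observed variant/reference normalized-frequency ratios
global_ka_fit <- function(q, e) {
  lq <- log(q)
  apply(lq, 1L, function(y) {
    ok <- is.finite(y)
    if (!any(ok)) return(NA_real_)
    obj <- function(lka) {
      kd <- exp(-lka)
      sum((y[ok] - log((kd / (kd + e[ok])) * (1 + e[ok])))^2)
    }
    exp(optimize(obj, c(-25, 25))$minimum)
  })
}

#' Ground-truth relative affinities of a simulated landscape
#'
#' Converts a ground-truth [make_landscape()] into an affinity table with
#' `ka_rel = kd(reference) / kd(variant)`, the quantity the depletion
#' estimator targets.
#'
#' @param landscape an affinity landscape.
#' @param reference reference variant (default `UGCAUGU`).
#' @return An `"affinity_table"` data.frame.
#' @export
true_affinity <- function(landscape, reference = "UGCAUGU") {
  i <- match(reference, landscape$variant)
  if (is.na(i)) stop("reference variant not in landscape")
  as_affinity_table(data.frame(variant = landscape$variant,
                               ka_rel = landscape$kd_nM[i] / landscape$kd_nM,
                               stringsAsFactors = FALSE),
                    reference = reference)
}

#' Coerce a variant/affinity data.frame to an affinity table
#'
#' @param x data.frame with columns `variant` and `ka_rel` (extra columns
#'   are kept).
#' @param reference reference variant label stored with the table.
#' @return An `"affinity_table"` data.frame.
#' @export
as_affinity_table <- function(x, reference = "UGCAUGU") {
  stopifnot(all(c("variant", "ka_rel") %in% names(x)))
  if (any(x$ka_rel < 0)) stop("'ka_rel' must be nonnegative")
  attr(x, "reference") <- reference
  class(x) <- unique(c("affinity_table", class(x)))
  x
}

#' @export
print.affinity_table <- function(x, ...) {
  cat(sprintf("Affinity table: %d variants (reference %s = 1)\n",
              nrow(x), attr(x, "reference")))
  cat(sprintf("  ka_rel range: %.3g - %.3g; below detection: %d\n",
              min(x$ka_rel), max(x$ka_rel),
              if (!is.null(x$below_detection)) sum(x$below_detection) else 0L))
  invisible(x)
}
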