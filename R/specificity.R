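#' Histogram of the relative-affinity distribution
#'
#' Equal-width histogram of `ka_rel` over `[0, max(ka_rel)]` with
#' `n_bins` bins (default 100). Counts conserve the variant total.
#'
#' @param table an `affinity_table`.
#' @param n_bins number of bins (>= 2).
#' @return List of class `"affinity_histogram"` with `breaks`, `counts`,
#'   `mids`.
#' @export
affinity_histogram <- function(table, n_bins = 100L) {
  if (nrow(table) == 0L) stop("empty affinity table")
  if (n_bins < 2L) stop("'n_bins' must be >= 2")
  breaks <- seq(0, max(table$ka_rel), length.out = n_bins + 1L)
  h <- hist(table$ka_rel, breaks = breaks, plot = FALSE,
            include.lowest = TRUE, right = TRUE)
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 n = nrow(table)),
            class = "affinity_histogram")
}

#' @export
print.affinity_histogram <- function(x, ...) {
  cat(sprintf("Affinity histogram: %d variants in %d bins over [0, %.3g]\n",
              x$n, length(x$counts), max(x$breaks)))
  invisible(x)
}

#' @export
plot.affinity_histogram <- function(x, log_count = TRUE, ...) {
  barplot(if (log_count) log10(x$counts + 1) else x$counts,
          names.arg = signif(x$mids, 2),
          xlab = "ka_rel", ylab = if (log_count) "log10(count + 1)"
          else "count", ...)
  invisible(x)
}

#' Assess bimodality of the log-affinity distribution
#'
#' Fits one- and two-component Gaussian mixtures (unequal variances) to
#' `ln(ka_rel)` (floored at a detection limit) and compares them by BIC.
#' A positive `delta_bic` (two-component BIC minus one-component BIC, in
#' mclust's larger-is-better convention) means the two-component model is
#' preferred, i.e. the affinity distribution is bimodal. The membership
#' of the minor, high-affinity component is reported; for a highly
#' specific protein it should contain the cognate-motif variants.
#'
#' @param table an `affinity_table` with at least 50 variants.
#' @param floor detection floor applied before the log transform.
#' @return List of class `"bimodality_test"`: `preferred` (1 or 2),
#'   `delta_bic`, `components` (weight/mean/sd per component of the
#'   two-component fit), `high_affinity_members` (variants assigned to
#'   the higher-mean component), `note`.
#' @export
assess_bimodality <- function(table, floor = 1e-4) {
  if (nrow(table) < 50L) stop("need at least 50 variants")
  x <- log(pmax(table$ka_rel, floor))
  if (sd(x) < sqrt(.Machine$double.eps))
    return(structure(list(preferred = 1L, delta_bic = NA_real_,
                          components = data.frame(weight = 1, mean = x[1],
                                                  sd = 0),
                          high_affinity_members = character(0),
                          note = "degenerate: zero variance"),
                     class = "bimodality_test"))
  m1 <- Mclust(x, G = 1, modelNames = "V", verbose = FALSE)
  m2 <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  delta <- as.numeric(m2$bic - m1$bic)
  comp <- data.frame(weight = m2$parameters$pro,
                     mean = m2$parameters$mean,
                     sd = sqrt(m2$parameters$variance$sigmasq))
  hi <- which.max(comp$mean)
  structure(list(preferred = if (delta > 0) 2L else 1L,
                 delta_bic = delta, components = comp,
                 high_affinity_members =
                   table$variant[m2$classification == hi],
                 note = ""),
            class = "bimodality_test")
}

#' @export
print.bimodality_test <- function(x, ...) {
  cat(sprintf("Bimodality assessment: %d component(s) preferred (delta BIC = %.1f)\n",
              x$preferred, x$delta_bic))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  print(signif(x$components, 3))
  cat(sprintf("  high-affinity component members: %d variants\n",
              length(x$high_affinity_members)))
  invisible(x)
}

#' Sequence logo matrix of the highest-affinity variants
#'
#' Position frequency matrix and per-position information content (bits)
#' computed from the top `n` variants ranked by `ka_rel` (ties broken
#' lexicographically by variant sequence).
#'
#' @param table an `affinity_table`.
#' @param n number of top variants (default 40).
#' @return List of class `"logo_matrix"`: `frequencies` (4 x k matrix,
#'   columns sum to 1), `information` (bits per position, in [0, 2]),
#'   `variants` (the top set).
#' @export
top_variants_logo <- function(table, n = 40L) {
  if (n <= 0L) stop("'n' must be positive")
  if (n > nrow(table)) stop("'n' exceeds the table size")
  ord <- order(-table$ka_rel, table$variant)
  top <- table$variant[ord][seq_len(n)]
  k <- nchar(top[1])
  freq <- vapply(seq_len(k), function(i) {
    nt <- substr(top, i, i)
    tabulate(match(nt, RNA_BASES), nbins = 4L) / n
  }, numeric(4L))
  dimnames(freq) <- list(RNA_BASES, seq_len(k))
  info <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  structure(list(frequencies = freq, information = info, variants = top),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("Sequence logo from %d variants\n", length(x$variants)))
  cat("Information content (bits):",
      paste(sprintf("%.2f", x$information), collapse = " "), "\n")
  cons <- apply(x$frequencies, 2L, function(p) RNA_BASES[which.max(p)])
  cat("Consensus:", paste(cons, collapse = ""), "\n")
  invisible(x)
}

#' @export
plot.logo_matrix <- function(x, ...) {
  barplot(x$frequencies * rep(x$information, each = 4),
          col = c("forestgreen", "dodgerblue", "orange", "firebrick"),
          names.arg = colnames(x$frequencies), xlab = "position",
          ylab = "information (bits)", legend.text = RNA_BASES, ...)
  invisible(x)
}

#' Percentile rank of a variant in the affinity distribution
#'
#' Midrank percentile: `100 * (#below + ties/2) / n`.
#'
#' @param table an `affinity_table`.
#' @param query variant sequence.
#' @return Percentile in percent.
#' @export
percentile_rank <- function(table, query) {
  i <- match(query, table$variant)
  if (is.na(i)) stop("query variant '", query, "' not in the table")
  q <- table$ka_rel[i]
  100 * (sum(table$ka_rel < q) + 0.5 * sum(table$ka_rel == q)) / nrow(table)
}

#' Normalize RBNS R scores to the unit interval
#'
#' Linearly maps enrichment scores onto `[1, e]` and takes the natural
#' log, yielding a strictly monotone map onto `[0, 1]`. This puts RBNS
#' (RNA Bind-n-Seq) R scores from different proteins on a common scale
#' for specificity comparisons.
#'
#' @param r_scores numeric vector of R scores (>= 2 distinct values).
#' @return Numeric vector in `[0, 1]`, same order/names.
#' @examples
#' normalize_rbns(c(1, 2, 3))  # 0, log((1+e)/2) ~ 0.620, 1
#' @export
normalize_rbns <- function(r_scores) {
  rng <- range(r_scores)
  if (diff(rng) == 0)
    stop("no dynamic range: all R scores are identical")
  log(1 + (exp(1) - 1) * (r_scores - rng[1]) / diff(rng))
}

#' Inherent-specificity ratio of an affinity distribution
#'
#' The highest affinity value divided by the median affinity value. The
#' ratio is scale-invariant and >= 1 for any distribution whose maximum
#' is the normalization unit; larger values mean the protein discriminates
#' more strongly between its best substrate and a typical one.
#'
#' @param x numeric vector of (normalized) affinities, or an
#'   `affinity_table`.
#' @return The max/median ratio; `Inf` (with a warning) when the median
#'   is 0.
#' @export
specificity_ratio <- function(x) {
  if (inherits(x, "affinity_table") || is.data.frame(x)) x <- x$ka_rel
  if (!length(x)) stop("empty input")
  med <- median(x)
  if (med == 0) {
    warning("median affinity is 0: specificity ratio is infinite")
    return(Inf)
  }
  max(x) / med
}
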