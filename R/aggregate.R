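#' 7-mer contexts of a 5-mer
#'
#' All distinct 7-mers over \{A,C,G,U\} that contain the given 5-mer as a
#' substring entirely within the randomized window (offsets 0, 1 or 2).
#' A 5-mer that cannot overlap itself has exactly 3 x 16 = 48 contexts;
#' self-overlapping 5-mers (e.g. `AAAAA`) have fewer because some
#' placements coincide.
#'
#' @param kmer5 a 5-mer over \{A,C,G,U\}.
#' @return Character vector of distinct 7-mer contexts.
#' @examples
#' length(kmer_contexts("GCAUG"))  # 48
#' length(kmer_contexts("AAAAA"))  # 40
#' @export
kmer_contexts <- function(kmer5) {
  if (nchar(kmer5) != 5L) stop("'kmer5' must have length 5")
  check_alphabet(kmer5, RNA_BASES, "5-mer")
  n2 <- all_kmers(2L)
  n1 <- all_kmers(1L)
  unique(c(paste0(kmer5, n2),
           paste0(rep(n1, each = 4), kmer5, n1),
           paste0(n2, kmer5)))
}

#' Project 7-mer affinities onto 5-mer space
#'
#' For each of the 1,024 5-mers, collects the relative affinities of all
#' of its 7-mer contexts (the distinct 7-mers carrying the 5-mer at any of
#' its three registers inside the randomized window) and summarizes them
#' with box-plot statistics. The 5-mer summary statistic (median by
#' default) is the quantity fed to the PWM/PWC binding models.
#'
#' @param table an `affinity_table` covering the 7-mers.
#' @param stat `"median"` (default) or `"mean"`.
#' @return A data.frame of class `"fivemer_summary"` with columns `kmer5`,
#'   `ka_rel` (the chosen statistic), `context_count`, `q1`, `median`,
#'   `q3`, `whisker_lo`, `whisker_hi`. 7-mers absent from `table` reduce
#'   `context_count`; rows with missing contexts carry
#'   `attr(, "incomplete") = TRUE`.
#' @export
aggregate_5mer <- function(table, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  ka <- setNames(table$ka_rel, table$variant)
  k5 <- all_kmers(5L)
  res <- vector("list", length(k5))
  incomplete <- FALSE
  for (i in seq_along(k5)) {
    ctx <- kmer_contexts(k5[i])
    v <- ka[ctx]
    v <- v[!is.na(v)]
    if (length(v) < length(ctx)) incomplete <- TRUE
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    res[[i]] <- c(if (stat == "median") q[2] else mean(v),
                  length(v), q[1], q[2], q[3], min(v), max(v))
  }
  m <- do.call(rbind, res)
  out <- data.frame(kmer5 = k5, ka_rel = m[, 1],
                    context_count = as.integer(m[, 2]),
                    q1 = m[, 3], median = m[, 4], q3 = m[, 5],
                    whisker_lo = m[, 6], whisker_hi = m[, 7],
                    stringsAsFactors = FALSE)
  attr(out, "stat") <- stat
  attr(out, "incomplete") <- incomplete
  attr(out, "reference") <- attr(table, "reference")
  class(out) <- c("fivemer_summary", "data.frame")
  out
}

#' Effect of the nucleotides flanking a core 5-mer
#'
#' Considers the 16 7-mers `N-core5-N` (the centered register, where the
#' core occupies positions 2-6) and groups their affinities by the 5' and
#' 3' flanking nucleotide. Reports per-flank medians and the natural-log
#' ratios between every pair of flank choices, on each side.
#'
#' @param table an `affinity_table` covering the 7-mers.
#' @param core5 core 5-mer.
#' @return A list of class `"flanking_effect"`: `variants` (the 16-row
#'   table of flank combinations and affinities), `medians` (4 x 2 matrix,
#'   nucleotide x side), `log_ratios` (list of two 4 x 4 matrices,
#'   `log(median[row]/median[col])`, one per side).
#' @export
flanking_effect <- function(table, core5) {
  if (nchar(core5) != 5L) stop("'core5' must have length 5")
  ka <- setNames(table$ka_rel, table$variant)
  n1 <- all_kmers(1L)
  grid <- expand.grid(f5 = n1, f3 = n1, stringsAsFactors = FALSE)
  v7 <- paste0(grid$f5, core5, grid$f3)
  df <- data.frame(grid, variant = v7, ka_rel = ka[v7],
                   stringsAsFactors = FALSE, row.names = NULL)
  med <- cbind(`5p` = tapply(df$ka_rel, df$f5, median, na.rm = TRUE)[n1],
               `3p` = tapply(df$ka_rel, df$f3, median, na.rm = TRUE)[n1])
  rownames(med) <- n1
  lr <- lapply(c("5p", "3p"), function(s) {
    m <- outer(med[, s], med[, s], function(a, b) log(a / b))
    dimnames(m) <- list(n1, n1)
    m
  })
  names(lr) <- c("5p", "3p")
  structure(list(core5 = core5, variants = df, medians = med,
                 log_ratios = lr),
            class = "flanking_effect")
}

#' @export
print.flanking_effect <- function(x, ...) {
  cat(sprintf("Flanking-nucleotide effect around %s (centered register, %d 7-mers)\n",
              x$core5, nrow(x$variants)))
  cat("Group medians of ka_rel:\n")
  print(signif(x$medians, 3))
  invisible(x)
}
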