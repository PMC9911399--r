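#' Indicator design matrix for k-mer regression models
#'
#' Encodes k-mers as 0/1 indicators with the cognate (baseline) sequence
#' as reference level: one column per (position, non-baseline nucleotide),
#' and, if `pairwise`, one per (position pair, non-baseline nucleotide
#' pair). The baseline k-mer encodes to the all-zero row. For a 5-mer this
#' gives 15 positional columns and 10 x 9 = 90 interaction columns.
#'
#' @param kmers character vector of k-mers over \{A,C,G,U\}.
#' @param baseline baseline k-mer (same length).
#' @param pairwise include pairwise interaction columns.
#' @return Numeric matrix with one row per k-mer; column metadata in
#'   `attr(, "positional")` and `attr(, "pairwise")`.
#' @export
encode_variants <- function(kmers, baseline, pairwise = FALSE) {
  k <- nchar(baseline)
  if (any(nchar(kmers) != k))
    stop("all k-mers must have the length of the baseline (", k, ")")
  check_alphabet(c(kmers, baseline), RNA_BASES, "k-mers")
  ntpos <- lapply(seq_len(k), function(i) substr(kmers, i, i))
  base_nt <- strsplit(baseline, "")[[1]]

  pos_meta <- do.call(rbind, lapply(seq_len(k), function(i)
    data.frame(pos = i, nt = setdiff(RNA_BASES, base_nt[i]),
               stringsAsFactors = FALSE)))
  pos_meta$col <- sprintf("p%d.%s", pos_meta$pos, pos_meta$nt)
  X <- vapply(seq_len(nrow(pos_meta)),
              function(r) as.numeric(ntpos[[pos_meta$pos[r]]] ==
                                       pos_meta$nt[r]),
              numeric(length(kmers)))
  colnames(X) <- pos_meta$col

  pair_meta <- NULL
  if (pairwise) {
    pair_meta <- do.call(rbind, lapply(seq_len(k - 1), function(i) {
      do.call(rbind, lapply(seq(i + 1, k), function(j) {
        g <- expand.grid(nt1 = setdiff(RNA_BASES, base_nt[i]),
                         nt2 = setdiff(RNA_BASES, base_nt[j]),
                         stringsAsFactors = FALSE)
        data.frame(pos1 = i, pos2 = j, g, stringsAsFactors = FALSE)
      }))
    }))
    pair_meta$col <- sprintf("p%d%s:p%d%s", pair_meta$pos1, pair_meta$nt1,
                             pair_meta$pos2, pair_meta$nt2)
    Xi <- vapply(seq_len(nrow(pair_meta)), function(r)
      as.numeric(ntpos[[pair_meta$pos1[r]]] == pair_meta$nt1[r] &
                   ntpos[[pair_meta$pos2[r]]] == pair_meta$nt2[r]),
      numeric(length(kmers)))
    colnames(Xi) <- pair_meta$col
    X <- cbind(X, Xi)
  }
  rownames(X) <- kmers
  attr(X, "positional") <- pos_meta
  attr(X, "pairwise") <- pair_meta
  attr(X, "baseline") <- baseline
  X
}

## shared fitting engine for the PWM and PWC models
fit_kmer_model <- function(x, baseline, pairwise, floor, intercept,
                           t_threshold = 3.5) {
  kmers <- if (!is.null(x$variant)) x$variant else x$kmer5
  if (is.null(kmers)) stop("'x' must have a 'variant' or 'kmer5' column")
  ka <- x$ka_rel
  k <- nchar(kmers[1])
  if (is.null(baseline))
    baseline <- if (k == 5L) "GCAUG" else "UGCAUGU"
  if (!baseline %in% kmers)
    stop("baseline variant '", baseline, "' not present in the table")
  if (any(ka <= 0)) {
    if (floor <= 0)
      stop("nonpositive affinities present: supply a positive detection ",
           "'floor' to clip them before the log transform")
    ka <- pmax(ka, floor)
  } else if (floor > 0) ka <- pmax(ka, floor)
  y <- log(ka)

  X <- encode_variants(kmers, baseline, pairwise = pairwise)
  fit_idx <- kmers != baseline       # cognate point withheld from the fit
  Xf <- X[fit_idx, , drop = FALSE]
  yf <- y[fit_idx]
  if (length(yf) <= ncol(Xf) + intercept)
    stop("fewer observations than free parameters")

  Xd <- if (intercept) cbind(`(Intercept)` = 1, Xf) else Xf
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd)) {
    aliased <- colnames(Xd)[qx$pivot[seq(qx$rank + 1, ncol(Xd))]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qx, yf)
  fitted_f <- drop(Xd %*% beta)
  res_f <- yf - fitted_f
  dfree <- length(yf) - ncol(Xd)
  sigma2 <- sum(res_f^2) / dfree
  XtXinv <- matrix(NA_real_, ncol(Xd), ncol(Xd))
  XtXinv[qx$pivot, qx$pivot] <- chol2inv(qr.R(qx))  # undo any column pivoting
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  names(se) <- colnames(Xd)
  tss <- sum((yf - mean(yf))^2)
  r2 <- if (tss > 0) 1 - sum(res_f^2) / tss else 0

  icpt <- if (intercept) beta[["(Intercept)"]] else 0
  pred_all <- drop(X %*% beta[colnames(X)]) + icpt
  # r2 including the withheld cognate point, for reference
  tss_all <- sum((y - mean(y))^2)
  r2_all <- if (tss_all > 0) 1 - sum((y - pred_all)^2) / tss_all else 0
  base_i <- which(kmers == baseline)

  pos_meta <- attr(X, "positional")
  coef_mat <- matrix(0, 4L, k, dimnames = list(RNA_BASES, seq_len(k)))
  coef_mat[cbind(match(pos_meta$nt, RNA_BASES), pos_meta$pos)] <-
    beta[pos_meta$col]
  se_mat <- matrix(0, 4L, k, dimnames = list(RNA_BASES, seq_len(k)))
  se_mat[cbind(match(pos_meta$nt, RNA_BASES), pos_meta$pos)] <-
    se[pos_meta$col]

  out <- list(coefficients = coef_mat, coef_se = se_mat,
              intercept = icpt, baseline = baseline, k = k,
              r2 = r2, r2_with_baseline = r2_all, sigma = sqrt(sigma2),
              df_residual = dfree,
              fitted = pred_all, residuals = y - pred_all,
              kmers = kmers, y = y, floor = floor,
              baseline_prediction = unname(pred_all[base_i]),
              baseline_residual = unname((y - pred_all)[base_i]))
  if (pairwise) {
    pm <- attr(X, "pairwise")
    pm$coefficient <- beta[pm$col]
    pm$se <- se[pm$col]
    pm$t <- pm$coefficient / pm$se
    pm$significant <- abs(pm$t) > t_threshold
    rownames(pm) <- NULL
    out$interactions <- pm[c("pos1", "nt1", "pos2", "nt2",
                             "coefficient", "se", "t", "significant")]
    out$t_threshold <- t_threshold
  }
  out
}

#' Position weight matrix (PWM) model of log relative affinity
#'
#' Ordinary least squares of `ln(ka_rel)` on per-position nucleotide
#' indicators, with the cognate motif as baseline in two senses: its
#' nucleotides are the reference level (their coefficients are fixed at
#' 0), and the cognate variant's data point is withheld from the fit so
#' that its out-of-fit residual diagnoses whether the cognate behaves as
#' an outlier relative to the additive model. Negative coefficients mean
#' destabilization relative to the cognate nucleotide at that position.
#'
#' @param x an `affinity_table` (7-mers) or [aggregate_5mer()] summary
#'   (5-mers); any data.frame with a `variant`/`kmer5` column and
#'   `ka_rel`.
#' @param baseline baseline k-mer; defaults to `GCAUG` (5-mers) or
#'   `UGCAUGU` (7-mers).
#' @param floor detection floor applied to `ka_rel` before the log
#'   transform (default 1e-4); below-detection values otherwise dominate
#'   the fit.
#' @param intercept include an intercept (default TRUE); the baseline row
#'   encodes to all zeros, so without an intercept its predicted
#'   log-affinity is forced to 0.
#' @return An object of class `"pwm_fit"`: coefficient matrix (4 x k,
#'   baseline entries 0), standard errors, `r2` on the fitted set (the
#'   cognate excluded), `r2_with_baseline`, per-variant fitted values and
#'   residuals, and the cognate's out-of-fit prediction/residual.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`.
#' @seealso [fit_pwc()] for the pairwise-coupling extension.
#' @export
fit_pwm <- function(x, baseline = NULL, floor = 1e-4, intercept = TRUE) {
  out <- fit_kmer_model(x, baseline, pairwise = FALSE, floor = floor,
                        intercept = intercept)
  class(out) <- "pwm_fit"
  out
}

#' Pairwise-coupling (PWC) model of log relative affinity
#'
#' Extends the PWM model ([fit_pwm()]) with interaction coefficients for
#' every pair of nucleotide positions, capturing couplings such as the
#' G2-A4 interaction of the cognate RbFox motif. Couplings with
#' |t| > `t_threshold` (default 3.5) are flagged statistically
#' significant; t statistics are the OLS coefficient estimates divided by
#' their standard errors, with no multiple-testing correction.
#'
#' @inheritParams fit_pwm
#' @param t_threshold |t| cutoff for flagging a coupling as significant.
#' @return An object of class `c("pwc_fit", "pwm_fit")`; in addition to
#'   the PWM fields it carries `interactions`, a data.frame with columns
#'   `pos1`, `nt1`, `pos2`, `nt2`, `coefficient`, `se`, `t`,
#'   `significant`. Use [coupling_matrix()] for a heatmap-ready layout.
#' @export
fit_pwc <- function(x, baseline = NULL, floor = 1e-4, intercept = TRUE,
                    t_threshold = 3.5) {
  out <- fit_kmer_model(x, baseline, pairwise = TRUE, floor = floor,
                        intercept = intercept, t_threshold = t_threshold)
  class(out) <- c("pwc_fit", "pwm_fit")
  out
}

#' @export
coef.pwm_fit <- function(object, ...) object$coefficients

#' @export
fitted.pwm_fit <- function(object, ...)
  setNames(object$fitted, object$kmers)

#' @export
residuals.pwm_fit <- function(object, ...)
  setNames(object$residuals, object$kmers)

#' @export
predict.pwm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  kmers <- if (is.character(newdata)) newdata
           else if (!is.null(newdata$variant)) newdata$variant
           else newdata$kmer5
  X <- encode_variants(kmers, object$baseline,
                       pairwise = inherits(object, "pwc_fit"))
  pos <- attr(X, "positional")
  pred <- rep(object$intercept, length(kmers))
  pred <- pred + drop(X[, pos$col, drop = FALSE] %*%
                        object$coefficients[cbind(match(pos$nt, RNA_BASES),
                                                  pos$pos)])
  if (inherits(object, "pwc_fit")) {
    pm <- attr(X, "pairwise")
    key <- sprintf("p%d%s:p%d%s", object$interactions$pos1,
                   object$interactions$nt1, object$interactions$pos2,
                   object$interactions$nt2)
    pred <- pred + drop(X[, pm$col, drop = FALSE] %*%
                          object$interactions$coefficient[match(pm$col, key)])
  }
  setNames(pred, kmers)
}

#' @export
print.pwm_fit <- function(x, ...) {
  kind <- if (inherits(x, "pwc_fit")) "Pairwise-coupling (PWC)"
          else "Position weight matrix (PWM)"
  cat(sprintf("%s model of ln(ka_rel), baseline %s\n", kind, x$baseline))
  cat(sprintf("  fitted on %d variants (cognate withheld); R2 = %.3f\n",
              length(x$kmers) - 1L, x$r2))
  cat(sprintf("  cognate out-of-fit residual: %+.3f (predicted %.3f, observed %.3f)\n",
              x$baseline_residual, x$baseline_prediction,
              x$y[x$kmers == x$baseline]))
  if (inherits(x, "pwc_fit"))
    cat(sprintf("  significant couplings (|t| > %.1f): %d of %d\n",
                x$t_threshold, sum(x$interactions$significant),
                nrow(x$interactions)))
  invisible(x)
}

#' @export
summary.pwm_fit <- function(object, ...) {
  cat(sprintf("R2 (fit set) = %.3f; R2 incl. baseline = %.3f; sigma = %.3f\n",
              object$r2, object$r2_with_baseline, object$sigma))
  cat("Positional coefficients (ln ka_rel; baseline nucleotides = 0):\n")
  print(round(object$coefficients, 3))
  if (inherits(object, "pwc_fit")) {
    sig <- object$interactions[object$interactions$significant, ]
    cat(sprintf("\nSignificant couplings (|t| > %.1f):\n",
                object$t_threshold))
    print(sig, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' @export
plot.pwm_fit <- function(x, ...) {
  k <- x$k
  image(seq_len(k), 1:4, t(x$coefficients)[, 4:1, drop = FALSE],
        xlab = "position", ylab = "", axes = FALSE,
        main = "PWM coefficients (ln ka_rel)", ...)
  axis(1, at = seq_len(k)); axis(2, at = 1:4, labels = rev(RNA_BASES),
                                 las = 1)
  box()
  invisible(x)
}

#' Heatmap layout of pairwise-coupling coefficients
#'
#' Arranges PWC interaction values as a square matrix over all
#' (position, nucleotide) states, suitable for heatmap display. Cells for
#' same-position pairs and for pairs involving a baseline nucleotide are
#' `NA` (the latter are reference levels, identically 0 in the model).
#'
#' @param object a [fit_pwc()] object.
#' @param value `"coefficient"` (default) or `"t"`.
#' @return A symmetric (4k x 4k) matrix with dimnames like `"1A"`, `"1C"`,
#'   ...
#' @export
coupling_matrix <- function(object, value = c("coefficient", "t")) {
  value <- match.arg(value)
  stopifnot(inherits(object, "pwc_fit"))
  k <- object$k
  states <- paste0(rep(seq_len(k), each = 4), rep(RNA_BASES, k))
  m <- matrix(NA_real_, length(states), length(states),
              dimnames = list(states, states))
  it <- object$interactions
  i <- match(paste0(it$pos1, it$nt1), states)
  j <- match(paste0(it$pos2, it$nt2), states)
  m[cbind(i, j)] <- it[[value]]
  m[cbind(j, i)] <- it[[value]]
  m
}

#' Coefficient differences between two fitted binding models
#'
#' Elementwise difference `a - b` of the positional coefficients (and,
#' for PWC fits, the pairwise couplings) of two models with the same
#' baseline and k-mer length, e.g. a wild-type protein versus a mutant.
#' Positive values mean the coefficient is larger in `model_a`.
#'
#' @param model_a,model_b fitted [fit_pwm()] or [fit_pwc()] objects.
#' @return A list of class `"coefficient_difference"` with `positional`
#'   (4 x k matrix) and, when both models carry couplings,
#'   `interactions` (the PWC interaction table with a `difference`
#'   column).
#' @export
coefficient_difference <- function(model_a, model_b) {
  if (model_a$baseline != model_b$baseline)
    stop("models have different baselines: ", model_a$baseline, " vs ",
         model_b$baseline)
  if (model_a$k != model_b$k) stop("models have different k-mer lengths")
  out <- list(baseline = model_a$baseline,
              positional = model_a$coefficients - model_b$coefficients)
  if (inherits(model_a, "pwc_fit") && inherits(model_b, "pwc_fit")) {
    ia <- model_a$interactions; ib <- model_b$interactions
    stopifnot(identical(ia[c("pos1", "nt1", "pos2", "nt2")],
                        ib[c("pos1", "nt1", "pos2", "nt2")]))
    out$interactions <- cbind(ia[c("pos1", "nt1", "pos2", "nt2")],
                              difference = ia$coefficient - ib$coefficient)
  }
  class(out) <- "coefficient_difference"
  out
}

#' @export
print.coefficient_difference <- function(x, ...) {
  cat("Coefficient differences (model_a - model_b), baseline",
      x$baseline, "\n")
  print(round(x$positional, 3))
  if (!is.null(x$interactions)) {
    big <- x$interactions[order(-abs(x$interactions$difference)), ][1:5, ]
    cat("Largest coupling differences:\n")
    print(big, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
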