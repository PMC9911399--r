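#' Equilibrium binding-isotherm models
#'
#' `quadratic_isotherm()` is the exact two-component equilibrium solution
#' for direct titration of an RNA at concentration `r0` with protein at
#' total concentration `p0`:
#' `A * ((K + R0 + P0) - sqrt((K + R0 + P0)^2 - 4*R0*P0)) / (2*R0)`.
#' It does not assume protein excess, and reduces to the hyperbola
#' `A * P0/(P0 + K)` as `r0 -> 0`. `competition_isotherm()` is the bound
#' fraction of a labelled RNA (`r1`, dissociation constant `k1`) in the
#' presence of an unlabelled competitor at concentration `r2` with
#' dissociation constant `k2`:
#' `A * R1 / (R1 + K1 * (1 + R2/K2))`.
#'
#' @param p0 total protein concentration(s), nM.
#' @param k_half apparent dissociation constant, nM.
#' @param A amplitude (maximal bound fraction).
#' @param r0 total RNA concentration, nM.
#' @param r2 competitor RNA concentration(s), nM.
#' @param k2 competitor dissociation constant, nM.
#' @param r1 labelled RNA concentration, nM.
#' @param k1 dissociation constant of the labelled RNA, nM.
#' @return Predicted bound fraction(s).
#' @export
quadratic_isotherm <- function(p0, k_half, A = 1, r0 = 1) {
  s <- k_half + r0 + p0
  # rationalized form of (s - sqrt(s^2 - 4*r0*p0)) / (2*r0): stable as r0 -> 0
  A * 2 * p0 / (s + sqrt(s^2 - 4 * r0 * p0))
}

#' @rdname quadratic_isotherm
#' @export
competition_isotherm <- function(r2, k2, A = 1, r1 = 1, k1 = 1) {
  A * r1 / (r1 + k1 * (1 + r2 / k2))
}

#' Fit a direct or competition binding isotherm
#'
#' `fit_isotherm()` fits the quadratic binding equation (see
#' [quadratic_isotherm()]) to bound fraction vs protein concentration by
#' nonlinear least squares, estimating the amplitude `A` and the apparent
#' half-saturation constant `k_half`. `fit_competition()` fits the
#' competitive-inhibition equation to bound fraction vs competitor
#' concentration, estimating `A` and the competitor constant `k2` given
#' the separately measured `k1`.
#'
#' Fits use Levenberg-Marquardt least squares with multistart
#' initialization: `k_half` (or `k2`) is started at 0.1x, 1x and 10x the
#' median nonzero titrant concentration, with `A` started at 1; the best
#' converged fit is returned.
#'
#' @param fraction_bound observed bound fractions.
#' @param p0 protein concentrations, nM (same length).
#' @param r0 RNA concentration, nM (fixed, default 1).
#' @param r2 competitor concentrations, nM.
#' @param r1 labelled RNA concentration, nM.
#' @param k1 dissociation constant of the labelled RNA, nM (fixed).
#' @return An object of class `"isotherm_fit"`: coefficients, standard
#'   errors, the fixed parameters, fitted values and residuals. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`.
#' @examples
#' p0 <- c(0, 1, 2, 4, 6, 25, 50, 100)
#' fb <- quadratic_isotherm(p0, k_half = 1.6, A = 1, r0 = 1)
#' fit <- fit_isotherm(fb, p0, r0 = 1)
#' coef(fit)["k_half"]
#' @export
fit_isotherm <- function(fraction_bound, p0, r0 = 1) {
  if (length(fraction_bound) != length(p0))
    stop("'fraction_bound' and 'p0' must have equal length")
  if (length(p0) < 3) stop("need at least 3 data points")
  if (any(p0 < 0)) stop("'p0' must be nonnegative")
  df <- data.frame(fb = fraction_bound, p0 = p0)
  mid <- median(p0[p0 > 0])
  starts <- lapply(c(0.1, 1, 10) * mid,
                   function(k) list(A = 1, k_half = k))
  fit <- multistart_nls(
    fb ~ quadratic_isotherm(p0, k_half, A, r0),
    data = df, starts = starts,
    lower = c(A = 1e-6, k_half = 1e-9))
  new_isotherm_fit(fit, model = "direct", data = df,
                   fixed = c(r0 = r0))
}

#' @rdname fit_isotherm
#' @export
fit_competition <- function(fraction_bound, r2, r1 = 1, k1) {
  if (missing(k1) || k1 <= 0)
    stop("'k1' (the labelled RNA's dissociation constant) must be supplied and positive")
  if (length(fraction_bound) != length(r2))
    stop("'fraction_bound' and 'r2' must have equal length")
  if (length(r2) < 3) stop("need at least 3 data points")
  if (all(fraction_bound == 0)) stop("no signal: all bound fractions are zero")
  df <- data.frame(fb = fraction_bound, r2 = r2)
  mid <- median(r2[r2 > 0])
  starts <- lapply(c(0.1, 1, 10) * mid, function(k) list(A = 1, k2 = k))
  fit <- multistart_nls(
    fb ~ competition_isotherm(r2, k2, A, r1, k1),
    data = df, starts = starts,
    lower = c(A = 1e-6, k2 = 1e-9))
  new_isotherm_fit(fit, model = "competition", data = df,
                   fixed = c(r1 = r1, k1 = k1))
}

multistart_nls <- function(formula, data, starts, lower) {
  best <- NULL; best_rss <- Inf
  for (s in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = s, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(residuals(f)^2)
      if (rss < best_rss) { best <- f; best_rss <- rss }
    }
  }
  if (is.null(best))
    stop("isotherm fit did not converge from any start (",
         paste(vapply(starts, function(s) sprintf("%.3g", s[[2]]),
                      character(1)), collapse = ", "), ")")
  best
}

new_isotherm_fit <- function(fit, model, data, fixed) {
  sm <- summary(fit)
  structure(list(coefficients = coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 model = model, fixed = fixed, data = data,
                 fitted = fitted(fit), residuals = residuals(fit),
                 nls = fit),
            class = "isotherm_fit")
}

#' @export
coef.isotherm_fit <- function(object, ...) object$coefficients

#' @export
fitted.isotherm_fit <- function(object, ...) object$fitted

#' @export
residuals.isotherm_fit <- function(object, ...) object$residuals

#' @export
predict.isotherm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  cf <- object$coefficients
  if (object$model == "direct") {
    quadratic_isotherm(newdata$p0, cf[["k_half"]], cf[["A"]],
                       object$fixed[["r0"]])
  } else {
    competition_isotherm(newdata$r2, cf[["k2"]], cf[["A"]],
                         object$fixed[["r1"]], object$fixed[["k1"]])
  }
}

#' @export
print.isotherm_fit <- function(x, ...) {
  lab <- if (x$model == "direct") "quadratic binding isotherm"
         else "competition binding isotherm"
  cat(sprintf("Fit of %s (%d points)\n", lab, nrow(x$data)))
  k <- setdiff(names(x$coefficients), "A")
  cat(sprintf("  A = %.4g +/- %.2g, %s = %.4g +/- %.2g nM\n",
              x$coefficients[["A"]], x$se[["A"]], k,
              x$coefficients[[k]], x$se[[k]]))
  cat("  fixed:", paste(names(x$fixed), signif(x$fixed, 4),
                        sep = " = ", collapse = ", "), "nM\n")
  invisible(x)
}

#' @export
summary.isotherm_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$coefficients / object$se)
  structure(list(model = object$model, coefficients = tab,
                 rss = sum(object$residuals^2), n = nrow(object$data)),
            class = "summary.isotherm_fit")
}

#' @export
print.summary.isotherm_fit <- function(x, ...) {
  cat(sprintf("%s isotherm fit, n = %d, RSS = %.3g\n",
              x$model, x$n, x$rss))
  printCoefmat(x$coefficients)
  invisible(x)
}

#' @export
plot.isotherm_fit <- function(x, ...) {
  xv <- x$data[[2]]
  xx <- seq(min(xv), max(xv), length.out = 200)
  nd <- setNames(data.frame(xx), names(x$data)[2])
  plot(xv, x$data$fb, log = if (all(xv > 0)) "x" else "",
       xlab = paste0(names(x$data)[2], " (nM)"),
       ylab = "fraction bound", ...)
  lines(xx, predict(x, nd))
  invisible(x)
}
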