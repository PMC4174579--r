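#' Fit a saturation-binding calibration curve
#'
#' Nonlinear least squares of the binding isotherm
#' `signal = a * D / (D + K)` to a reagent titration, where `a` is the
#' plateau signal and `K` the half-saturation concentration (ug/ml).
#' Used to calibrate the working concentration of the soluble
#' availability reagents.  Fluorescence noise is multiplicative, so the
#' default loss weights residuals by the inverse squared fitted signal
#' (relative residuals, two-pass); `loss = "linear"` gives plain
#' unweighted least squares.
#'
#' @param concentrations reagent concentrations (ug/ml); at least 3
#'   distinct values.
#' @param signals measured signals (same length; replicates appear as
#'   repeated concentrations).
#' @param loss `"relative"` (default) or `"linear"`.
#' @return An object of class `saturation_fit` with `coefficients`
#'   (`a`, `K`), asymptotic standard errors `se`, `residual_norm`, and an
#'   `identifiable` flag (set to `FALSE`, with a warning, when the fitted
#'   `K` falls well outside the sampled concentration range, i.e. the
#'   design contains no information about half saturation).
#' @export
fit_saturation <- function(concentrations, signals,
                           loss = c("relative", "linear")) {
  loss <- match.arg(loss)
  stopifnot(length(concentrations) == length(signals))
  if (length(unique(concentrations)) < 3)
    stop("need at least 3 distinct concentrations", call. = FALSE)
  if (all(signals == 0)) stop("all signals are zero; nothing to fit",
                              call. = FALSE)
  df <- data.frame(D = concentrations, y = signals)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * D / (D + K), data = df,
                      start = list(a = max(signals),
                                   K = stats::median(concentrations)),
                      lower = c(a = 1e-12, K = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("saturation fit flagged: K is not identified by the sampled concentrations (",
            conditionMessage(fit), ")", call. = FALSE)
    return(structure(list(coefficients = c(a = NA_real_, K = NA_real_),
                          se = c(a = NA_real_, K = NA_real_), fit = NULL,
                          data = df, residual_norm = NA_real_,
                          identifiable = FALSE),
                     class = "saturation_fit"))
  }
  if (loss == "relative") {
    w <- 1 / pmax(stats::predict(fit), max(signals) * 1e-6)^2
    fit <- minpack.lm::nlsLM(y ~ a * D / (D + K), data = df, weights = w,
                             start = as.list(stats::coef(fit)),
                             lower = c(a = 1e-12, K = 1e-12),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 2))
  pos <- concentrations[concentrations > 0]
  identifiable <- cf[["K"]] >= min(pos) / 10 && cf[["K"]] <= max(pos) * 10 &&
    all(is.finite(se))
  if (!identifiable)
    warning("saturation fit flagged: K is not identified by the sampled concentrations",
            call. = FALSE)
  structure(list(coefficients = cf, se = se, fit = fit, data = df,
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 identifiable = identifiable),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, digits = 4, ...) {
  cat("Saturation-binding fit: signal = a * D / (D + K)\n")
  cat(sprintf("  a = %s +/- %s\n", format(x$coefficients[["a"]], digits = digits),
              format(x$se[[1]], digits = 3)))
  cat(sprintf("  K = %s +/- %s ug/ml\n",
              format(x$coefficients[["K"]], digits = digits),
              format(x$se[[2]], digits = 3)))
  if (!x$identifiable) cat("  [flagged: K not identified]\n")
  invisible(x)
}

#' @export
coef.saturation_fit <- function(object, ...) object$coefficients

#' @export
predict.saturation_fit <- function(object, newdata = NULL, ...) {
  D <- if (is.null(newdata)) object$data$D
  else if (is.numeric(newdata)) newdata else newdata[[1L]]
  cf <- object$coefficients
  cf[["a"]] * D / (D + cf[["K"]])
}

#' @export
plot.saturation_fit <- function(x, pch = 16, col = "steelblue",
                                curve_col = "firebrick", ...) {
  graphics::plot(x$data$D, x$data$y, pch = pch, col = col,
                 xlab = "Reagent concentration (ug/ml)",
                 ylab = "Signal (fluorescence)", ...)
  Dg <- seq(0, max(x$data$D), length.out = 200)
  graphics::lines(Dg, predict(x, Dg), col = curve_col, lwd = 2)
  invisible(x)
}
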