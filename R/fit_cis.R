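#' Fit the cis-inhibition dose-response model to single-cell data
#'
#' Fits the quasi-steady-state availability curve
#' `avail = bg + A / (1 + L / L50)` to single-cell (effective ligand,
#' availability) points by nonlinear least squares.  `A` is the
#' availability at zero ligand, `L50` the effective-ligand level halving
#' it (the fluorescence-scale analogue of the model's `kc * gamma_N`),
#' and `bg` an additive background offset.  Each cell is weighted
#' equally; by default residuals are taken on the log scale
#' (`log(avail)` vs `log(model)`), which stabilises the multiplicative
#' measurement variance — points with non-positive availability are then
#' dropped.
#'
#' @param x a formula `availability ~ ligand` with `data`, or a numeric
#'   vector of effective-ligand values.
#' @param y availability values (when `x` is numeric).
#' @param data data.frame supplying the formula variables.
#' @param log_residuals logical; fit on log-availability residuals
#'   (default) or on the linear scale.
#' @param start optional named list/vector with starting values `A`,
#'   `L50`, `bg`.
#' @return An object of class `cis_fit` with methods `print`, `summary`,
#'   `coef`, `vcov`, `confint`, `predict`, `fitted`, `residuals`, `plot`
#'   and `simulate`.  Fields include `coefficients`, `se`,
#'   `identifiable`, `notes` and `residual_norm`.  If `L50` falls outside
#'   the sampled ligand range the fit is flagged non-identifiable with a
#'   warning.
#' @examples
#' cfg <- generator_config(n_cells_per_level = 50)
#' tab <- generate_availability_dataset(cfg, assay_kinetic_params())
#' fit <- fit_cis_inhibition(availability_fluor ~ total_ligand_fluor, data = tab)
#' coef(fit)
#' @export
fit_cis_inhibition <- function(x, y = NULL, data = NULL,
                               log_residuals = TRUE, start = NULL) {
  cl <- match.call()
  if (inherits(x, "formula")) {
    mf <- stats::model.frame(x, data = data)
    yv <- mf[[1L]]; xv <- mf[[2L]]
  } else {
    xv <- x; yv <- y
  }
  ok <- is.finite(xv) & is.finite(yv) & xv >= 0
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 4) stop("need at least 4 points", call. = FALSE)
  lo <- stats::quantile(xv, 0.1); hi <- stats::quantile(xv, 0.9)
  if (is.null(start)) {
    bg0 <- max(stats::median(yv[xv >= hi]), 1e-8)
    A0 <- max(stats::median(yv[xv <= lo]) - bg0, 1e-6)
    half <- bg0 + A0 / 2
    ox <- order(xv)
    runmed_y <- stats::runmed(yv[ox], k = min(31L,
      2L * (length(yv) %/% 2L) - 1L))
    cross <- which(runmed_y <= half)[1]
    L500 <- if (!is.na(cross)) max(xv[ox][cross], min(xv[xv > 0]))
    else stats::median(xv)
    start <- list(A = A0, L50 = L500, bg = bg0)
  }
  df <- data.frame(L = xv, avail = yv)
  fit <- tryCatch({
    if (log_residuals) {
      dfit <- df[df$avail > 0, ]
      minpack.lm::nlsLM(
        log(avail) ~ log(bg + A / (1 + L / L50)), data = dfit,
        start = start, lower = c(A = 0, L50 = 1e-12, bg = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        avail ~ bg + A / (1 + L / L50), data = dfit <- df,
        start = start, lower = c(A = 0, L50 = 1e-12, bg = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    # degenerate data (e.g. no ligand dependence): flagged, not fatal
    notes <- paste("optimizer failed:", conditionMessage(fit))
    warning("cis fit flagged non-identifiable: ", notes, call. = FALSE)
    return(structure(list(coefficients = c(A = NA_real_, L50 = NA_real_,
                                           bg = NA_real_),
                          se = c(A = NA_real_, L50 = NA_real_,
                                 bg = NA_real_),
                          fit = NULL, data = df,
                          log_residuals = log_residuals,
                          residual_norm = NA_real_, sigma = NA_real_,
                          identifiable = FALSE, notes = notes, call = cl),
                     class = "cis_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 3))
  notes <- character(0)
  pos <- xv[xv > 0]
  if (cf[["L50"]] < min(pos) || cf[["L50"]] > max(pos))
    notes <- c(notes, "L50 outside the sampled ligand range")
  if (is.finite(se[["L50"]]) && se[["L50"]] / cf[["L50"]] > 1)
    notes <- c(notes, "L50 relative standard error exceeds 100%")
  if (any(!is.finite(se)))
    notes <- c(notes, "singular covariance (parameters not identified)")
  identifiable <- length(notes) == 0
  if (!identifiable)
    warning("cis fit flagged non-identifiable: ",
            paste(notes, collapse = "; "), call. = FALSE)
  structure(list(coefficients = cf, se = se, fit = fit, data = df,
                 log_residuals = log_residuals,
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 sigma = stats::sigma(fit),
                 identifiable = identifiable, notes = notes, call = cl),
            class = "cis_fit")
}

#' @export
print.cis_fit <- function(x, digits = 4, ...) {
  cat("Cis-inhibition dose-response fit: avail = bg + A / (1 + L/L50)\n")
  cat(sprintf("  A   = %s (availability at zero ligand)\n",
              format(x$coefficients[["A"]], digits = digits)))
  cat(sprintf("  L50 = %s (half-inhibition effective ligand)\n",
              format(x$coefficients[["L50"]], digits = digits)))
  cat(sprintf("  bg  = %s (background offset)\n",
              format(x$coefficients[["bg"]], digits = digits)))
  cat(sprintf("  n = %d cells, %s-scale residual norm %.4g\n",
              nrow(x$data), if (x$log_residuals) "log" else "linear",
              x$residual_norm))
  if (!x$identifiable)
    cat("  [flagged]", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.cis_fit <- function(object, ...) object$coefficients

#' @export
vcov.cis_fit <- function(object, ...) stats::vcov(object$fit)

#' @export
confint.cis_fit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients; se <- object$se
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(cf - z * se, cf + z * se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.cis_fit <- function(object, ...) {
  cf <- object$coefficients
  cf[["bg"]] + cf[["A"]] / (1 + object$data$L / cf[["L50"]])
}

#' @export
residuals.cis_fit <- function(object, ...) {
  if (object$log_residuals) {
    pos <- object$data$avail > 0
    log(object$data$avail[pos]) - log(fitted(object)[pos])
  } else object$data$avail - fitted(object)
}

#' Predicted availability from a cis-inhibition fit
#'
#' @param object a `cis_fit`.
#' @param newdata numeric vector of effective-ligand levels, or a
#'   data.frame with the model-frame ligand column; default: the fitted
#'   data.
#' @param ... unused.
#' @export
predict.cis_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$data$L
  else if (is.numeric(newdata)) newdata
  else newdata[[1L]]
  cf <- object$coefficients
  cf[["bg"]] + cf[["A"]] / (1 + L / cf[["L50"]])
}

#' @export
summary.cis_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$coefficients / object$se)
  structure(list(coefficients = tab, sigma = object$sigma,
                 n = nrow(object$data), identifiable = object$identifiable,
                 notes = object$notes, log_residuals = object$log_residuals),
            class = "summary.cis_fit")
}

#' @export
print.summary.cis_fit <- function(x, ...) {
  cat("Cis-inhibition dose-response fit (single-cell least squares,",
      if (x$log_residuals) "log" else "linear", "residuals)\n\n")
  stats::printCoefmat(x$coefficients, has.Pvalue = FALSE)
  cat(sprintf("\nResidual sd %.4g on %d cells\n", x$sigma, x$n))
  if (!x$identifiable) cat("Flagged:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
plot.cis_fit <- function(x, log = "x", pch = 16, cex = 0.4,
                         col = grDevices::adjustcolor("grey40", 0.5),
                         curve_col = "firebrick", ...) {
  d <- x$data[x$data$L > 0, ]
  graphics::plot(d$L, d$avail, log = log, pch = pch, cex = cex, col = col,
                 xlab = "Effective total ligand (fluorescence)",
                 ylab = "Availability (fluorescence)", ...)
  Lg <- 10^seq(log10(min(d$L)), log10(max(d$L)), length.out = 200)
  graphics::lines(Lg, predict(x, Lg), col = curve_col, lwd = 2)
  graphics::abline(v = x$coefficients[["L50"]], lty = 3, col = curve_col)
  invisible(x)
}

#' Simulate availability data from a fitted cis-inhibition model
#'
#' Draws new availability values at the fitted ligand levels using the
#' fitted curve and the residual spread (log-normal for log-scale fits,
#' Gaussian otherwise).
#'
#' @param object a `cis_fit`.
#' @param nsim number of simulated datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A data.frame with `nsim` columns (`sim_1`, ...), rows matching
#'   the fitted data.
#' @export
simulate.cis_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  with_seed(seed, {
    out <- replicate(nsim, if (object$log_residuals)
      mu * exp(stats::rnorm(length(mu), 0, object$sigma))
    else mu + stats::rnorm(length(mu), 0, object$sigma))
    out <- as.data.frame(out)
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Ratio of half-inhibition levels between two fits
#'
#' Compares cis-inhibition strengths between conditions (e.g. Jag1
#' versus Dll1) as `L50_a / L50_b` on the shared effective-ligand axis; a
#' ratio of 2 means twice as much ligand of condition a is needed to
#' halve availability.  Uncertainty by first-order (delta-method)
#' propagation of the two L50 standard errors.
#'
#' @param fit_a,fit_b identifiable `cis_fit` objects.
#' @return A list with `ratio`, `se`, and the two L50 estimates.
#' @export
half_inhibition_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "cis_fit"), inherits(fit_b, "cis_fit"))
  if (!fit_a$identifiable || !fit_b$identifiable)
    stop("both fits must be identifiable", call. = FALSE)
  la <- fit_a$coefficients[["L50"]]; lb <- fit_b$coefficients[["L50"]]
  sa <- fit_a$se[["L50"]]; sb <- fit_b$se[["L50"]]
  ratio <- la / lb
  list(ratio = ratio,
       se = ratio * sqrt((sa / la)^2 + (sb / lb)^2),
       L50_a = la, L50_b = lb)
}
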