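#' Detect reporter onset time in a dilution trace
#'
#' Onset of Notch activity in the cis-ligand dilution assay: the reporter
#' series is smoothed with a centered moving average, its slope estimated
#' by centered finite differences, and the final slope taken as the mean
#' smoothed slope over the last fraction of frames.  `t_on` is the first
#' time the slope strictly exceeds `threshold_fraction` times the final
#' slope; the ligand fluorescence at `t_on` is reported alongside (the
#' cis-ligand level at which the cell starts responding).  The detector
#' is invariant to rescaling the reporter by any positive constant.
#'
#' @param trace a data.frame with columns `t` (hours, strictly
#'   increasing), `reporter_fluor` and (optionally) `ligand_fluor`; e.g.
#'   one element of [generate_dilution_timecourses()].
#' @param threshold_fraction onset threshold as a fraction of the final
#'   slope, in (0, 1).
#' @param smooth_window moving-average window (frames, odd).
#' @param final_window_frac fraction of trailing frames defining the
#'   final slope.
#' @return A list of class `t_on_result`: `t_on` (hours; `NA` if no
#'   onset), `final_slope`, `threshold_fraction`, `ligand_at_t_on`,
#'   `onset` (logical).  A non-positive final slope yields a flagged
#'   no-onset result.
#' @export
detect_t_on <- function(trace, threshold_fraction = 0.10,
                        smooth_window = 5L, final_window_frac = 0.2) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  t <- trace$t; y <- trace$reporter_fluor
  if (length(t) < 5) stop("need at least 5 frames", call. = FALSE)
  if (any(diff(t) <= 0)) stop("time must be strictly increasing",
                              call. = FALSE)
  k <- as.integer(smooth_window)
  if (k %% 2L == 0L) k <- k + 1L
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  ys <- as.numeric(ys)
  # pad the ends with the nearest smoothed value
  first <- which(!is.na(ys))[1]; last <- max(which(!is.na(ys)))
  ys[seq_len(first - 1L)] <- ys[first]
  if (last < length(ys)) ys[(last + 1L):length(ys)] <- ys[last]
  n <- length(t)
  slope <- rep(NA_real_, n)
  slope[2:(n - 1)] <- (ys[3:n] - ys[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  slope[1] <- slope[2]; slope[n] <- slope[n - 1]
  n_final <- max(3L, ceiling(final_window_frac * n))
  tail_i <- (n - n_final + 1L):n
  # regression slope over the trailing window (immune to the smoothing
  # pad at the series end)
  final_slope <- unname(stats::coef(stats::lm(y[tail_i] ~ t[tail_i]))[2])
  if (!is.finite(final_slope) || final_slope <= 0) {
    return(structure(list(t_on = NA_real_, final_slope = final_slope,
                          threshold_fraction = threshold_fraction,
                          ligand_at_t_on = NA_real_, onset = FALSE),
                     class = "t_on_result"))
  }
  # tiny relative epsilon so a slope exactly at threshold (the marginal
  # smoothing frame of an abrupt onset) does not trigger on rounding
  idx <- which(slope > threshold_fraction * final_slope * (1 + 1e-9))[1]
  if (is.na(idx)) {
    return(structure(list(t_on = NA_real_, final_slope = final_slope,
                          threshold_fraction = threshold_fraction,
                          ligand_at_t_on = NA_real_, onset = FALSE),
                     class = "t_on_result"))
  }
  t_on <- t[idx]
  lig <- if ("ligand_fluor" %in% names(trace)) trace$ligand_fluor[idx]
  else NA_real_
  structure(list(t_on = t_on, final_slope = final_slope,
                 threshold_fraction = threshold_fraction,
                 ligand_at_t_on = lig, onset = TRUE),
            class = "t_on_result")
}

#' @export
print.t_on_result <- function(x, ...) {
  if (x$onset)
    cat(sprintf("Reporter onset t_on = %.2f h (ligand %.4g, final slope %.4g)\n",
                x$t_on, x$ligand_at_t_on, x$final_slope))
  else cat("No reporter onset detected (final slope <= 0 or never crossed)\n")
  invisible(x)
}
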