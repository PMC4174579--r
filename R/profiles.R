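#' Log-binned median profile with bootstrap confidence intervals
#'
#' Groups (x, y) points into bins evenly spaced along log10(x), and
#' reports the per-bin median of y with a percentile-bootstrap confidence
#' interval for the median.  Empty bins are returned with `n = 0` and
#' `NA` statistics; bins with fewer than `n_min` points are flagged.
#'
#' @param x positive values binned on the log scale (e.g. effective total
#'   ligand).
#' @param y values summarised per bin (e.g. availability fluorescence).
#' @param n_bins number of log-spaced bins spanning `range(x)`.
#' @param n_boot bootstrap resamples per bin (`>= 100`).
#' @param level confidence level.
#' @param seed integer seed (the profile is deterministic given it).
#' @param n_min minimum points for a bin to be considered reliable.
#' @return An object of class `binned_profile`: a data.frame with
#'   `bin_lo`, `bin_hi`, `bin_mid` (geometric midpoint), `n`, `median`,
#'   `ci_low`, `ci_high`, `reliable`; bin edges in attribute `edges`.
#' @export
binned_median_profile <- function(x, y, n_bins = 12, n_boot = 1000,
                                  level = 0.95, seed = 1L, n_min = 10) {
  stopifnot(length(x) == length(y), n_boot >= 100, level > 0, level < 1)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (any(x <= 0)) stop("x must be positive for log binning", call. = FALSE)
  edges <- 10^seq(log10(min(x)), log10(max(x)), length.out = n_bins + 1L)
  edges[1] <- edges[1] * (1 - 1e-12)
  edges[n_bins + 1L] <- edges[n_bins + 1L] * (1 + 1e-12)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  alpha <- (1 - level) / 2
  out <- with_seed(seed, {
    rows <- lapply(seq_len(n_bins), function(b) {
      yb <- y[idx == b]
      n <- length(yb)
      if (n == 0)
        return(data.frame(n = 0L, median = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_))
      med <- stats::median(yb)
      if (n == 1) return(data.frame(n = 1L, median = med, ci_low = med,
                                    ci_high = med))
      boot <- vapply(seq_len(n_boot), function(k)
        stats::median(yb[sample.int(n, n, replace = TRUE)]), 0)
      ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
      data.frame(n = n, median = med, ci_low = ci[1], ci_high = ci[2])
    })
    do.call(rbind, rows)
  })
  out <- cbind(data.frame(bin_lo = edges[-(n_bins + 1L)],
                          bin_hi = edges[-1L],
                          bin_mid = sqrt(edges[-(n_bins + 1L)] * edges[-1L])),
               out)
  out$reliable <- out$n >= n_min
  structure(out, edges = edges, level = level,
            class = c("binned_profile", "data.frame"))
}

#' Effective-total-ligand normalization from ligand-only data
#'
#' Different ligands reach the cell surface with different efficiencies,
#' so the same total-ligand fluorescence corresponds to different surface
#' ligand levels.  Following the assay's calibration step, the total
#' ligand versus ligand-availability relation of cells expressing ligand
#' only is fit with a straight line per ligand, and the fitted slopes
#' define a rescaling of each ligand's total-ligand axis ("effective
#' total ligand") that makes the axes comparable across ligands.  The
#' reference ligand gets scale 1; applying the mapping to the reference
#' ligand's own data is the identity up to fit error.
#'
#' @param ligand_only_table availability table (see
#'   [generate_availability_dataset()]) with `assay ==
#'   "ligand_availability"` rows from ligand-only conditions, possibly
#'   several ligands.
#' @param reference ligand whose scale is fixed at 1 (default: first
#'   ligand in the table).
#' @return A list of class `effective_ligand_scale` with `slopes` (named
#'   per-ligand fitted slopes), `scale` (named slope ratios to the
#'   reference) and `reference`.
#' @export
normalize_effective_ligand <- function(ligand_only_table, reference = NULL) {
  tab <- ligand_only_table[ligand_only_table$assay == "ligand_availability", ]
  if (nrow(tab) == 0) stop("no ligand-availability rows", call. = FALSE)
  ligs <- unique(tab$ligand)
  slopes <- vapply(ligs, function(l) {
    d <- tab[tab$ligand == l, ]
    if (nrow(d) < 3)
      stop(sprintf("fewer than 3 ligand-only points for '%s'", l),
           call. = FALSE)
    unname(stats::coef(stats::lm(availability_fluor ~ total_ligand_fluor,
                                 data = d))[2])
  }, 0)
  if (is.null(reference)) reference <- ligs[1]
  if (!reference %in% ligs) stop("reference ligand not in table", call. = FALSE)
  structure(list(slopes = slopes,
                 scale = slopes / slopes[[reference]],
                 reference = reference),
            class = "effective_ligand_scale")
}

#' Apply an effective-ligand scale to an availability table
#'
#' Adds an `effective_ligand` column, `total_ligand_fluor * scale[ligand]`.
#'
#' @param table an availability table.
#' @param scales an `effective_ligand_scale` from
#'   [normalize_effective_ligand()].
#' @return The table with an `effective_ligand` column.
#' @export
apply_effective_ligand <- function(table, scales) {
  stopifnot(inherits(scales, "effective_ligand_scale"))
  miss <- setdiff(unique(table$ligand), names(scales$scale))
  if (length(miss))
    stop("no scale for ligand(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  table$effective_ligand <-
    table$total_ligand_fluor * unname(scales$scale[table$ligand])
  table
}

#' Normalize a binned profile to the uninduced availability level
#'
#' Fringe expression changes the detection gain of the availability
#' reagent, rescaling the whole curve; dividing medians and confidence
#' intervals by the availability measured at uninduced ligand levels
#' removes that gain so curves with and without Fringe are comparable.
#'
#' @param profile a [binned_median_profile()] result.
#' @param uninduced_level positive availability level of uninduced cells.
#' @return The rescaled `binned_profile`.
#' @export
normalize_to_uninduced <- function(profile, uninduced_level) {
  stopifnot(inherits(profile, "binned_profile"))
  stop_if_not_scalar_pos(uninduced_level, "uninduced_level")
  for (col in c("median", "ci_low", "ci_high"))
    profile[[col]] <- profile[[col]] / uninduced_level
  profile
}

#' Per-bin Wilcoxon rank-sum comparison of two availability tables
#'
#' Bins both tables on shared log-spaced bin edges along the x variable
#' and applies a two-sided Wilcoxon rank-sum test to the y values of each
#' bin with at least `n_min` points in both tables.  No multiple-testing
#' correction is applied by default (each bin is starred on its own
#' p-value); Benjamini-Hochberg is available via `p_adjust = "BH"`.
#'
#' @param table_a,table_b data.frames with the columns named by `xvar`
#'   and `yvar`.
#' @param bins number of bins, or a numeric vector of shared bin edges.
#' @param xvar,yvar column names for the binning axis and the compared
#'   values.
#' @param n_min minimum per-table bin occupancy for testing.
#' @param alpha significance level for flagging.
#' @param p_adjust `"none"` or any method of [stats::p.adjust()].
#' @return A data.frame with `bin_lo`, `bin_hi`, `bin_mid`, `n_a`, `n_b`,
#'   `p`, `p_adj`, `significant` (NA p for untested bins, excluded from
#'   flags).
#' @export
compare_conditions <- function(table_a, table_b, bins = 12,
                               xvar = "total_ligand_fluor",
                               yvar = "availability_fluor",
                               n_min = 10, alpha = 0.05,
                               p_adjust = "none") {
  xa <- table_a[[xvar]]; ya <- table_a[[yvar]]
  xb <- table_b[[xvar]]; yb <- table_b[[yvar]]
  ok_a <- is.finite(xa) & xa > 0; ok_b <- is.finite(xb) & xb > 0
  xa <- xa[ok_a]; ya <- ya[ok_a]; xb <- xb[ok_b]; yb <- yb[ok_b]
  if (length(bins) == 1L) {
    rng <- range(c(xa, xb))
    edges <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = bins + 1L)
    edges[1] <- edges[1] * (1 - 1e-12)
    edges[length(edges)] <- edges[length(edges)] * (1 + 1e-12)
  } else edges <- bins
  nb <- length(edges) - 1L
  ia <- findInterval(xa, edges, rightmost.closed = TRUE)
  ib <- findInterval(xb, edges, rightmost.closed = TRUE)
  p <- rep(NA_real_, nb)
  n_a <- n_b <- integer(nb)
  for (b in seq_len(nb)) {
    va <- ya[ia == b]; vb <- yb[ib == b]
    n_a[b] <- length(va); n_b[b] <- length(vb)
    if (n_a[b] >= n_min && n_b[b] >= n_min)
      p[b] <- stats::wilcox.test(va, vb, exact = FALSE)$p.value
  }
  p_adj <- p
  tested <- !is.na(p)
  if (!identical(p_adjust, "none"))
    p_adj[tested] <- stats::p.adjust(p[tested], method = p_adjust)
  data.frame(bin_lo = edges[-(nb + 1L)], bin_hi = edges[-1L],
             bin_mid = sqrt(edges[-(nb + 1L)] * edges[-1L]),
             n_a = n_a, n_b = n_b, p = p, p_adj = p_adj,
             significant = !is.na(p_adj) & p_adj < alpha)
}
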