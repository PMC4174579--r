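#' Configuration of the synthetic availability-assay generator
#'
#' Describes the generative model the synthetic single-cell data follow:
#' a saturating Hill dose-response maps inducer (4-epiTc) dose to the
#' median total-ligand fluorescence per induction level, cells scatter
#' log-normally around that median, a per-ligand surface efficiency maps
#' total-ligand fluorescence to surface ligand in model units, the
#' cis-inhibition steady state determines free receptor and ligand, and
#' measurement adds multiplicative log-normal noise plus additive Gaussian
#' background (clipped at zero).
#'
#' @param n_cells_per_level cells per induction level.
#' @param induction_levels 4-epiTc doses (ng/ml).
#' @param expression_model list with `basal`, `vmax` (fluorescence units),
#'   `ec50` (ng/ml), `hill`, `sigma` (natural-log spread of cells around
#'   the level median).
#' @param surface_efficiency named vector, ligand -> model units of
#'   surface ligand per unit total-ligand fluorescence.
#' @param noise_cv multiplicative measurement noise CV.
#' @param background_mean,background_sd additive availability background
#'   (fluorescence units).
#' @param gain fluorescence units per model unit of free receptor/ligand.
#' @param seed integer seed making every generated table reproducible.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_cells_per_level = 250,
                             induction_levels = c(0, 2, 5, 10, 25, 50, 100, 200),
                             expression_model = list(basal = 20, vmax = 10000,
                                                     ec50 = 25, hill = 2,
                                                     sigma = 0.5),
                             surface_efficiency = c(Dll1 = 1e-3, Jag1 = 2e-3),
                             noise_cv = 0.1,
                             background_mean = 100, background_sd = 20,
                             gain = 20000,
                             seed = 1L) {
  stopifnot(n_cells_per_level >= 1, length(induction_levels) >= 1,
            expression_model$sigma >= 0, noise_cv >= 0, gain > 0,
            all(surface_efficiency > 0))
  structure(list(n_cells_per_level = as.integer(n_cells_per_level),
                 induction_levels = induction_levels,
                 expression_model = expression_model,
                 surface_efficiency = surface_efficiency,
                 noise_cv = noise_cv,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 gain = gain, seed = seed),
            class = "generator_config")
}

hill_median <- function(dose, em) {
  em$basal + em$vmax * dose^em$hill / (dose^em$hill + em$ec50^em$hill)
}

#' Generate a synthetic per-cell availability table
#'
#' Emulates the availability assay: ligand expression is induced across
#' the configured dose levels, cells scatter log-normally, and the
#' measured availability fluorescence follows the cis-inhibition steady
#' state of the (Fringe-modified) kinetic model plus measurement noise and
#' background.  For `assay = "receptor_availability"` the signal reports
#' free Notch scaled by `gain * detection_gain`; for
#' `"ligand_availability"` it reports free ligand scaled by `gain` (the
#' detection-gain change is a property of the Notch-binding reagent only).
#' A ligand-only condition (no receptor) is obtained with `beta_N = 0` in
#' `params`.
#'
#' @param config a [generator_config()].
#' @param params a [kinetic_params()] object; `beta_D` is ignored (ligand
#'   production is set per cell from the expression model).
#' @param fringe a [fringe_config()].
#' @param ligand ligand expressed in cis (must index
#'   `config$surface_efficiency` and the fringe factor maps).
#' @param assay which availability reagent is emulated.
#' @param seed optional override of `config$seed`.
#' @return A data.frame with columns `cell_id`, `ligand`, `fringe`,
#'   `assay`, `dose`, `total_ligand_fluor`, `availability_fluor`, `area`,
#'   `is_isolated`.
#' @export
generate_availability_dataset <- function(config, params,
                                          fringe = fringe_config(),
                                          ligand = "Dll1",
                                          assay = c("receptor_availability",
                                                    "ligand_availability"),
                                          seed = NULL) {
  stopifnot(inherits(config, "generator_config"),
            inherits(params, "kinetic_params"),
            inherits(fringe, "fringe_config"))
  assay <- match.arg(assay)
  if (length(config$induction_levels) == 0)
    stop("induction_levels is empty", call. = FALSE)
  if (!ligand %in% names(config$surface_efficiency))
    stop(sprintf("no surface efficiency configured for ligand '%s'", ligand),
         call. = FALSE)
  if (is.null(seed)) seed <- config$seed
  pf <- apply_fringe(params, fringe, ligand)
  kc <- kc_of(pf)
  eff <- config$surface_efficiency[[ligand]]
  em <- config$expression_model

  with_seed(seed, {
    dose <- rep(config$induction_levels, each = config$n_cells_per_level)
    n <- length(dose)
    total <- hill_median(dose, em) * exp(stats::rnorm(n, 0, em$sigma))
    d0 <- eff * total                       # unopposed surface ligand
    if (params$beta_N > 0) {
      ss <- steady_state_single(params$beta_N, params$gamma_N,
                                d0 * params$gamma_D, params$gamma_D, kc)
      N_free <- ss$N; D_free <- ss$D
    } else {
      N_free <- rep(0, n); D_free <- d0
    }
    signal <- if (assay == "receptor_availability")
      config$gain * fringe$detection_gain * N_free
    else config$gain * D_free
    avail <- signal * rlnorm_cv(n, config$noise_cv) +
      stats::rnorm(n, config$background_mean, config$background_sd)
    area <- pmax(50, stats::rnorm(n, 500, 80))
    data.frame(cell_id = seq_len(n),
               ligand = ligand,
               fringe = fringe$identity,
               assay = assay,
               dose = dose,
               total_ligand_fluor = pmax(0, total),
               availability_fluor = pmax(0, avail),
               area = area,
               is_isolated = stats::runif(n) > 0.05,
               stringsAsFactors = FALSE)
  })
}

#' Half-inhibition level implied by a generator configuration
#'
#' Total-ligand fluorescence at which the noise-free availability signal
#' drops to half of its uninduced value under the generating model.  From
#' the steady-state algebra, free Notch is halved when free ligand equals
#' `kc*gamma_N`, which corresponds to an unopposed surface-ligand level
#' `kc*gamma_N * (1 + beta_N / (2*gamma_N*kc*gamma_D))` and hence to a
#' total fluorescence of that divided by the surface efficiency.  This is
#' the ground truth for generate-and-fit recovery checks.
#'
#' @inheritParams generate_availability_dataset
#' @return Total-ligand fluorescence at half inhibition (scalar).
#' @export
generating_half_inhibition <- function(config, params,
                                       fringe = fringe_config(),
                                       ligand = "Dll1") {
  pf <- apply_fringe(params, fringe, ligand)
  kc <- kc_of(pf)
  d0_half <- kc * params$gamma_N *
    (1 + params$beta_N / (2 * params$gamma_N * kc * params$gamma_D))
  d0_half / config$surface_efficiency[[ligand]]
}

#' Generate a saturation-binding calibration dataset
#'
#' Emulates titration of the soluble availability reagent: the noise-free
#' signal follows `a * D / (D + K)` and each replicate carries
#' multiplicative log-normal noise.
#'
#' @param a plateau signal (fluorescence units), `> 0`.
#' @param K half-saturation concentration (ug/ml), `> 0`.
#' @param concentrations reagent concentrations (ug/ml), `>= 0`.
#' @param replicates replicates per concentration.
#' @param noise_cv multiplicative noise CV.
#' @param seed integer seed.
#' @return A data.frame with columns `concentration`, `replicate`,
#'   `signal`.
#' @export
generate_calibration_dataset <- function(a, K, concentrations,
                                         replicates = 2, noise_cv = 0.1,
                                         seed = 1L) {
  stop_if_not_scalar_pos(a, "a")
  stop_if_not_scalar_pos(K, "K")
  if (any(concentrations < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  with_seed(seed, {
    conc <- rep(concentrations, each = replicates)
    mu <- a * conc / (conc + K)
    data.frame(concentration = conc,
               replicate = rep(seq_len(replicates),
                               times = length(concentrations)),
               signal = mu * rlnorm_cv(length(conc), noise_cv))
  })
}

#' Configuration of the dilution time-lapse generator
#'
#' Describes the cis-ligand dilution assay: cells pre-induced to high
#' ligand levels are seeded on ligand-coated plates; after washout at
#' `t = 0`, cis-ligand decays by dilution through division (half per
#' division period) plus degradation, the free receptor tracks the cis
#' steady state, and the Notch reporter accumulates at the trans signal
#' rate from the plate-bound ligand.
#'
#' @param ligand cis-ligand species expressed by the cells.
#' @param plate_ligand species coated on the plate.
#' @param division_period hours per cell division (ligand halves each
#'   division).
#' @param frame_interval hours between frames.
#' @param t_end hours of imaging after washout.
#' @param L0_median,L0_sigma median and natural-log spread of the
#'   pre-induced cis-ligand level (model units) at washout.
#' @param noise_cv multiplicative measurement noise per frame.
#' @param gain,reporter_gain fluorescence units per model unit for the
#'   ligand and reporter channels.
#' @return A list of class `dilution_config`.
#' @export
dilution_config <- function(ligand = "Jag1", plate_ligand = "Dll1",
                            division_period = 18, frame_interval = 1 / 3,
                            t_end = 60, L0_median = 25, L0_sigma = 0.3,
                            noise_cv = 0.05, gain = 2000,
                            reporter_gain = 2000) {
  stopifnot(division_period > 0, frame_interval > 0, t_end > frame_interval,
            L0_median > 0, L0_sigma >= 0, noise_cv >= 0)
  structure(list(ligand = ligand, plate_ligand = plate_ligand,
                 division_period = division_period,
                 frame_interval = frame_interval, t_end = t_end,
                 L0_median = L0_median, L0_sigma = L0_sigma,
                 noise_cv = noise_cv, gain = gain,
                 reporter_gain = reporter_gain),
            class = "dilution_config")
}

#' Generate synthetic cis-ligand dilution time courses
#'
#' For each cell: `L(t) = L0 * exp(-(ln 2 / division_period + gamma_D) t)`
#' after washout, free Notch follows the quasi-steady-state dose response
#' at the current ligand level (with the cell's Fringe modifying the cis
#' strength for its ligand), and the reporter integrates
#' `trans_signal_rate(N(t), plate_ligand_density)` with the receiver's
#' Fringe modifying the trans rate for the plate ligand.  Fluorescence
#' traces carry per-frame multiplicative noise.
#'
#' @param config a [dilution_config()].
#' @param params a [kinetic_params()] object.
#' @param fringe a [fringe_config()]; factor maps must cover both the cis
#'   and the plate ligand.
#' @param plate_ligand_density plate-bound ligand level (model units).
#' @param n_cells number of cells (traces).
#' @param seed integer seed.
#' @return A list of data.frames (`t` hours, `ligand_fluor`,
#'   `reporter_fluor`), each of class `dilution_trace` with attributes
#'   `division_period` and `L0`.
#' @export
generate_dilution_timecourses <- function(config, params,
                                          fringe = fringe_config(),
                                          plate_ligand_density = 1,
                                          n_cells = 30, seed = 1L) {
  stopifnot(inherits(config, "dilution_config"),
            inherits(params, "kinetic_params"),
            inherits(fringe, "fringe_config"),
            plate_ligand_density >= 0, n_cells >= 1)
  p_cis <- apply_fringe(params, fringe, config$ligand)
  p_trans <- apply_fringe(params, fringe, config$plate_ligand)
  kc <- kc_of(p_cis)
  tt <- seq(0, config$t_end, by = config$frame_interval)
  rate <- log(2) / config$division_period + params$gamma_D
  with_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      L0 <- config$L0_median * exp(stats::rnorm(1, 0, config$L0_sigma))
      L <- L0 * exp(-rate * tt)
      N <- qss_available_notch(L, params$beta_N, params$gamma_N, kc)
      r <- trans_signal_rate(N, plate_ligand_density, p_trans)
      # cumulative trapezoid of the signal rate
      S <- c(0, cumsum((r[-1] + r[-length(r)]) / 2 * diff(tt)))
      tr <- data.frame(
        t = tt,
        ligand_fluor = config$gain * L * rlnorm_cv(length(tt), config$noise_cv),
        reporter_fluor = config$reporter_gain * S *
          rlnorm_cv(length(tt), config$noise_cv))
      structure(tr, class = c("dilution_trace", "data.frame"),
                division_period = config$division_period, L0 = L0)
    })
  })
}

#' Random non-overlapping cell layout for synthetic images
#'
#' Places circular cells by rejection sampling so that no two cells are
#' closer than `min_gap` (edge to edge) and none touches the image border.
#'
#' @param n number of cells to place.
#' @param image_shape `c(height, width)` in pixels.
#' @param radius_range min/max cell radius (pixels).
#' @param min_gap minimum edge-to-edge separation (pixels); negative
#'   values allow overlap.
#' @param seed integer seed.
#' @return A data.frame with columns `x`, `y`, `r`.
#' @export
sample_cell_layout <- function(n, image_shape = c(400, 400),
                               radius_range = c(8, 12), min_gap = 6,
                               seed = 1L) {
  with_seed(seed, {
    xs <- ys <- rs <- numeric(0)
    tries <- 0L
    while (length(xs) < n && tries < 20000L) {
      tries <- tries + 1L
      r <- stats::runif(1, radius_range[1], radius_range[2])
      x <- stats::runif(1, r + 2, image_shape[2] - r - 2)
      y <- stats::runif(1, r + 2, image_shape[1] - r - 2)
      if (length(xs) == 0 ||
          all(sqrt((xs - x)^2 + (ys - y)^2) > rs + r + min_gap)) {
        xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
      }
    }
    if (length(xs) < n)
      stop("could not place all cells; reduce n or min_gap", call. = FALSE)
    data.frame(x = xs, y = ys, r = rs)
  })
}

#' Render a synthetic multi-channel field with ground truth
#'
#' Each cell is a soft-edged disk (linear intensity roll-off over
#' `edge_width` pixels around its radius) added to every channel at its
#' per-cell intensity, on top of an additive background (constant or
#' linear gradient) and Gaussian read noise.  The pixel-exact label mask
#' assigns each pixel within a cell radius to that cell; pixels claimed by
#' two cells flag both as overlapping in the ground truth.
#'
#' @param cells data.frame with columns `x`, `y`, `r` and one column per
#'   channel intensity (e.g. `cyto`, `ligand`, `avail`).
#' @param image_shape `c(height, width)` pixels.
#' @param background_model list; `list(type = "constant", value = v)` or
#'   `list(type = "gradient", from = a, to = b, axis = "x"|"y")`.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param edge_width soft-edge width in pixels.
#' @param seed integer seed (read noise only).
#' @return A list with `image` (array height x width x channel, named),
#'   `mask` (integer label matrix, 0 = background) and `truth` (data.frame
#'   with `cell_id`, `x`, `y`, `r`, `area`, `overlaps`, and the realized
#'   in-mask mean signal `mean_<channel>` for every channel).
#' @export
render_synthetic_field <- function(cells, image_shape = c(400, 400),
                                   background_model = list(type = "constant",
                                                           value = 10),
                                   noise_sd = 0, edge_width = 1.5,
                                   seed = 1L) {
  stopifnot(is.data.frame(cells), all(c("x", "y", "r") %in% names(cells)),
            all(cells$r > 0))
  if (any(cells$x < 1 | cells$x > image_shape[2] |
          cells$y < 1 | cells$y > image_shape[1]))
    stop("cell centers must lie within the image", call. = FALSE)
  channels <- setdiff(names(cells), c("x", "y", "r"))
  if (length(channels) == 0) stop("no channel intensity columns", call. = FALSE)
  H <- image_shape[1]; W <- image_shape[2]
  img <- array(0, dim = c(H, W, length(channels)),
               dimnames = list(NULL, NULL, channels))
  mask <- matrix(0L, H, W)
  overlaps <- logical(nrow(cells))
  mean_sig <- matrix(NA_real_, nrow(cells), length(channels),
                     dimnames = list(NULL, channels))
  area <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- cells$r[i]
    rows <- max(1, floor(cells$y[i] - r - edge_width)):
      min(H, ceiling(cells$y[i] + r + edge_width))
    cols <- max(1, floor(cells$x[i] - r - edge_width)):
      min(W, ceiling(cells$x[i] + r + edge_width))
    d <- sqrt(outer((rows - cells$y[i])^2, (cols - cells$x[i])^2, "+"))
    w <- pmin(1, pmax(0, (r + edge_width / 2 - d) / edge_width))
    inside <- d <= r                      # ground-truth mask: w >= 1/2
    for (ch in channels)
      img[rows, cols, ch] <- img[rows, cols, ch] + cells[[ch]][i] * w
    prev <- mask[rows, cols]
    clash <- inside & prev > 0
    if (any(clash)) {
      overlaps[i] <- TRUE
      overlaps[unique(prev[clash])] <- TRUE
    }
    mask[rows, cols][inside] <- i
    area[i] <- sum(inside)
    for (ch in channels)
      mean_sig[i, ch] <- cells[[ch]][i] * mean(w[inside])
  }
  bg <- switch(background_model$type,
    constant = matrix(background_model$value, H, W),
    gradient = {
      ax <- if (is.null(background_model$axis)) "x" else background_model$axis
      ramp <- seq(background_model$from, background_model$to,
                  length.out = if (ax == "x") W else H)
      if (ax == "x") matrix(ramp, H, W, byrow = TRUE) else matrix(ramp, H, W)
    },
    stop("unknown background type", call. = FALSE))
  with_seed(seed, {
    for (ch in channels) {
      noise <- if (noise_sd > 0) matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
      else 0
      img[, , ch] <- img[, , ch] + bg + noise
    }
  })
  truth <- data.frame(cell_id = seq_len(nrow(cells)),
                      x = cells$x, y = cells$y, r = cells$r,
                      area = area, overlaps = overlaps)
  for (ch in channels) truth[[paste0("mean_", ch)]] <- mean_sig[, ch]
  list(image = img, mask = mask, truth = truth)
}

#' Default kinetic parameters of the synthetic availability scenario
#'
#' The study condition used throughout the generate-and-fit checks: unit
#' production and degradation for receptor and ligand, and cis rates
#' giving a lumped cis strength `kc = 5` (so half-depletion of available
#' Notch at a free-ligand level of 5 model units, i.e. an unopposed
#' surface-ligand level of 5.5 units, mid-range of the induced expression
#' spread).  `cis_strength_factor` rescales the cis association rate, e.g.
#' `0.5` halves the cis strength (doubles `kc`), the condition used for
#' the Jag1-versus-Dll1 comparison.
#'
#' @param cis_strength_factor multiplicative factor on `kC_plus`.
#' @return A [kinetic_params()] object.
#' @export
assay_kinetic_params <- function(cis_strength_factor = 1) {
  kinetic_params(kC_plus = 0.4 * cis_strength_factor, kC_minus = 10, kI = 10)
}

#' Default kinetic parameters of the dilution time-lapse scenario
#'
#' Study condition for the cis-ligand dilution assay: strong cis
#' interaction (`kc = 0.5`, so pre-induced ligand at ~25 model units
#' suppresses available Notch ~50-fold at washout) and slow ligand
#' protein turnover (`gamma_D = 0.02`/h, smaller than the dilution rate
#' `ln 2 / 18 h`, so cis-ligand loss is dominated by division dilution).
#'
#' @return A [kinetic_params()] object.
#' @export
dilution_kinetic_params <- function() {
  kinetic_params(gamma_D = 0.02, kC_plus = 4, kC_minus = 10, kI = 10)
}
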