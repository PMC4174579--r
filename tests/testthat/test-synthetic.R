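test_that("availability generator is reproducible and validates input", {
  cfg <- generator_config(n_cells_per_level = 20)
  p <- assay_kinetic_params()
  a <- generate_availability_dataset(cfg, p, seed = 5)
  b <- generate_availability_dataset(cfg, p, seed = 5)
  expect_identical(a, b)
  c <- generate_availability_dataset(cfg, p, seed = 6)
  expect_false(identical(a$availability_fluor, c$availability_fluor))
  bad <- cfg; bad$induction_levels <- numeric(0)
  expect_error(generate_availability_dataset(bad, p), "empty")
  expect_error(generate_availability_dataset(cfg, p, ligand = "DeltaD"),
               "surface efficiency")
})

test_that("noise-free generated availability equals the model prediction", {
  em <- list(basal = 0, vmax = 10000, ec50 = 25, hill = 2, sigma = 0)
  cfg <- generator_config(n_cells_per_level = 3, induction_levels = 0,
                          expression_model = em, noise_cv = 0,
                          background_mean = 0, background_sd = 0)
  p <- assay_kinetic_params()
  fr <- fringe_preset("lfng")
  tab <- generate_availability_dataset(cfg, p, fringe = fr, seed = 1)
  expect_equal(tab$availability_fluor,
               rep(cfg$gain * fr$detection_gain * p$beta_N / p$gamma_N, 3))
  # with induced expression, the gain-scaled steady state is returned exactly
  cfg2 <- generator_config(n_cells_per_level = 1,
                           induction_levels = c(0, 50, 200),
                           expression_model = em, noise_cv = 0,
                           background_mean = 0, background_sd = 0)
  tab2 <- generate_availability_dataset(cfg2, p, seed = 1)
  d0 <- cfg2$surface_efficiency[["Dll1"]] * tab2$total_ligand_fluor
  pred <- vapply(d0, function(d) {
    pp <- p; pp$beta_D <- d * p$gamma_D
    solve_cis_steady_state(do.call(kinetic_params, unclass(pp)))$N
  }, 0)
  expect_equal(tab2$availability_fluor, cfg2$gain * pred, tolerance = 1e-10)
})

test_that("ligand-only tables report free ligand scaled by efficiency", {
  em <- list(basal = 100, vmax = 5000, ec50 = 25, hill = 2, sigma = 0.3)
  cfg <- generator_config(n_cells_per_level = 50, expression_model = em,
                          noise_cv = 0, background_mean = 0,
                          background_sd = 0)
  p0 <- kinetic_params(beta_N = 0, kC_plus = 0.4, kC_minus = 10, kI = 10)
  tab <- generate_availability_dataset(cfg, p0, ligand = "Jag1",
                                       assay = "ligand_availability",
                                       seed = 2)
  expect_equal(tab$availability_fluor,
               cfg$gain * cfg$surface_efficiency[["Jag1"]] *
                 tab$total_ligand_fluor)
})

test_that("calibration generator follows the binding isotherm", {
  d <- generate_calibration_dataset(100, 2, c(0, 2, 10), replicates = 2,
                                    noise_cv = 0, seed = 1)
  expect_equal(d$signal[d$concentration == 0], c(0, 0))
  expect_equal(d$signal[d$concentration == 2], c(50, 50))
  expect_equal(nrow(d), 6)
  expect_identical(generate_calibration_dataset(100, 2, 1:3, seed = 9),
                   generate_calibration_dataset(100, 2, 1:3, seed = 9))
  expect_error(generate_calibration_dataset(100, 2, c(-1, 1)),
               "non-negative")
})

test_that("dilution traces follow washout kinetics", {
  p <- dilution_kinetic_params()
  dc <- dilution_config(t_end = 20, noise_cv = 0)
  # no plate ligand: reporter never accumulates
  tr0 <- generate_dilution_timecourses(dc, p, plate_ligand_density = 0,
                                       n_cells = 2, seed = 1)
  expect_true(all(tr0[[1]]$reporter_fluor == 0))
  # no degradation, effectively no divisions: ligand stays constant
  pstable <- kinetic_params(gamma_D = 1e-12, kC_plus = 4, kC_minus = 10,
                            kI = 10)
  dc2 <- dilution_config(division_period = 1e12, t_end = 20, noise_cv = 0)
  tr <- generate_dilution_timecourses(dc2, pstable, plate_ligand_density = 1,
                                      n_cells = 1, seed = 1)
  expect_lt(diff(range(tr[[1]]$ligand_fluor)) /
              mean(tr[[1]]$ligand_fluor), 1e-8)
  # ligand decays at ln2/period + gamma_D
  tr2 <- generate_dilution_timecourses(dc, p, plate_ligand_density = 1,
                                       n_cells = 1, seed = 3)
  lf <- tr2[[1]]$ligand_fluor
  rate_hat <- -coef(lm(log(lf) ~ tr2[[1]]$t))[[2]]
  expect_equal(rate_hat, log(2) / dc$division_period + p$gamma_D,
               tolerance = 1e-6)
})

test_that("rendered fields carry exact ground truth", {
  cells <- data.frame(x = 30, y = 40, r = 10, cyto = 100, avail = 80)
  fld <- render_synthetic_field(cells, c(80, 80),
                                background_model = list(type = "constant",
                                                        value = 0),
                                noise_sd = 0, seed = 1)
  inmask <- fld$image[, , "avail"][fld$mask == 1]
  expect_equal(mean(inmask), fld$truth$mean_avail[1])
  expect_equal(max(fld$mask), 1)
  # two disjoint cells -> two labels, no overlap flags
  cells2 <- rbind(cells, data.frame(x = 60, y = 60, r = 8, cyto = 100,
                                    avail = 120))
  fld2 <- render_synthetic_field(cells2, c(80, 80), noise_sd = 0, seed = 1)
  expect_equal(sort(unique(as.vector(fld2$mask))), 0:2)
  expect_false(any(fld2$truth$overlaps))
  # overlapping cells are flagged, not dropped
  cells3 <- rbind(cells, data.frame(x = 38, y = 42, r = 10, cyto = 100,
                                    avail = 90))
  fld3 <- render_synthetic_field(cells3, c(80, 80), noise_sd = 0, seed = 1)
  expect_true(all(fld3$truth$overlaps))
  expect_error(render_synthetic_field(
    data.frame(x = 500, y = 5, r = 4, cyto = 1), c(80, 80)), "within")
})

test_that("renders are bit-reproducible for a fixed seed", {
  cells <- sample_cell_layout(5, c(100, 100), seed = 3)
  cells$cyto <- 100
  a <- render_synthetic_field(cells, c(100, 100), noise_sd = 4, seed = 9)
  b <- render_synthetic_field(cells, c(100, 100), noise_sd = 4, seed = 9)
  expect_identical(a$image, b$image)
  expect_identical(sample_cell_layout(8, seed = 2),
                   sample_cell_layout(8, seed = 2))
})
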