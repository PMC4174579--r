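test_that("binned profiles handle degenerate bins", {
  x <- 10^runif(300, 0, 3)
  pr <- binned_median_profile(x, rep(4.2, 300), n_bins = 6, seed = 1)
  expect_true(all(pr$median[pr$n > 0] == 4.2))
  expect_true(all(pr$ci_low[pr$n > 0] == 4.2 & pr$ci_high[pr$n > 0] == 4.2))
  # one point per bin: median and CI collapse to the point
  xs <- c(1, 10, 100); ys <- c(5, 7, 9)
  pr1 <- binned_median_profile(xs, ys, n_bins = 3, seed = 1)
  expect_equal(pr1$median[pr1$n == 1], ys)
  expect_equal(pr1$ci_low[pr1$n == 1], ys)
  expect_error(binned_median_profile(c(0, 1), c(1, 2)), "positive")
  yy <- rnorm(300)
  expect_identical(binned_median_profile(x, yy, seed = 3),
                   binned_median_profile(x, yy, seed = 3))
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  set.seed(5)
  width_at <- vapply(c(50, 200, 800), function(n) {
    w <- vapply(1:12, function(i) {
      pr <- binned_median_profile(exp(runif(n, 0, 1)), rnorm(n, 10, 2),
                                  n_bins = 1, n_boot = 400, seed = i)
      pr$ci_high[1] - pr$ci_low[1]
    }, 0)
    mean(w)
  }, 0)
  expect_gt(width_at[1] / width_at[2], 1.4)   # ~2 expected
  expect_gt(width_at[2] / width_at[3], 1.4)
  expect_lt(width_at[1] / width_at[3], 8)     # ~4 expected
})

test_that("effective-ligand scales recover surface-efficiency ratios", {
  # perfectly linear ligand-only data: scale equals the slope ratio
  tab <- data.frame(ligand = rep(c("A", "B"), each = 10),
                    assay = "ligand_availability",
                    total_ligand_fluor = rep(1:10, 2),
                    availability_fluor = c(3 * (1:10), 6 * (1:10)))
  sc <- normalize_effective_ligand(tab, reference = "A")
  expect_equal(unname(sc$scale), c(1, 2))
  expect_equal(unname(sc$slopes), c(3, 6))
  et <- apply_effective_ligand(tab, sc)
  expect_equal(et$effective_ligand,
               tab$total_ligand_fluor * rep(c(1, 2), each = 10))
  expect_error(normalize_effective_ligand(
    data.frame(ligand = "A", assay = "ligand_availability",
               total_ligand_fluor = 1:2, availability_fluor = 1:2)),
    "fewer than 3")
  # generator round trip: efficiencies 1e-3 vs 2e-3 -> ratio 2 +/- 10%
  cfg <- generator_config(n_cells_per_level = 100)
  p0 <- kinetic_params(beta_N = 0, kC_plus = 0.4, kC_minus = 10, kI = 10)
  tD <- generate_availability_dataset(cfg, p0, ligand = "Dll1",
                                      assay = "ligand_availability", seed = 1)
  tJ <- generate_availability_dataset(cfg, p0, ligand = "Jag1",
                                      assay = "ligand_availability", seed = 2)
  sc2 <- normalize_effective_ligand(rbind(tD, tJ), reference = "Dll1")
  expect_equal(sc2$scale[["Jag1"]], 2, tolerance = 0.1)
})

test_that("effective-ligand scale is unbiased under measurement noise", {
  cfg <- generator_config(n_cells_per_level = 40)
  p0 <- kinetic_params(beta_N = 0, kC_plus = 0.4, kC_minus = 10, kI = 10)
  ratios <- vapply(1:50, function(s) {
    tD <- generate_availability_dataset(cfg, p0, ligand = "Dll1",
                                        assay = "ligand_availability",
                                        seed = 2 * s)
    tJ <- generate_availability_dataset(cfg, p0, ligand = "Jag1",
                                        assay = "ligand_availability",
                                        seed = 2 * s + 1)
    normalize_effective_ligand(rbind(tD, tJ), "Dll1")$scale[["Jag1"]]
  }, 0)
  expect_equal(mean(ratios), 2, tolerance = 0.03)
})

test_that("uninduced normalization rescales profiles and cancels detection gain", {
  x <- 10^runif(400, 0, 2)
  pr <- binned_median_profile(x, rep(6, 400), n_bins = 4, seed = 1)
  nm <- normalize_to_uninduced(pr, 6)
  expect_true(all(nm$median[nm$n > 0] == 1))
  # ratios between bins are preserved under the scalar division
  pr2 <- binned_median_profile(x, x, n_bins = 4, seed = 1)
  nm2 <- normalize_to_uninduced(pr2, 3)
  ok <- pr2$n > 0
  expect_equal(nm2$median[ok] / nm2$median[ok][1],
               pr2$median[ok] / pr2$median[ok][1])
  expect_error(normalize_to_uninduced(pr, 0), "positive")
  # generator round trip: doubling detection gain leaves the normalized
  # curve unchanged (noise-free)
  em <- list(basal = 50, vmax = 8000, ec50 = 25, hill = 2, sigma = 0.4)
  cfg <- generator_config(n_cells_per_level = 60, expression_model = em,
                          noise_cv = 0, background_mean = 0,
                          background_sd = 0)
  p <- assay_kinetic_params()
  f1 <- fringe_config("g1", c(Dll1 = 1, Jag1 = 1), c(Dll1 = 1, Jag1 = 1), 1.0)
  f2 <- fringe_config("g2", c(Dll1 = 1, Jag1 = 1), c(Dll1 = 1, Jag1 = 1), 2.0)
  t1 <- generate_availability_dataset(cfg, p, fringe = f1, seed = 4)
  t2 <- generate_availability_dataset(cfg, p, fringe = f2, seed = 4)
  un1 <- median(t1$availability_fluor[t1$dose == 0])
  un2 <- median(t2$availability_fluor[t2$dose == 0])
  pr1 <- normalize_to_uninduced(
    binned_median_profile(t1$total_ligand_fluor, t1$availability_fluor,
                          seed = 1), un1)
  pr2n <- normalize_to_uninduced(
    binned_median_profile(t2$total_ligand_fluor, t2$availability_fluor,
                          seed = 1), un2)
  expect_equal(pr1$median, pr2n$median, tolerance = 1e-10)
})

test_that("saturation fits recover generating parameters", {
  D <- c(0.2, 0.5, 1, 2, 5, 10)
  f <- fit_saturation(D, 3 * D / (D + 1.5))
  expect_equal(unname(coef(f)), c(3, 1.5), tolerance = 1e-6)
  expect_true(f$identifiable)
  expect_error(fit_saturation(D, rep(0, 6)), "zero")
  expect_error(fit_saturation(c(1, 1, 1), c(1, 2, 3)), "distinct")
  # all concentrations far above K: flagged unidentifiable
  expect_warning(fu <- fit_saturation(c(100, 300, 1000),
                                      3 * c(100, 300, 1000) /
                                        (c(100, 300, 1000) + 0.01)),
                 "not identified")
  expect_false(fu$identifiable)
})

test_that("cis-inhibition fit recovers noise-free parameters exactly", {
  L <- 10^seq(0, 4, length.out = 60)
  y <- 5 + 200 / (1 + L / 300)
  f <- fit_cis_inhibition(L, y)
  expect_equal(unname(coef(f)), c(200, 300, 5), tolerance = 1e-5)
  expect_true(f$identifiable)
  expect_equal(predict(f, 300), 5 + 100)
  expect_equal(length(residuals(f)), 60)
  # flat data: flagged unidentifiable
  expect_warning(ff <- fit_cis_inhibition(L, rep(50, 60)), "flagged")
  expect_false(ff$identifiable)
})

test_that("cis fit methods are coherent", {
  cfg <- generator_config(n_cells_per_level = 60)
  p <- assay_kinetic_params()
  tab <- generate_availability_dataset(cfg, p, seed = 8)
  f <- fit_cis_inhibition(availability_fluor ~ total_ligand_fluor,
                          data = tab)
  expect_s3_class(f, "cis_fit")
  expect_named(coef(f), c("A", "L50", "bg"))
  s <- summary(f)
  expect_equal(s$coefficients[, "Estimate"], coef(f))
  ci <- confint(f)
  expect_true(all(ci[, 1] <= coef(f) & coef(f) <= ci[, 2]))
  sim <- simulate(f, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(nrow(f$data), 2L))
  expect_identical(sim, simulate(f, nsim = 2, seed = 1))
  expect_output(print(f), "L50")
})

test_that("generate-and-fit recovers the half-inhibition within 10%", {
  cfg <- generator_config()
  p <- assay_kinetic_params()
  truth <- generating_half_inhibition(cfg, p)
  tab <- generate_availability_dataset(cfg, p, seed = 42)
  f <- fit_cis_inhibition(availability_fluor ~ total_ligand_fluor,
                          data = tab)
  expect_equal(coef(f)[["L50"]], truth, tolerance = 0.1)
})

test_that("half-inhibition ratios propagate and invert correctly", {
  L <- 10^seq(0, 4, length.out = 50)
  fa <- fit_cis_inhibition(L, 10 + 100 / (1 + L / 200))
  fb <- fit_cis_inhibition(L, 10 + 100 / (1 + L / 200))
  expect_equal(half_inhibition_ratio(fa, fb)$ratio, 1)
  fc <- fit_cis_inhibition(L, 10 + 100 / (1 + L / 400))
  r1 <- half_inhibition_ratio(fc, fa)
  expect_equal(r1$ratio, 2, tolerance = 1e-4)
  expect_equal(half_inhibition_ratio(fa, fc)$ratio, 1 / r1$ratio,
               tolerance = 1e-10)
  expect_warning(flat <- fit_cis_inhibition(L, rep(5, 50)))
  expect_error(half_inhibition_ratio(fa, flat), "identifiable")
})

test_that("a table compared with itself shows no significant bins", {
  cfg <- generator_config(n_cells_per_level = 60)
  tab <- generate_availability_dataset(cfg, assay_kinetic_params(), seed = 3)
  cc <- compare_conditions(tab, tab)
  expect_true(all(!cc$significant))
  expect_true(all(abs(cc$p[!is.na(cc$p)] - 1) < 1e-6))
})

test_that("receptor presence versus absence is detected at high ligand", {
  # ligand availability with and without Notch: cis depletion shows up in
  # the high-expression bins
  cfg <- generator_config(n_cells_per_level = 150)
  p <- assay_kinetic_params()
  p0 <- kinetic_params(beta_N = 0, kC_plus = 0.4, kC_minus = 10, kI = 10)
  with_notch <- generate_availability_dataset(cfg, p,
                                              assay = "ligand_availability",
                                              seed = 10)
  without <- generate_availability_dataset(cfg, p0,
                                           assay = "ligand_availability",
                                           seed = 11)
  cc <- compare_conditions(without, with_notch)
  tested <- which(!is.na(cc$p))
  hi <- tail(tested, 3)   # highest-expression tested bins
  expect_true(any(cc$significant[hi]))
})

test_that("t_on detection localizes onsets and flags flat traces", {
  t <- seq(0, 60, by = 1 / 3)
  ramp <- data.frame(t = t, reporter_fluor = pmax(0, t - 10) * 3,
                     ligand_fluor = 100 * exp(-0.05 * t))
  r <- detect_t_on(ramp)
  expect_true(r$onset)
  expect_lte(abs(r$t_on - 10), 1 / 3 + 1e-9)
  expect_equal(r$ligand_at_t_on, ramp$ligand_fluor[ramp$t == r$t_on])
  # scale invariance
  ramp2 <- ramp; ramp2$reporter_fluor <- ramp2$reporter_fluor * 37.5
  expect_equal(detect_t_on(ramp2)$t_on, r$t_on)
  # flat and decreasing traces yield flagged no-onset results
  expect_false(detect_t_on(data.frame(t = t, reporter_fluor = rep(2,
    length(t))))$onset)
  expect_false(detect_t_on(data.frame(t = t,
    reporter_fluor = 100 - t))$onset)
  expect_error(detect_t_on(data.frame(t = c(1, 2, 2, 3, 4),
    reporter_fluor = 1:5)), "increasing")
})

test_that("Lfng shifts dilution onsets earlier and to higher ligand", {
  p <- dilution_kinetic_params()
  dc <- dilution_config()
  none <- generate_dilution_timecourses(dc, p, fringe_config(),
                                        plate_ligand_density = 1,
                                        n_cells = 15, seed = 2)
  lfng <- generate_dilution_timecourses(dc, p, fringe_preset("lfng"),
                                        plate_ligand_density = 1,
                                        n_cells = 15, seed = 2)
  rn <- lapply(none, detect_t_on); rl <- lapply(lfng, detect_t_on)
  expect_lt(median(vapply(rl, `[[`, 0, "t_on")),
            median(vapply(rn, `[[`, 0, "t_on")))
  expect_gt(median(vapply(rl, `[[`, 0, "ligand_at_t_on")),
            median(vapply(rn, `[[`, 0, "ligand_at_t_on")))
})
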