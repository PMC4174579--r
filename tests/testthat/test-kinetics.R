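test_that("effective_kc evaluates the lumped cis constant", {
  expect_equal(effective_kc(1, 0, 1)$kc, 1)
  expect_equal(effective_kc(2, 3, 1)$kc, 2)
  # every encounter inactivates: kc -> 1/kC_plus as kI grows
  expect_equal(effective_kc(4, 1, 1e9)$kc, 1 / 4, tolerance = 1e-8)
  expect_equal(effective_kc(2, 3, 1, gamma_N = 0.5)$half_depletion, 1)
  expect_error(effective_kc(0, 1, 1), "positive")
  expect_error(effective_kc(1, 1, 0), "positive")
})

test_that("qss_available_notch matches the closed form and its landmarks", {
  expect_equal(qss_available_notch(0, 3, 1.5, 2), 2)           # beta_N/gamma_N
  expect_equal(qss_available_notch(2 * 1.5, 3, 1.5, 2), 1)     # half at kc*gamma_N
  expect_equal(qss_available_notch(c(0, 5), 0, 1, 1), c(0, 0)) # no production
  expect_error(qss_available_notch(-1, 1, 1, 1), "non-negative")
})

test_that("half-depletion ratio is exactly 1/2 for random positive parameters", {
  set.seed(42)
  for (i in 1:25) {
    bN <- runif(1, 0.1, 10); gN <- runif(1, 0.1, 5); kc <- runif(1, 0.05, 20)
    expect_equal(qss_available_notch(kc * gN, bN, gN, kc) /
                   qss_available_notch(0, bN, gN, kc), 0.5)
  }
})

test_that("qss_available_notch is strictly decreasing in D", {
  D <- seq(0, 50, length.out = 200)
  set.seed(1)
  for (i in 1:10) {
    v <- qss_available_notch(D, runif(1, 0.5, 5), runif(1, 0.2, 3),
                             runif(1, 0.1, 10))
    expect_true(all(diff(v) < 0))
  }
})

test_that("cis ODE right-hand side matches the mass-action scheme", {
  p <- params_kc1()
  expect_equal(cis_ode_rhs(c(N = 0, D = 0, C = 0), p),
               c(N = p$beta_N, D = p$beta_D, C = 0))
  # uncoupled case
  p0 <- kinetic_params(kC_plus = 0, kC_minus = 0, kI = 1)
  expect_equal(cis_ode_rhs(c(N = p0$beta_N / p0$gamma_N,
                             D = p0$beta_D / p0$gamma_D, C = 0), p0),
               c(N = 0, D = 0, C = 0))
  # at the brute-force (long-time ODE) steady state all derivatives vanish
  long <- integrate_cis_ode(p, times = c(0, 500))
  st <- c(N = long$N[2], D = long$D[2], C = long$C[2])
  expect_equal(unname(cis_ode_rhs(st, p)), c(0, 0, 0), tolerance = 1e-7)
})

test_that("steady-state solver handles degenerate and symmetric cases", {
  p <- kinetic_params(beta_D = 0)
  ss <- solve_cis_steady_state(p)
  expect_equal(ss$N, p$beta_N / p$gamma_N)
  expect_equal(unname(ss$D), 0)
  # symmetric parameters give N = D
  ps <- kinetic_params(beta_N = 2, beta_D = 2, gamma_N = 0.7, gamma_D = 0.7)
  sss <- solve_cis_steady_state(ps)
  expect_equal(sss$N, unname(sss$D), tolerance = 1e-10)
})

test_that("steady-state solver agrees with direct ODE integration", {
  set.seed(7)
  for (i in 1:10) {
    p <- kinetic_params(beta_N = runif(1, 0.5, 3), beta_D = runif(1, 0.5, 3),
                        gamma_N = runif(1, 0.3, 2), gamma_D = runif(1, 0.3, 2),
                        kC_plus = runif(1, 0.5, 4), kC_minus = runif(1, 1, 20),
                        kI = runif(1, 1, 20))
    ss <- solve_cis_steady_state(p)
    ode <- integrate_cis_ode(p, times = c(0, 400))
    expect_equal(ss$N, ode$N[2], tolerance = 5e-3)
    expect_equal(unname(ss$D), ode$D[2], tolerance = 5e-3)
  }
})

test_that("two-ligand competition reduces to the closed-form relation", {
  p1 <- params_kc(2); p2 <- params_kc(0.5)
  p2$beta_D <- 3; p2 <- do.call(kinetic_params, unclass(p2))
  ss <- solve_cis_steady_state(list(A = p1, B = p2))
  # Notch balance: beta_N = N*(gamma_N + sum D_l / kc_l)
  lhs <- p1$beta_N
  rhs <- ss$N * (p1$gamma_N + ss$D[["A"]] / 2 + ss$D[["B"]] / 0.5)
  expect_equal(lhs, rhs, tolerance = 1e-8)
  # and matches the two-ligand ODE at long times
  ode <- integrate_cis_ode(list(A = p1, B = p2), times = c(0, 500))
  expect_equal(ss$N, ode$N[2], tolerance = 1e-4)
  expect_equal(unname(ss$D), c(ode$D.A[2], ode$D.B[2]), tolerance = 1e-4)
})

test_that("production balances degradation plus inactivation at steady state", {
  set.seed(11)
  for (i in 1:10) {
    p <- kinetic_params(beta_N = runif(1, 0.5, 3), beta_D = runif(1, 0.5, 3),
                        kC_plus = runif(1, 0.5, 4), kC_minus = runif(1, 1, 20),
                        kI = runif(1, 1, 20))
    ss <- solve_cis_steady_state(p)
    expect_equal(p$beta_N, p$gamma_N * ss$N + p$kI * unname(ss$C_cis),
                 tolerance = 1e-6)
    expect_equal(p$beta_D, p$gamma_D * unname(ss$D) + p$kI * unname(ss$C_cis),
                 tolerance = 1e-6)
  }
})

test_that("trans signal rate is bilinear and matches the complex ODE slope", {
  p <- params_kc1()
  expect_equal(trans_signal_rate(2, 0, p), 0)
  expect_equal(trans_signal_rate(0, 3, p), 0)
  expect_equal(trans_signal_rate(4, 3, p), 2 * trans_signal_rate(2, 3, p))
  # oracle: integrate the trans complex explicitly at clamped N, D
  N <- 1.3; D <- 0.8
  rhs <- function(t, y, parms)
    list(c(T = p$kD_plus * N * D - (p$kD_minus + p$kS) * y[["T"]],
           S = p$kS * y[["T"]]))
  out <- deSolve::lsoda(c(T = 0, S = 0), times = seq(0, 60, by = 1), rhs,
                        atol = 1e-12, rtol = 1e-10)
  late_slope <- diff(tail(out[, "S"], 2))
  expect_equal(trans_signal_rate(N, D, p), late_slope, tolerance = 1e-4)
  p_bad <- kinetic_params(kD_minus = 0, kS = 0)
  expect_error(trans_signal_rate(1, 1, p_bad), "kD_minus")
})

test_that("Fringe modulation scales association rates in the stated directions", {
  p <- params_kc1()
  expect_identical(apply_fringe(p, fringe_preset("none"), "Jag1"), p)
  lf <- fringe_preset("lfng")
  pj <- apply_fringe(p, lf, "Jag1")
  expect_lt(pj$kC_plus, p$kC_plus)
  expect_lt(pj$kD_plus, p$kD_plus)
  pd <- apply_fringe(p, lf, "Dll1")
  expect_gt(pd$kC_plus, p$kC_plus)
  rf <- fringe_preset("rfng")
  pr <- apply_fringe(p, rf, "Jag1")
  expect_gte(pr$kC_plus, p$kC_plus)
  expect_gte(pr$kD_plus, p$kD_plus)
  expect_error(apply_fringe(p, lf, "Delta"), "not found")
})

test_that("Fringe application is multiplicative and composable", {
  p <- params_kc1()
  f1 <- fringe_config("Lfng", c(Dll1 = 2, Jag1 = 0.2),
                      c(Dll1 = 2, Jag1 = 0.2), 1.5)
  f2 <- fringe_config("Rfng", c(Dll1 = 1.5, Jag1 = 1.5),
                      c(Dll1 = 1.5, Jag1 = 1.5), 1.5)
  f12 <- fringe_config("both", c(Dll1 = 3, Jag1 = 0.3),
                       c(Dll1 = 3, Jag1 = 0.3), 1.5)
  a <- apply_fringe(apply_fringe(p, f1, "Jag1"), f2, "Jag1")
  b <- apply_fringe(p, f12, "Jag1")
  expect_equal(a$kC_plus, b$kC_plus)
  expect_equal(a$kD_plus, b$kD_plus)
})

test_that("kinetic parameters round-trip through YAML and JSON", {
  p <- kinetic_params(beta_N = 2.5, kC_plus = 0.4, kC_minus = 10, kI = 10)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_kinetic_params(p, f)
    expect_equal(read_kinetic_params(f), p)
    unlink(f)
  }
})

test_that("parameter validation rejects invalid rate sets", {
  expect_error(kinetic_params(gamma_N = 0), "gamma_N")
  expect_error(kinetic_params(beta_N = -1), "non-negative")
  expect_error(kinetic_params(kC_plus = 1, kC_minus = 0, kI = 0), "kC_minus")
})
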