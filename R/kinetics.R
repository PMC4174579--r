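#' Kinetic parameters of the cis/trans Notch-ligand reaction scheme
#'
#' Bundles the rate constants of the two elementary reactions of the model:
#' cis-inhibition, `N + D <-> [ND] -> 0` (association/dissociation `kC_plus`,
#' `kC_minus`, irreversible mutual inactivation `kI`), and trans-activation,
#' `N_i + D_j <-> [N_i D_j] -> S` (rates `kD_plus`, `kD_minus`, `kS`),
#' together with zeroth-order production (`beta_N`, `beta_D`) and
#' first-order degradation (`gamma_N`, `gamma_D`).  Concentrations and
#' rates are in dimensionless model units; conversion to fluorescence
#' happens only in the synthetic-data generators.
#'
#' @param beta_N,beta_D production rates (concentration/time), `>= 0`.
#' @param gamma_N,gamma_D degradation rates (1/time), `> 0`.
#' @param kC_plus,kC_minus cis association (1/(concentration time)) and
#'   dissociation (1/time) rates.
#' @param kI cis-complex inactivation rate (1/time).
#' @param kD_plus,kD_minus trans association and dissociation rates.
#' @param kS trans activation (signal production) rate (1/time).
#' @return An object of class `kinetic_params` (a named list).
#' @seealso [effective_kc()], [solve_cis_steady_state()], [apply_fringe()]
#' @export
kinetic_params <- function(beta_N = 1, beta_D = 1, gamma_N = 1, gamma_D = 1,
                           kC_plus = 2, kC_minus = 10, kI = 10,
                           kD_plus = 1, kD_minus = 1, kS = 1) {
  p <- list(beta_N = beta_N, beta_D = beta_D, gamma_N = gamma_N,
            gamma_D = gamma_D, kC_plus = kC_plus, kC_minus = kC_minus,
            kI = kI, kD_plus = kD_plus, kD_minus = kD_minus, kS = kS)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] < 0)
      stop(sprintf("'%s' must be a non-negative finite number", nm),
           call. = FALSE)
  }
  if (p$gamma_N <= 0) stop("'gamma_N' must be > 0", call. = FALSE)
  if (p$gamma_D <= 0) stop("'gamma_D' must be > 0", call. = FALSE)
  if (p$kC_plus > 0 && p$kC_minus + p$kI <= 0)
    stop("kC_minus + kI must be > 0 when kC_plus > 0 (cis complex would be absorbing)",
         call. = FALSE)
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (model units):\n")
  cat(sprintf("  production    beta_N = %g, beta_D = %g\n", x$beta_N, x$beta_D))
  cat(sprintf("  degradation   gamma_N = %g, gamma_D = %g\n",
              x$gamma_N, x$gamma_D))
  cat(sprintf("  cis           kC+ = %g, kC- = %g, kI = %g  (kc = %g)\n",
              x$kC_plus, x$kC_minus, x$kI,
              tryCatch(effective_kc(x$kC_plus, x$kC_minus, x$kI)$kc,
                       error = function(e) NA_real_)))
  cat(sprintf("  trans         kD+ = %g, kD- = %g, kS = %g\n",
              x$kD_plus, x$kD_minus, x$kS))
  invisible(x)
}

#' Lumped cis-interaction strength kc
#'
#' The quasi-steady-state reduction of the cis reaction lumps the three
#' elementary cis rates into a single constant,
#' `kc = (kC_minus + kI) / (kC_plus * kI)`, so that the net inactivation
#' flux is `N * D / kc`.  The cis-ligand level that halves available Notch
#' is `kc * gamma_N`.
#'
#' @param kC_plus,kC_minus,kI cis rates; `kC_plus > 0` and `kI > 0` are
#'   required (otherwise there is no cis inactivation pathway and kc is
#'   undefined/infinite).
#' @param gamma_N optional Notch degradation rate; when supplied, the
#'   half-depletion ligand level `kc * gamma_N` is filled in.
#' @return A list of class `effective_cis_strength` with elements `kc` and
#'   `half_depletion` (`NA` unless `gamma_N` given).
#' @export
effective_kc <- function(kC_plus, kC_minus, kI, gamma_N = NULL) {
  stop_if_not_scalar_pos(kC_plus, "kC_plus")
  stop_if_not_scalar_pos(kI, "kI")
  stop_if_not_scalar_pos(kC_minus, "kC_minus", strict = FALSE)
  kc <- (kC_minus + kI) / (kC_plus * kI)
  half <- if (is.null(gamma_N)) NA_real_ else {
    stop_if_not_scalar_pos(gamma_N, "gamma_N")
    kc * gamma_N
  }
  structure(list(kc = kc, half_depletion = half),
            class = "effective_cis_strength")
}

# kc straight from a kinetic_params object
kc_of <- function(params) {
  effective_kc(params$kC_plus, params$kC_minus, params$kI)$kc
}

#' Quasi-steady-state available Notch
#'
#' Closed-form steady-state level of free (trans-available) Notch under
#' cis-inhibition: `N_ss = (beta_N/gamma_N) / (1 + D/(kc*gamma_N))`, where
#' `D` is the steady-state free cis-ligand level.  Strictly decreasing in
#' `D`; equals the unopposed level `beta_N/gamma_N` at `D = 0` and half of
#' it at `D = kc*gamma_N`.
#'
#' @param D free cis-ligand level(s), `>= 0` (vectorized).
#' @param beta_N Notch production rate, `>= 0`.
#' @param gamma_N Notch degradation rate, `> 0`.
#' @param kc lumped cis constant, `> 0` (see [effective_kc()]).
#' @return Free Notch level(s), same length as `D`.
#' @export
qss_available_notch <- function(D, beta_N, gamma_N, kc) {
  if (!is.numeric(D) || any(!is.finite(D)) || any(D < 0))
    stop("'D' must be non-negative and finite", call. = FALSE)
  stop_if_not_scalar_pos(beta_N, "beta_N", strict = FALSE)
  stop_if_not_scalar_pos(gamma_N, "gamma_N")
  stop_if_not_scalar_pos(kc, "kc")
  (beta_N / gamma_N) / (1 + D / (kc * gamma_N))
}

#' Time derivatives of the single-ligand cis-inhibition ODE system
#'
#' Right-hand side of the mass-action system for one cell expressing Notch
#' `N`, one cis-ligand `D` and their cis complex `C`:
#' `dN/dt = beta_N - gamma_N*N - (kC_plus*N*D - kC_minus*C)`,
#' `dD/dt = beta_D - gamma_D*D - (kC_plus*N*D - kC_minus*C)`,
#' `dC/dt = kC_plus*N*D - kC_minus*C - kI*C`.
#'
#' @param state named numeric vector or list with elements `N`, `D`, `C`
#'   (all `>= 0`).
#' @param params a [kinetic_params()] object.
#' @return Named numeric vector `c(N=, D=, C=)` of time derivatives.
#' @export
cis_ode_rhs <- function(state, params) {
  state <- unlist(state)[c("N", "D", "C")]
  if (any(is.na(state)) || any(state < 0))
    stop("state must have non-negative entries N, D, C", call. = FALSE)
  flux <- params$kC_plus * state[["N"]] * state[["D"]] -
    params$kC_minus * state[["C"]]
  c(N = params$beta_N - params$gamma_N * state[["N"]] - flux,
    D = params$beta_D - params$gamma_D * state[["D"]] - flux,
    C = flux - params$kI * state[["C"]])
}

#' Integrate the cis-inhibition ODE system
#'
#' Stiff-capable numerical integration (via [deSolve::lsoda()]) of the
#' single-ligand system of [cis_ode_rhs()], or of its multi-ligand
#' extension in which independent cis reactions share the Notch pool.
#' Mainly used as the dynamic counterpart to the algebraic steady-state
#' solver.
#'
#' @param params a single [kinetic_params()] object or a named list of one
#'   per ligand (shared `beta_N`/`gamma_N` are taken from the first).
#' @param times output time points (first element is the initial time).
#' @param state0 optional initial state; default all species at 0.  For
#'   multiple ligands a list `list(N=, D=c(...), C=c(...))`.
#' @param clamp_D optionally hold the free-ligand level(s) fixed at the
#'   given value(s) (ligand treated as a buffered reservoir); used to probe
#'   the dose-response `N_ss(D)` directly.
#' @param atol,rtol integration tolerances.
#' @return A data.frame with columns `time`, `N`, `D.<ligand>`,
#'   `C.<ligand>` (single-ligand: `D`, `C`).
#' @export
integrate_cis_ode <- function(params, times, state0 = NULL, clamp_D = NULL,
                              atol = 1e-12, rtol = 1e-8) {
  plist <- if (inherits(params, "kinetic_params")) list(D = params) else params
  stopifnot(length(plist) >= 1L, all(vapply(plist, inherits, TRUE,
                                            "kinetic_params")))
  nl <- length(plist)
  lig <- names(plist)
  if (is.null(lig)) lig <- paste0("L", seq_len(nl))
  bN <- plist[[1]]$beta_N; gN <- plist[[1]]$gamma_N
  if (is.null(state0)) state0 <- list(N = 0, D = rep(0, nl), C = rep(0, nl))
  y0 <- c(N = state0$N,
          stats::setNames(rep(state0$D, length.out = nl), paste0("D", seq_len(nl))),
          stats::setNames(rep(state0$C, length.out = nl), paste0("C", seq_len(nl))))
  if (!is.null(clamp_D)) {
    clamp_D <- rep(clamp_D, length.out = nl)
    y0[paste0("D", seq_len(nl))] <- clamp_D
  }
  rhs <- function(t, y, ...) {
    N <- y[1L]
    D <- y[1L + seq_len(nl)]
    C <- y[1L + nl + seq_len(nl)]
    flux <- vapply(seq_len(nl), function(i)
      plist[[i]]$kC_plus * N * D[i] - plist[[i]]$kC_minus * C[i], 0)
    dN <- bN - gN * N - sum(flux)
    dD <- vapply(seq_len(nl), function(i)
      plist[[i]]$beta_D - plist[[i]]$gamma_D * D[i] - flux[i], 0)
    dC <- vapply(seq_len(nl), function(i)
      flux[i] - plist[[i]]$kI * C[i], 0)
    if (!is.null(clamp_D)) dD[] <- 0
    list(c(dN, dD, dC))
  }
  out <- deSolve::lsoda(y = y0, times = times, func = rhs,
                        atol = atol, rtol = rtol)
  out <- as.data.frame(out)
  nms <- c("time", "N",
           if (nl == 1L) c("D", "C")
           else c(paste0("D.", lig), paste0("C.", lig)))
  stats::setNames(out, nms)
}

# Closed-form steady state of the QSS-reduced single-ligand system
# (identical to the exact ODE steady state since dC/dt = 0 there):
#   beta_N = N*(gamma_N + D/kc),  beta_D = D*(gamma_D + N/kc)
# Eliminating D yields a quadratic in N with a unique positive root.
# Vectorized over beta_D.
steady_state_single <- function(beta_N, gamma_N, beta_D, gamma_D, kc) {
  a <- gamma_N
  b <- gamma_N * kc * gamma_D + beta_D - beta_N
  cc <- -beta_N * kc * gamma_D
  # stable quadratic root: N = (-b + sqrt(b^2 - 4ac)) / 2a
  disc <- sqrt(b^2 - 4 * a * cc)
  N <- ifelse(b <= 0, (-b + disc) / (2 * a), -2 * cc / (b + disc))
  D <- beta_D / (gamma_D + N / kc)
  list(N = N, D = D)
}

#' Steady state of the coupled cis-inhibition system
#'
#' Solves the quasi-steady-state system for one or more cis-ligands
#' sharing the Notch pool:
#' `beta_N = N*(gamma_N + sum_l D_l/kc_l)`,
#' `beta_D_l = D_l*(gamma_D_l + N/kc_l)`.
#' For a single ligand the closed-form quadratic root is used; for several
#' ligands a damped fixed-point iteration on `N` with per-ligand
#' elimination, falling back to a bracketed root solve.  The returned state
#' equals the long-time limit of [integrate_cis_ode()] (the reduced system
#' is exact at steady state, where the complex is at equilibrium).
#'
#' @param params a [kinetic_params()] object (single ligand) or a named
#'   list of one per ligand; `beta_N`/`gamma_N` shared from the first.
#' @param tol relative convergence tolerance on the Notch balance residual.
#' @param max_iter iteration budget for the fixed-point phase.
#' @return A list of class `cell_state` with elements `N`, `D` (named per
#'   ligand), `C_cis` (named per ligand, complex at its equilibrium), `S = 0`.
#' @export
solve_cis_steady_state <- function(params, tol = 1e-10, max_iter = 200L) {
  plist <- if (inherits(params, "kinetic_params")) list(D = params) else params
  if (length(plist) < 1L) stop("need at least one ligand", call. = FALSE)
  stopifnot(all(vapply(plist, inherits, TRUE, "kinetic_params")))
  stop_if_not_scalar_pos(tol, "tol")
  lig <- names(plist)
  if (is.null(lig)) lig <- paste0("L", seq_along(plist))
  bN <- plist[[1]]$beta_N; gN <- plist[[1]]$gamma_N
  kc <- vapply(plist, kc_of, 0)
  bD <- vapply(plist, `[[`, 0, "beta_D")
  gD <- vapply(plist, `[[`, 0, "gamma_D")

  D_of_N <- function(N) bD / (gD + N / kc)
  resid <- function(N) bN - N * (gN + sum(D_of_N(N) / kc))
  scale <- max(bN, gN, 1)

  if (length(plist) == 1L) {
    ss <- steady_state_single(bN, gN, unname(bD), unname(gD), unname(kc))
    N <- ss$N; D <- ss$D
  } else {
    # damped fixed point: N <- (1-w) N + w * beta_N / (gamma_N + sum D_l/kc_l)
    N <- bN / gN
    w <- 0.5
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      Nn <- (1 - w) * N + w * bN / (gN + sum(D_of_N(N) / kc))
      if (abs(Nn - N) <= tol * max(Nn, 1e-300)) { N <- Nn; ok <- TRUE; break }
      N <- Nn
    }
    if (!ok || abs(resid(N)) > tol * scale) {
      # fall back to bracketed root solve; resid is strictly decreasing in N
      hi <- bN / gN
      if (bN == 0) { N <- 0 } else {
        r <- stats::uniroot(resid, lower = 0, upper = hi * (1 + 1e-12),
                            tol = tol * max(hi, 1) * 1e-3)
        N <- r$root
      }
    }
    if (abs(resid(N)) > 1e-6 * scale)
      stop(sprintf("steady-state solve did not converge (residual %.3g)",
                   resid(N)), call. = FALSE)
    D <- D_of_N(N)
  }
  C <- vapply(seq_along(plist), function(i)
    plist[[i]]$kC_plus * N * D[i] / (plist[[i]]$kC_minus + plist[[i]]$kI), 0)
  structure(list(N = N,
                 D = stats::setNames(D, lig),
                 C_cis = stats::setNames(C, lig),
                 S = 0),
            class = "cell_state")
}

#' Quasi-steady trans-activation signal rate
#'
#' Signal production rate when the trans complex between receiver Notch
#' and sender ligand is at quasi-steady state:
#' `rate = kS * kD_plus * N * D / (kD_minus + kS)`.
#'
#' @param N_receiver free Notch on the receiving cell (vectorized).
#' @param D_sender free trans-ligand presented by the sender (vectorized).
#' @param params a [kinetic_params()] object supplying `kD_plus`,
#'   `kD_minus`, `kS`.
#' @return Signal production rate (S per unit time).
#' @export
trans_signal_rate <- function(N_receiver, D_sender, params) {
  if (any(N_receiver < 0) || any(D_sender < 0))
    stop("N_receiver and D_sender must be non-negative", call. = FALSE)
  if (params$kD_plus > 0 && params$kD_minus + params$kS <= 0)
    stop("kD_minus + kS must be > 0 when kD_plus > 0 (trans complex would be absorbing)",
         call. = FALSE)
  if (params$kD_plus == 0) return(0 * N_receiver * D_sender)
  params$kS * params$kD_plus * N_receiver * D_sender /
    (params$kD_minus + params$kS)
}
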