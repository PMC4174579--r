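#' Configuration of the dorsal-ventral boundary lattice
#'
#' Rectangular grid of cells split row-wise into a dorsal and a ventral
#' compartment, with trans signaling between 4-neighbours.  Dorsal cells
#' express Notch, Serrate and Fringe (Delta expression is configurable
#' and defaults to 0 — any low-level dorsal Delta signaling is left to
#' the user to enable); ventral cells express Notch and Delta without
#' Fringe.  Notch signal in ventral cells feeds back on Delta production
#' through a Hill function, implementing the second phase of boundary
#' formation (activated ventral cells up-regulate Delta and signal back
#' to dorsal cells).
#'
#' In the wing-disc scenario Delta cannot activate Notch efficiently in
#' cells lacking Fringe; with `delta_requires_fringe = TRUE` (default)
#' Delta trans flux into Fringe-negative receivers is blocked.  A
#' receiver-side Fringe trans factor below `block_cutoff` likewise blocks
#' that ligand entirely (Fringe "blocks" Serrate trans signaling rather
#' than merely damping it).
#'
#' @param nrow,ncol grid dimensions (rows are compartment-parallel).
#' @param dorsal_rows indices of dorsal rows (remaining rows are
#'   ventral); both compartments must be non-empty.
#' @param dorsal,ventral lists with `notch`, `Delta`, `Serrate`
#'   production rates; the dorsal compartment uses `fringe` (default the
#'   `"fly"` preset), the ventral compartment is Fringe-negative.
#' @param feedback list with `hill`, `K` (signal at half-maximal
#'   up-regulation), `beta_max` (added Delta production at saturation).
#' @param block_cutoff receiver trans factor below which a ligand is
#'   blocked.
#' @param delta_requires_fringe block Delta reception in Fringe-negative
#'   cells.
#' @param thr_frac target-gene activation threshold as a fraction of the
#'   maximal ventral signal at the end of the run.
#' @param dt Euler time step; `noise_sd` optional Gaussian noise on the
#'   per-step signal increment (0 = deterministic).
#' @return A list of class `lattice_config`.
#' @export
lattice_config <- function(nrow = 8, ncol = 6, dorsal_rows = 1:4,
                           dorsal = list(notch = 1, Delta = 0, Serrate = 3,
                                         fringe = fringe_preset("fly")),
                           ventral = list(notch = 1, Delta = 0.3,
                                          Serrate = 0),
                           feedback = list(hill = 2, K = 2, beta_max = 3),
                           block_cutoff = 0.5,
                           delta_requires_fringe = TRUE,
                           thr_frac = 0.5, dt = 0.05, noise_sd = 0) {
  dorsal_rows <- sort(unique(as.integer(dorsal_rows)))
  if (nrow < 2 || length(dorsal_rows) == 0 || length(dorsal_rows) == nrow ||
      any(dorsal_rows < 1) || any(dorsal_rows > nrow))
    stop("grid must contain at least one dorsal and one ventral row",
         call. = FALSE)
  structure(list(nrow = nrow, ncol = ncol, dorsal_rows = dorsal_rows,
                 dorsal = dorsal, ventral = ventral, feedback = feedback,
                 block_cutoff = block_cutoff,
                 delta_requires_fringe = delta_requires_fringe,
                 thr_frac = thr_frac, dt = dt, noise_sd = noise_sd),
            class = "lattice_config")
}

#' Simulate two-phase signaling at the dorsal-ventral boundary
#'
#' Integrates the lattice: at every step each cell's free Notch and free
#' ligands are set to the cis steady state of its current (Fringe-
#' modified) production rates — cis equilibration is fast relative to
#' signal accumulation — then trans signal flows between 4-neighbours at
#' the quasi-steady trans rate with the receiver's Fringe trans factors
#' (blocked ligands contribute nothing), and accumulated signal
#' up-regulates Delta production in ventral cells through the feedback
#' Hill function.  With the default configuration signaling proceeds in
#' two phases: dorsal cells (free Serrate preserved by Fringe-weakened
#' cis-inhibition) activate the first ventral row, which up-regulates
#' Delta, switches towards a sending state and trans-activates the first
#' dorsal row — activation stays confined to the two interface rows.
#'
#' A cell is flagged activated when its final signal strictly exceeds
#' `thr_frac` times the maximal ventral signal at `t_end`.
#'
#' @param config a [lattice_config()].
#' @param params base [kinetic_params()] (production rates come from the
#'   compartments).
#' @param t_end simulated time (model units).
#' @param seed integer seed (only used when `config$noise_sd > 0`).
#' @param save_every save the state every this many steps.
#' @param threshold optional absolute activation threshold; by default it
#'   is self-calibrated as `thr_frac` times the maximal ventral signal of
#'   this run.  When comparing a perturbed scenario (e.g. a Serrate
#'   knockout) against a reference, pass the reference run's `threshold`
#'   so "activated" means the same signal level in both.
#' @return A list of class `lattice_result`: `times`, signal array `S`
#'   (cells x saved times), matrices `activated`, `final_S`,
#'   `activation_time`, `free_N`, `compartment`, and `threshold`.
#' @export
simulate_dv_boundary <- function(config, params = kinetic_params(),
                                 t_end = 10, seed = 1L, save_every = 5L,
                                 threshold = NULL) {
  stopifnot(inherits(config, "lattice_config"), t_end > 0)
  nr <- config$nrow; nc <- config$ncol
  ncell <- nr * nc
  is_dorsal <- matrix(FALSE, nr, nc)
  is_dorsal[config$dorsal_rows, ] <- TRUE
  fr_none <- fringe_config(identity = "none",
                           cis_factor = c(Delta = 1, Serrate = 1),
                           trans_factor = c(Delta = 1, Serrate = 1))
  fr_d <- config$dorsal$fringe
  if (is.null(fr_d)) fr_d <- fringe_preset("fly")

  beta_N <- ifelse(is_dorsal, config$dorsal$notch, config$ventral$notch)
  beta_Ser <- ifelse(is_dorsal, config$dorsal$Serrate, config$ventral$Serrate)
  beta_Del0 <- ifelse(is_dorsal, config$dorsal$Delta, config$ventral$Delta)

  # Fringe-modified per-ligand kinetics for each compartment
  comp_params <- function(fr, l) apply_fringe(params, fr, l)
  kc_cis <- list(
    dorsal = c(Delta = kc_of(comp_params(fr_d, "Delta")),
               Serrate = kc_of(comp_params(fr_d, "Serrate"))),
    ventral = c(Delta = kc_of(comp_params(fr_none, "Delta")),
                Serrate = kc_of(comp_params(fr_none, "Serrate"))))
  # receiver-side trans rate coefficient kS*kD+*f/(kD-+kS), 0 when blocked
  trans_coef <- function(fr, dorsal_receiver) {
    vapply(c("Delta", "Serrate"), function(l) {
      f <- fr$trans_factor[[l]]
      if (f < config$block_cutoff) return(0)
      if (l == "Delta" && config$delta_requires_fringe && !dorsal_receiver)
        return(0)
      params$kS * params$kD_plus * f / (params$kD_minus + params$kS)
    }, 0)
  }
  tc <- list(dorsal = trans_coef(fr_d, TRUE),
             ventral = trans_coef(fr_none, FALSE))

  steps <- ceiling(t_end / config$dt)
  save_at <- unique(c(seq(0L, steps, by = save_every), steps))
  S <- matrix(0, nr, nc)
  beta_Del <- beta_Del0
  S_saved <- matrix(NA_real_, ncell, length(save_at))
  S_saved[, 1] <- 0
  free_N <- matrix(0, nr, nc); free_Del <- free_N; free_Ser <- free_N

  # neighbour index offsets (4-neighbourhood)
  nb_of <- function(r, c) {
    out <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    out[out[, 1] >= 1 & out[, 1] <= nr & out[, 2] >= 1 & out[, 2] <= nc, ,
        drop = FALSE]
  }
  nbs <- lapply(seq_len(ncell), function(i)
    nb_of((i - 1) %% nr + 1, (i - 1) %/% nr + 1))

  equilibrate <- function() {
    for (i in seq_len(ncell)) {
      r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
      key <- if (is_dorsal[r, c]) "dorsal" else "ventral"
      kc <- kc_cis[[key]]
      bN <- beta_N[r, c]
      bD <- c(Delta = beta_Del[r, c], Serrate = beta_Ser[r, c])
      # scalar root in N for the two-ligand competition
      Dfun <- function(N) bD / (params$gamma_D + N / kc)
      if (bN == 0) N <- 0
      else {
        f <- function(N) bN - N * (params$gamma_N + sum(Dfun(N) / kc))
        N <- stats::uniroot(f, c(0, bN / params$gamma_N * (1 + 1e-12)),
                            tol = 1e-12)$root
      }
      D <- Dfun(N)
      free_N[r, c] <<- N
      free_Del[r, c] <<- D[["Delta"]]
      free_Ser[r, c] <<- D[["Serrate"]]
    }
  }

  run <- function() {
    si <- 1L
    for (step in seq_len(steps)) {
      equilibrate()
      dS <- matrix(0, nr, nc)
      for (i in seq_len(ncell)) {
        r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
        key <- if (is_dorsal[r, c]) "dorsal" else "ventral"
        co <- tc[[key]]
        nb <- nbs[[i]]
        flux <- 0
        for (k in seq_len(nrow(nb))) {
          flux <- flux + co[["Delta"]] * free_N[r, c] *
            free_Del[nb[k, 1], nb[k, 2]] +
            co[["Serrate"]] * free_N[r, c] * free_Ser[nb[k, 1], nb[k, 2]]
        }
        dS[r, c] <- flux * config$dt
      }
      if (config$noise_sd > 0)
        dS <- dS + matrix(stats::rnorm(ncell, 0,
                                       config$noise_sd * sqrt(config$dt)),
                          nr, nc)
      S <<- pmax(S + dS, 0)
      # Delta up-regulation in activated ventral cells
      hs <- S^config$feedback$hill /
        (S^config$feedback$hill + config$feedback$K^config$feedback$hill)
      beta_Del <<- beta_Del0 + ifelse(is_dorsal, 0,
                                      config$feedback$beta_max * hs)
      if (step %in% save_at) {
        si <- si + 1L
        S_saved[, si] <<- as.vector(S)
      }
    }
  }
  with_seed(if (config$noise_sd > 0) seed else NULL, run())

  times <- save_at * config$dt
  if (is.null(threshold))
    threshold <- config$thr_frac * max(S[!is_dorsal])
  activated <- S > threshold
  act_time <- matrix(NA_real_, nr, nc)
  for (i in seq_len(ncell)) {
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    idx <- which(S_saved[i, ] > threshold)[1]
    if (!is.na(idx)) act_time[r, c] <- times[idx]
  }
  structure(list(times = times, S = S_saved, final_S = S,
                 activated = activated, activation_time = act_time,
                 free_N = free_N, free_Delta = free_Del,
                 free_Serrate = free_Ser,
                 compartment = ifelse(is_dorsal, "dorsal", "ventral"),
                 threshold = threshold, config = config),
            class = "lattice_result")
}

#' @export
print.lattice_result <- function(x, ...) {
  nr <- nrow(x$activated)
  cat(sprintf("D/V boundary simulation: %d x %d lattice, threshold %.3g\n",
              nr, ncol(x$activated), x$threshold))
  for (r in seq_len(nr))
    cat(sprintf("  row %2d (%s): %d/%d activated\n", r, x$compartment[r, 1],
                sum(x$activated[r, ]), ncol(x$activated)))
  invisible(x)
}
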