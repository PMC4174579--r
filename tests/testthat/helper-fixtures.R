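# shared fixtures: small parameter sets and synthetic fields built in code

params_kc1 <- function() kinetic_params()            # kc = 1
params_kc <- function(kc) {
  # kC_minus = kI = 10 so kc = 20 / (10 * kC_plus)
  kinetic_params(kC_plus = 2 / kc, kC_minus = 10, kI = 10)
}

fringe_none_ds <- function() {
  fringe_config(identity = "none",
                cis_factor = c(Delta = 1, Serrate = 1),
                trans_factor = c(Delta = 1, Serrate = 1))
}

# a tiny field of disjoint disks with known intensities
small_field <- function(n = 10, shape = c(220, 220), noise_sd = 0,
                        background = list(type = "constant", value = 0),
                        seed = 7, avail_range = c(50, 200)) {
  cells <- sample_cell_layout(n, shape, c(8, 12), min_gap = 10, seed = seed)
  cells$cyto <- 100
  cells$avail <- with_seed_test(seed + 1, stats::runif(n, avail_range[1],
                                                       avail_range[2]))
  render_synthetic_field(cells, shape, background_model = background,
                         noise_sd = noise_sd, seed = seed + 2)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# match measured cells to ground-truth cells by nearest centroid
match_truth <- function(meas, truth) {
  vapply(seq_len(nrow(meas)), function(i)
    which.min((truth$x - meas$centroid_x[i])^2 +
                (truth$y - meas$centroid_y[i])^2), 0L)
}
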