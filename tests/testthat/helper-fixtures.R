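# Shared fixture builders and independent oracles.

# Quick ensemble from parallel vectors.
toy_ensemble <- function(energies, f, ids = NULL, functional = "SYN", phase = "gas") {
  ids <- ids %||% rep("c1", length(energies))
  states <- tibble::tibble(
    conformer_id = ids,
    energy_eV = energies,
    oscillator_strength = f
  ) |>
    dplyr::group_by(conformer_id) |>
    dplyr::mutate(state_index = dplyr::row_number()) |>
    dplyr::ungroup()
  new_ensemble(states, functional_tag = functional, phase_tag = phase)
}

# Independent double-loop reconstruction of the ensemble spectrum, written
# from the defining sum with an explicit Gaussian (no dnorm), as an oracle
# for the vectorised implementation.
naive_spectrum <- function(ens, params) {
  grid <- seq(params$grid_min_eV, params$grid_max_eV, by = params$grid_step_eV)
  sigma <- params$fwhm_eV / (2 * sqrt(2 * log(2)))
  ids <- unique(ens$conformer_id)
  A <- numeric(length(grid))
  for (id in ids) {
    rec <- ens[ens$conformer_id == id, , drop = FALSE]
    for (j in seq_len(nrow(rec))) {
      A <- A + rec$oscillator_strength[j] *
        exp(-(grid - rec$energy_eV[j])^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
    }
  }
  A / length(ids)
}

# Numerically measured FWHM: linear interpolation of the two half-maximum
# crossings of a single-band spectrum.
measure_fwhm <- function(sp) {
  y <- sp$intensity
  e <- sp$energy_eV
  half <- max(y) / 2
  above <- which(y >= half)
  i1 <- above[1]
  i2 <- above[length(above)]
  stopifnot(i1 > 1, i2 < length(y))
  xlo <- e[i1 - 1] + (half - y[i1 - 1]) / (y[i1] - y[i1 - 1]) * (e[i1] - e[i1 - 1])
  xhi <- e[i2] + (half - y[i2]) / (y[i2 + 1] - y[i2]) * (e[i2 + 1] - e[i2])
  xhi - xlo
}

# Uniform random proper rotation matrix.
rand_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(frames, R, shift) {
  xyz <- as.matrix(frames[, c("x", "y", "z")]) %*% t(R)
  frames$x <- xyz[, 1] + shift[1]
  frames$y <- xyz[, 2] + shift[2]
  frames$z <- xyz[, 3] + shift[3]
  frames
}

circ_mean_deg <- function(x) {
  atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi
}

# The published comparison table: absorption maxima (nm) and shifts (eV)
# for four functionals in two phases.
published_table1 <- function() {
  tibble::tribble(
    ~functional, ~phase,     ~conf_nm, ~opt_nm, ~delta_E_eV,
    "B3LYP",     "gas",      471,      426,     0.275,
    "BLYP",      "gas",      523,      477,     0.228,
    "PBE0",      "gas",      458,      418,     0.261,
    "PBE",       "gas",      525,      478,     0.229,
    "B3LYP",     "solution", 535,      500,     0.164,
    "BLYP",      "solution", 590,      561,     0.106,
    "PBE0",      "solution", 523,      486,     0.179,
    "PBE",       "solution", 592,      560,     0.122
  )
}
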