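#' Von Mises random deviates
#'
#' Draws from the von Mises distribution (the circular analogue of the
#' normal) centred at `mu_deg` with concentration `kappa`, using the
#' Best-Fisher rejection algorithm.  Values are returned in degrees,
#' wrapped to (-180, 180].
#'
#' @param n Number of draws.
#' @param mu_deg Center, degrees.
#' @param kappa Concentration (> 0); large kappa ~ normal with sd
#'   `1/sqrt(kappa)` radians.
#' @return Numeric vector of length `n`.
#' @export
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa <= 0) abort("kappa must be > 0", class = "specens_argument_error")
  if (n == 0) return(numeric(0))
  mu <- mu_deg * pi / 180
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    theta <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    out <- c(out, theta[ok])
  }
  wrap_deg((mu + out[seq_len(n)]) * 180 / pi)
}

#' Multimodal torsion model
#'
#' A von Mises mixture describing the stationary distribution of one
#' monitored dihedral: a set of mode centers with concentrations and
#' weights.  Emulates the multimodal torsional populations seen along
#' room-temperature trajectories of flexible fluorophores.
#'
#' @param centers_deg Mode centers, degrees in (-180, 180].
#' @param kappa Concentration(s), recycled across modes.
#' @param weights Positive mixture weights, recycled and normalised to
#'   sum to 1.
#' @return A `torsion_model` tibble with columns `center_deg`, `kappa`,
#'   `weight`.
#' @examples
#' torsion_model(c(-113, -76), kappa = 50)
#' @export
torsion_model <- function(centers_deg, kappa = 50, weights = 1) {
  if (any(kappa <= 0)) abort("kappa must be > 0", class = "specens_argument_error")
  if (any(weights <= 0)) abort("weights must be positive", class = "specens_argument_error")
  tm <- tibble(
    center_deg = wrap_deg(centers_deg),
    kappa = rep_len(kappa, length(centers_deg)),
    weight = rep_len(weights, length(centers_deg))
  )
  tm$weight <- tm$weight / sum(tm$weight)
  structure(tm, class = c("torsion_model", class(tm)))
}

#' Generate a dihedral-angle series
#'
#' Independent draws from a von Mises mixture, one per saved frame,
#' reproducible for a given seed.  Frames are treated as uncorrelated
#' (the sampling schedules this package models save frames far apart
#' relative to the torsional correlation time), so no autocorrelation is
#' imposed.
#'
#' @param model A [torsion_model()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @param name Angle name stored in the series.
#' @param save_interval_ps Frame spacing used to fill `time_ps`
#'   (frame k saved at `k * save_interval_ps`, frame 0 at t = 0).
#' @return An angle series tibble: `frame_index`, `time_ps`, `angle_name`,
#'   `angle_deg`.
#' @export
gen_angle_series <- function(model, n_frames, seed = 1, name = "delta",
                             save_interval_ps = 4) {
  stopifnot(inherits(model, "torsion_model"))
  if (n_frames < 1) abort("n_frames must be >= 1", class = "specens_argument_error")
  set.seed(seed)
  comp <- sample.int(nrow(model), n_frames, replace = TRUE, prob = model$weight)
  ang <- numeric(n_frames)
  for (j in seq_len(nrow(model))) {
    sel <- comp == j
    if (any(sel)) ang[sel] <- rvonmises_deg(sum(sel), model$center_deg[j], model$kappa[j])
  }
  tibble(
    frame_index = seq_len(n_frames) - 1L,
    time_ps = (seq_len(n_frames) - 1L) * save_interval_ps,
    angle_name = name,
    angle_deg = ang
  )
}

#' Torsion-coupled excitation model
#'
#' Generative model for per-conformer vertical excitations whose bright
#' state is coupled to one key dihedral.  The bright-state energy of
#' conformer `k` with dihedral `delta_k` is
#'
#' `E_k = E_ref + s * a * (1 - cos(delta_k - delta_0)) + noise`
#'
#' with `s = -1` (the default, `direction = "red"`): conformations away
#' from the reference dihedral `delta_0` absorb at lower energy, which is
#' the mechanism by which sampling non-minimum conformations red-shifts
#' the ensemble band relative to the optimised structure.  A template of
#' weak states at fixed energy offsets rides along with each conformer.
#'
#' @param reference_energy_eV Bright-state energy at `delta_0`, eV.
#' @param coupling_amplitude_eV Coupling amplitude `a` (>= 0), eV.
#' @param reference_angle_deg The reference dihedral `delta_0`, degrees.
#' @param noise_sd_eV Gaussian noise on the bright-state energy, eV.
#' @param bright_f0 Oscillator strength of the bright state.
#' @param f_noise_sd Gaussian noise on the bright oscillator strength
#'   (clipped at 0).
#' @param weak_states Tibble with columns `offset_eV`, `f`: the weak-state
#'   template (energies `E_k + offset_eV`).
#' @param direction `"red"` (energy lowers away from `delta_0`) or
#'   `"blue"`.
#' @return A `coupling_model` list.
#' @export
coupling_model <- function(reference_energy_eV = 2.65,
                           coupling_amplitude_eV = 1.2,
                           reference_angle_deg = -66,
                           noise_sd_eV = 0.02,
                           bright_f0 = 0.8012,
                           f_noise_sd = 0,
                           weak_states = tibble(offset_eV = c(0.4, 0.7),
                                                f = c(0.05, 0.02)),
                           direction = c("red", "blue")) {
  direction <- match.arg(direction)
  if (coupling_amplitude_eV < 0) {
    abort("coupling_amplitude_eV must be >= 0", class = "specens_argument_error")
  }
  if (reference_energy_eV <= 0) {
    abort("reference_energy_eV must be > 0", class = "specens_argument_error")
  }
  structure(list(reference_energy_eV = reference_energy_eV,
                 coupling_amplitude_eV = coupling_amplitude_eV,
                 reference_angle_deg = wrap_deg(reference_angle_deg),
                 noise_sd_eV = noise_sd_eV,
                 bright_f0 = bright_f0,
                 f_noise_sd = f_noise_sd,
                 weak_states = as_tibble(weak_states),
                 direction = direction),
            class = "coupling_model")
}

#' Generate a conformer ensemble from an angle series
#'
#' Applies a [coupling_model()] to every frame of an angle series,
#' producing one conformer record per frame (bright state plus the
#' weak-state template), together with the companion record of the
#' "optimised" structure: the bright state exactly at the reference
#' dihedral, noise-free.
#'
#' @param angles An angle series (`frame_index`, `angle_deg`), typically
#'   the decimated subset of a trajectory's series.
#' @param coupling A [coupling_model()].
#' @param seed Integer seed for the energy/strength noise.
#' @param functional_tag,phase_tag Provenance tags for the generated
#'   ensemble.
#' @return A list with elements `conf` (the `conformer_ensemble`, ids
#'   taken from `frame_index`), `opt` (single-record ensemble) and
#'   `angles` (the input series augmented with a `conformer_id` column).
#' @export
gen_ensemble <- function(angles, coupling, seed = 1,
                         functional_tag = "SYN", phase_tag = "gas") {
  stopifnot(inherits(coupling, "coupling_model"))
  angles <- as_tibble(angles)
  if (nrow(angles) == 0) abort("no frames in angle series", class = "specens_no_data")
  set.seed(seed)
  s <- if (coupling$direction == "red") -1 else 1
  dev_rad <- circ_diff_deg(angles$angle_deg, coupling$reference_angle_deg) * pi / 180
  e_bright <- coupling$reference_energy_eV +
    s * coupling$coupling_amplitude_eV * (1 - cos(dev_rad)) +
    rnorm(nrow(angles), 0, coupling$noise_sd_eV)
  f_noise <- if (coupling$f_noise_sd > 0) {
    rnorm(nrow(angles), 0, coupling$f_noise_sd)
  } else {
    numeric(nrow(angles))
  }
  f_bright <- pmax(0, coupling$bright_f0 + f_noise)
  weak <- coupling$weak_states
  if (any(e_bright <= 0) ||
      (nrow(weak) > 0 && any(outer(e_bright, weak$offset_eV, `+`) <= 0))) {
    abort("coupling parameters produced a non-positive excitation energy",
          class = "specens_generation_error")
  }
  ids <- as.character(angles$frame_index %||% (seq_len(nrow(angles)) - 1L))
  nw <- nrow(weak)
  states <- tibble(
    conformer_id = rep(ids, each = 1L + nw),
    state_index = rep(seq_len(1L + nw), times = length(ids)),
    energy_eV = as.vector(vapply(seq_along(ids), function(k) {
      sort(c(e_bright[k], e_bright[k] + weak$offset_eV))
    }, numeric(1L + nw))),
    oscillator_strength = as.vector(vapply(seq_along(ids), function(k) {
      e_all <- c(e_bright[k], e_bright[k] + weak$offset_eV)
      f_all <- c(f_bright[k], weak$f)
      f_all[order(e_all)]
    }, numeric(1L + nw)))
  )
  conf <- new_ensemble(states, functional_tag = functional_tag,
                       phase_tag = phase_tag, source = "synthetic")
  e0 <- coupling$reference_energy_eV
  opt_e <- c(e0, e0 + weak$offset_eV)
  opt_f <- c(coupling$bright_f0, weak$f)[order(opt_e)]
  opt <- new_ensemble(
    tibble(conformer_id = "opt", state_index = seq_len(1L + nw),
           energy_eV = sort(opt_e), oscillator_strength = opt_f),
    functional_tag = functional_tag, phase_tag = phase_tag,
    source = "synthetic optimised structure"
  )
  angles$conformer_id <- ids
  list(conf = conf, opt = opt, angles = angles)
}

#' Write Gaussian-dialect fixture logs
#'
#' Writes one quantum-chemistry log excerpt per conformer in the dialect
#' read by [parse_gaussian_excited_states()], with energies printed to
#' 4 decimals (eV), wavelengths to 2 decimals (nm) and oscillator
#' strengths to 4 decimals, so a write/parse round trip preserves the
#' ensemble to printed precision.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a tibble with columns `conformer_id`, `path`.
#' @export
write_fixture_logs <- function(ensemble, dir) {
  stopifnot(is_ensemble(ensemble))
  if (nrow(ensemble) == 0) abort("empty ensemble", class = "specens_no_data")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory ", dir), class = "specens_io_error")
  }
  ids <- unique(ensemble$conformer_id)
  paths <- vapply(ids, function(id) {
    g <- ensemble[ensemble$conformer_id == id, , drop = FALSE]
    path <- file.path(dir, paste0("conf_", id, ".log"))
    lines <- c(
      sprintf(" Entering excited-state section for conformer %s", id),
      sprintf(" %s / %s", attr(ensemble, "functional_tag"), attr(ensemble, "phase_tag")),
      sprintf(" Excited State %3d:      Singlet-A     %8.4f eV %8.2f nm  f=%.4f",
              g$state_index, g$energy_eV, HC_EV_NM / g$energy_eV,
              g$oscillator_strength),
      " Normal termination."
    )
    writeLines(lines, path)
    path
  }, character(1))
  invisible(tibble(conformer_id = ids, path = unname(paths)))
}

#' Build a toy frame realising requested torsions
#'
#' Constructs a minimal synthetic "molecule": for each requested angle an
#' isolated four-atom quadruple whose signed dihedral equals the target
#' exactly, by placing `A = (0,1,0)`, `B = (0,0,0)`, `C = (1,0,0)` and
#' rotating `D` about the B-C axis by the target angle
#' (`D = C + (0, cos t, sin t)`).  Quadruples are offset along z so they
#' do not overlap.  Used as an exact oracle for [compute_dihedral()].
#'
#' @param dihedral_targets Named numeric vector: angle name -> target
#'   degrees in (-180, 180] (-180 is accepted and wraps to +180).
#' @return A frames tibble (one frame, index 0) with attribute `specs`,
#'   a tibble of the realised quadruples (`angle_name`, `a1`..`a4`).
#' @examples
#' f <- gen_toy_frames(c(delta = 73))
#' sp <- attr(f, "specs")
#' compute_dihedral(f, unlist(sp[1, c("a1", "a2", "a3", "a4")]))
#' @export
gen_toy_frames <- function(dihedral_targets) {
  if (is.null(names(dihedral_targets)) || any(!nzchar(names(dihedral_targets)))) {
    abort("dihedral_targets must be a named vector", class = "specens_argument_error")
  }
  rows <- list()
  specs <- list()
  for (i in seq_along(dihedral_targets)) {
    nm <- names(dihedral_targets)[i]
    t_rad <- wrap_deg(dihedral_targets[[i]]) * pi / 180
    z0 <- 10 * (i - 1)
    labs <- paste0(nm, ".", c("A", "B", "C", "D"))
    rows[[i]] <- tibble(
      frame_index = 0L, time_ps = 0,
      atom = labs,
      x = c(0, 0, 1, 1),
      y = c(1, 0, 0, cos(t_rad)),
      z = c(z0, z0, z0, z0 + sin(t_rad))
    )
    specs[[i]] <- tibble(angle_name = nm, a1 = labs[1], a2 = labs[2],
                         a3 = labs[3], a4 = labs[4])
  }
  out <- purrr::list_rbind(rows)
  structure(validate_frames(out), specs = purrr::list_rbind(specs))
}

#' Default synthetic study scenarios
#'
#' The generator's reference conditions, chosen once to mirror the kind of
#' dataset the analysis targets: a 5 ns trajectory saved every 4 ps
#' (1251 frames counting t = 0) decimated by 10 to 126 conformers; a
#' bimodal key torsion with modes at -113 and -76 degrees; a bright state
#' at 2.65 eV (f = 0.8012) referenced to the optimised-structure-like
#' dihedral of -66 degrees, with a cosine coupling of 1.2 eV and 0.02 eV
#' noise, plus two weak states.  The `"solution"` scenario differs from
#' `"gas"` in two ways: a higher torsional concentration (kappa 60 vs 12),
#' emulating the reduced conformational mobility of the solvated probe --
#' so it yields a smaller static-versus-ensemble red-shift, roughly half
#' the gas-phase one under the default seed -- and a bright-state
#' reference energy lowered to 2.25 eV, emulating the dielectric
#' red-shift of the bright transition in solution (~80 nm on the
#' optimised structure).
#'
#' @param phase `"gas"` or `"solution"`.
#' @return A list with elements `torsion`, `coupling`, `schedule`
#'   (duration_ps, save_interval_ps, stride, include_initial),
#'   `angle_name`, `functional_tag`, `phase_tag`.
#' @export
default_scenario <- function(phase = c("gas", "solution")) {
  phase <- match.arg(phase)
  list(
    torsion = torsion_model(c(-113, -76),
                            kappa = if (phase == "gas") 12 else 60,
                            weights = c(0.5, 0.5)),
    coupling = coupling_model(
      reference_energy_eV = if (phase == "gas") 2.65 else 2.25),
    schedule = list(duration_ps = 5000, save_interval_ps = 4,
                    stride = 10, include_initial = TRUE),
    angle_name = "delta",
    functional_tag = "SYN",
    phase_tag = phase
  )
}

#' Run a synthetic scenario end to end
#'
#' Generates the full-trajectory angle series for a scenario, decimates it
#' according to the schedule, and produces the conformer ensemble and
#' companion optimised record.
#'
#' @param scenario A scenario list as returned by [default_scenario()].
#' @param seed Integer seed controlling both the angle draws and the
#'   excitation noise.
#' @return A list: `angles_full` (all saved frames), `angles` (decimated,
#'   with `conformer_id`), `conf`, `opt`.
#' @export
gen_scenario_data <- function(scenario, seed = 1) {
  sch <- scenario$schedule
  times <- saved_frame_times(sch$duration_ps, sch$save_interval_ps,
                             include_initial = isTRUE(sch$include_initial))
  n <- length(times)
  angles_full <- gen_angle_series(scenario$torsion, n, seed = seed,
                                  name = scenario$angle_name,
                                  save_interval_ps = sch$save_interval_ps)
  if (!isTRUE(sch$include_initial)) {
    angles_full$time_ps <- angles_full$time_ps + sch$save_interval_ps
  }
  keep <- decimation_indices(n, sch$stride, 0) + 1L
  dec <- angles_full[keep, , drop = FALSE]
  gen <- gen_ensemble(dec, scenario$coupling, seed = seed + 1L,
                      functional_tag = scenario$functional_tag,
                      phase_tag = scenario$phase_tag)
  list(angles_full = angles_full, angles = gen$angles,
       conf = gen$conf, opt = gen$opt)
}
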