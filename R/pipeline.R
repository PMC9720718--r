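#' Default run configuration
#'
#' The resolved configuration used by [run_pipeline()] and the command-line
#' wrapper.  Values follow the reference protocol: a 5 ns trajectory saved
#' every 4 ps, decimation stride 10 (with the initial frame included),
#' 0.2 eV broadening on a 1-5 eV / 0.001 eV grid, and the two default
#' synthetic scenarios (gas and solution).  A user configuration file (YAML
#' with the same structure) or CLI flags override individual entries.
#'
#' @return A nested list of configuration values.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "specens_out",
    tags = list(functional = "SYN"),
    schedule = list(duration_ps = 5000, save_interval_ps = 4, stride = 10,
                    include_initial = TRUE),
    broadening = list(fwhm_eV = 0.2, grid_min_eV = 1, grid_max_eV = 5,
                      grid_step_eV = 0.001),
    synthetic = list(
      phases = c("gas", "solution"),
      torsion = list(centers_deg = c(-113, -76),
                     kappa = list(gas = 12, solution = 60),
                     weights = c(0.5, 0.5)),
      coupling = list(reference_energy_eV = list(gas = 2.65, solution = 2.25),
                      coupling_amplitude_eV = 1.2,
                      reference_angle_deg = -66, noise_sd_eV = 0.02,
                      bright_f0 = 0.8012)
    ),
    dihedrals = NULL,   # tibble-like list for the dihedrals subcommand
    window = NULL       # list(name, center_deg, half_width_deg)
  )
}

# Recursively merge override values into a base config.
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a run configuration file
#'
#' Reads a YAML configuration and merges it over [default_run_config()].
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @param overrides Named list merged last (e.g. parsed CLI flags).
#' @return The resolved configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(paste0("config file not found: ", path), class = "specens_io_error")
    }
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, overrides)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  b <- cfg$broadening
  do.call(broadening_params, b)  # errors on invalid broadening
  sch <- cfg$schedule
  if (sch$duration_ps < 0 || sch$save_interval_ps <= 0 || sch$stride < 1) {
    abort("invalid schedule in config", class = "specens_argument_error")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

scenario_from_config <- function(cfg, phase) {
  syn <- cfg$synthetic
  kap <- syn$torsion$kappa
  kappa <- if (is.list(kap)) kap[[phase]] %||% kap[[1]] else kap
  list(
    torsion = torsion_model(unlist(syn$torsion$centers_deg), kappa = kappa,
                            weights = unlist(syn$torsion$weights)),
    coupling = do.call(coupling_model, lapply(syn$coupling, function(v) {
      if (is.list(v)) v[[phase]] %||% v[[1]] else v  # per-phase values allowed
    })),
    schedule = cfg$schedule,
    angle_name = "delta",
    functional_tag = cfg$tags$functional,
    phase_tag = phase
  )
}

write_provenance <- function(cfg, dir) {
  yaml::write_yaml(cfg, file.path(dir, "config_resolved.yaml"))
  writeLines(paste0("specens ", as.character(packageVersion("specens"))),
             file.path(dir, "VERSION"))
}

#' Run the full synthetic analysis pipeline
#'
#' Chains the package's stages under one configuration: for every
#' configured phase, generate the scenario data (angle series, conformer
#' ensemble, optimised record), write the exchange files, reconstruct the
#' conf and opt spectra, and compute the static-versus-ensemble shift;
#' when both phases are present, derive the solvent shifts as well.  All
#' artifacts, the resolved configuration and a version string are written
#' to `cfg$out_dir`; outputs are staged and only moved into place on
#' success, so a failing run leaves no partial files.
#'
#' @param cfg A configuration list from [read_run_config()] /
#'   [default_run_config()].
#' @return Invisibly, a list with `reports` (shift-report tibble),
#'   `solvent` (solvent-shift tibble or `NULL`) and `out_dir`.
#' @export
run_pipeline <- function(cfg = default_run_config()) {
  cfg <- validate_run_config(cfg)
  stage <- file.path(tempfile("specens_stage_"))
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  params <- do.call(broadening_params, cfg$broadening)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  reports <- list()
  for (phase in cfg$synthetic$phases) {
    scen <- scenario_from_config(cfg, phase)
    dat <- gen_scenario_data(scen, seed = cfg$seed)
    pdir <- file.path(stage, phase)
    dir.create(pdir)
    readr::write_csv(dat$angles_full, file.path(pdir, "angles.csv"), progress = FALSE)
    write_state_table(dat$conf, file.path(pdir, "states.csv"))
    write_state_table(dat$opt, file.path(pdir, "states_opt.csv"))
    sp_conf <- reconstruct_spectrum(dat$conf, params)
    sp_opt <- reconstruct_spectrum(dat$opt, params)
    write_spectrum(sp_conf, file.path(pdir, "spectrum_conf.dat"))
    write_spectrum(sp_opt, file.path(pdir, "spectrum_opt.dat"))
    rep <- build_shift_report(dat$conf, dat$opt, params)
    reports[[phase]] <- rep
    say("[%s] N_p = %d, lambda_max conf %.1f nm, opt %.1f nm, dE = %.4f eV",
        phase, rep$n_conformers, rep$lambda_conf_nm, rep$lambda_opt_nm,
        rep$delta_E_eV)
    if (!is.null(cfg$window)) {
      w <- cfg$window
      sp_w <- windowed_spectrum(dat$conf, dat$angles, w$center_deg,
                                w$half_width_deg, params)
      write_spectrum(sp_w, file.path(pdir, sprintf("spectrum_window_%s.dat", w$name)))
      say("[%s] window %s %g +/- %g deg: lambda_max %.1f nm",
          phase, w$name, w$center_deg, w$half_width_deg, lambda_max(sp_w))
    }
  }
  reports <- dplyr::bind_rows(reports)
  write_shift_report(reports, file.path(stage, "shift_report.csv"))
  solvent <- NULL
  if (all(c("gas", "solution") %in% reports$phase_tag)) {
    solvent <- solvent_shift_table(reports)
    readr::write_csv(solvent, file.path(stage, "solvent_shifts.csv"), progress = FALSE)
    say("solvent shift (conf) %.1f nm, (opt) %.1f nm",
        solvent$solvent_shift_conf_nm[1], solvent$solvent_shift_opt_nm[1])
  }
  write_provenance(cfg, stage)
  writeLines(log, file.path(stage, "run.log"))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(stage, recursive = TRUE)
  for (f in files) {
    dir.create(dirname(file.path(cfg$out_dir, f)), recursive = TRUE,
               showWarnings = FALSE)
    file.copy(file.path(stage, f), file.path(cfg$out_dir, f), overwrite = TRUE)
  }
  invisible(list(reports = reports, solvent = solvent, out_dir = cfg$out_dir))
}
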