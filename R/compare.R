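#' Static-versus-ensemble peak shift in energy
#'
#' Energy difference between two absorption maxima given as wavelengths:
#' `hc * (1/lambda_opt - 1/lambda_conf)`.  With the opt-minus-conf sign
#' convention the shift is positive when the conformational-average
#' maximum is red-shifted (longer wavelength) relative to the single
#' optimised structure.
#'
#' @param lambda_opt_nm Absorption maximum of the optimised (static)
#'   structure, nm.
#' @param lambda_conf_nm Absorption maximum of the conformational average,
#'   nm.
#' @return The shift in eV (vectorised).
#' @examples
#' shift_ev(477, 523) # ~0.229 eV red-shift
#' @export
shift_ev <- function(lambda_opt_nm, lambda_conf_nm) {
  if (any(lambda_opt_nm <= 0) || any(lambda_conf_nm <= 0)) {
    abort("wavelengths must be positive", class = "specens_argument_error")
  }
  HC_EV_NM * (1 / lambda_opt_nm - 1 / lambda_conf_nm)
}

#' Gas-to-solution peak shift in wavelength
#'
#' Simple wavelength difference `lambda_solution - lambda_gas`; positive
#' values are red-shifts induced by the solvent.
#'
#' @param lambda_solution_nm,lambda_gas_nm Absorption maxima, nm.
#' @return The shift in nm (vectorised).
#' @examples
#' solvent_shift_nm(561, 477) # 84 nm
#' @export
solvent_shift_nm <- function(lambda_solution_nm, lambda_gas_nm) {
  lambda_solution_nm - lambda_gas_nm
}

#' Spectrum of a dihedral-windowed sub-ensemble
#'
#' Restricts an ensemble to the conformers whose value of a monitored
#' dihedral falls inside a circular window `center +/- half_width`, then
#' reconstructs and normalises the spectrum of that sub-ensemble.  This is
#' how the contribution of individual torsional conformations (e.g. the
#' two maxima and the optimised-structure minimum of a bimodal torsion) to
#' the full band is dissected.
#'
#' @param ensemble A `conformer_ensemble` whose `conformer_id`s appear in
#'   `angle_series`.
#' @param angle_series A data frame linking conformers to angles: columns
#'   `conformer_id` (or `frame_index`, matched against the ensemble ids)
#'   and `angle_deg`.
#' @param center_deg,half_width_deg The circular window, degrees
#'   (`half_width_deg > 0`).
#' @param params [broadening_params()] for the reconstruction.
#' @return A normalised `ens_spectrum` of the selected conformers.
#' @export
windowed_spectrum <- function(ensemble, angle_series, center_deg,
                              half_width_deg, params = broadening_params()) {
  stopifnot(is_ensemble(ensemble))
  if (half_width_deg <= 0) {
    abort("half_width_deg must be > 0", class = "specens_argument_error")
  }
  as <- as_tibble(angle_series)
  if (!"conformer_id" %in% names(as)) {
    if ("frame_index" %in% names(as)) {
      as$conformer_id <- as.character(as$frame_index)
    } else {
      abort("angle_series needs a conformer_id or frame_index column",
            class = "specens_argument_error")
    }
  }
  as$conformer_id <- as.character(as$conformer_id)
  ids <- unique(ensemble$conformer_id)
  missing <- setdiff(ids, as$conformer_id)
  if (length(missing) > 0) {
    abort(paste0("angle series does not cover conformer(s): ",
                 paste(head(missing, 3), collapse = ", ")),
          class = "specens_argument_error")
  }
  ang <- as$angle_deg[match(ids, as$conformer_id)]
  inside <- abs(circ_diff_deg(ang, center_deg)) <= half_width_deg
  if (!any(inside)) {
    nearest <- ang[order(abs(circ_diff_deg(ang, center_deg)))][seq_len(min(3, length(ang)))]
    abort(sprintf("empty window %g +/- %g deg; nearest populated angles: %s",
                  center_deg, half_width_deg,
                  paste(sprintf("%.1f", nearest), collapse = ", ")),
          class = "specens_empty_window")
  }
  sub <- new_ensemble(
    as_tibble(ensemble)[ensemble$conformer_id %in% ids[inside], ],
    functional_tag = attr(ensemble, "functional_tag"),
    phase_tag = attr(ensemble, "phase_tag"),
    source = attr(ensemble, "source")
  )
  normalize_spectrum(reconstruct_spectrum(sub, params))
}

#' Build a static-versus-ensemble shift report
#'
#' Computes the absorption maximum of the conformational-average spectrum
#' and of the single optimised structure with the same broadening, and
#' their shift in eV (opt-minus-conf convention: positive = ensemble
#' red-shifted).  Both inputs must share functional and phase tags.
#'
#' @param conf_ensemble A `conformer_ensemble` of MD-sampled conformers.
#' @param opt_record A single-conformer `conformer_ensemble` for the
#'   optimised structure.
#' @param params [broadening_params()].
#' @return A `shift_report`: a one-row tibble with columns
#'   `functional_tag`, `phase_tag`, `lambda_conf_nm`, `lambda_opt_nm`,
#'   `delta_E_eV`, `n_conformers`.  Values are stored at full precision;
#'   round only for display.
#' @export
build_shift_report <- function(conf_ensemble, opt_record,
                               params = broadening_params()) {
  stopifnot(is_ensemble(conf_ensemble), is_ensemble(opt_record))
  for (tag in c("functional_tag", "phase_tag")) {
    if (!identical(attr(conf_ensemble, tag), attr(opt_record, tag))) {
      abort(sprintf("%s mismatch between conf ('%s') and opt ('%s') inputs",
                    tag, attr(conf_ensemble, tag), attr(opt_record, tag)),
            class = "specens_validation_error")
    }
  }
  l_conf <- lambda_max(reconstruct_spectrum(conf_ensemble, params))
  l_opt <- lambda_max(reconstruct_spectrum(opt_record, params))
  rep <- tibble(
    functional_tag = attr(conf_ensemble, "functional_tag"),
    phase_tag = attr(conf_ensemble, "phase_tag"),
    lambda_conf_nm = l_conf,
    lambda_opt_nm = l_opt,
    delta_E_eV = shift_ev(l_opt, l_conf),
    n_conformers = n_conformers(conf_ensemble)
  )
  structure(rep, class = c("shift_report", class(rep)))
}

#' Combine shift reports across phases into solvent shifts
#'
#' Given shift reports for the same functional in the gas phase and in
#' solution, adds the solvent-induced red-shifts of the opt and conf
#' maxima (`lambda_solution - lambda_gas`, in nm).
#'
#' @param reports A tibble of stacked `shift_report` rows covering both
#'   phases (phase tags `"gas"` and `"solution"`).
#' @return A tibble with one row per functional and columns
#'   `solvent_shift_opt_nm`, `solvent_shift_conf_nm`.
#' @export
solvent_shift_table <- function(reports) {
  reports <- as_tibble(reports)
  wide <- reports |>
    dplyr::select("functional_tag", "phase_tag", "lambda_conf_nm", "lambda_opt_nm") |>
    tidyr::pivot_wider(names_from = "phase_tag",
                       values_from = c("lambda_conf_nm", "lambda_opt_nm"))
  needed <- c("lambda_opt_nm_gas", "lambda_opt_nm_solution",
              "lambda_conf_nm_gas", "lambda_conf_nm_solution")
  missing <- setdiff(needed, names(wide))
  if (length(missing) > 0) {
    abort("reports must cover both gas and solution phases",
          class = "specens_argument_error")
  }
  wide |>
    dplyr::mutate(
      solvent_shift_opt_nm = solvent_shift_nm(.data$lambda_opt_nm_solution,
                                              .data$lambda_opt_nm_gas),
      solvent_shift_conf_nm = solvent_shift_nm(.data$lambda_conf_nm_solution,
                                               .data$lambda_conf_nm_gas)
    )
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf(
    "<shift_report> %s/%s: lambda_max conf %.1f nm, opt %.1f nm, dE = %+.4f eV (N_p = %d)\n",
    x$functional_tag, x$phase_tag, x$lambda_conf_nm, x$lambda_opt_nm,
    x$delta_E_eV, x$n_conformers))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.shift_report <- function(x, ...) as_tibble(x)

#' Write a shift-report table
#'
#' Delimited output mirroring the standard comparison-table columns
#' (functional, phase, conf and opt maxima in nm, shift in eV).
#'
#' @param reports One `shift_report` or a tibble of stacked report rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_shift_report <- function(reports, path) {
  as_tibble(reports) |>
    dplyr::select("functional_tag", "phase_tag", "lambda_conf_nm",
                  "lambda_opt_nm", "delta_E_eV") |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}
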