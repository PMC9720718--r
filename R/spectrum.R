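#' Gaussian broadening parameters
#'
#' Parameters of the nuclear-ensemble reconstruction: every vertical
#' transition is replaced by a unit-area Gaussian of full width at half
#' maximum `fwhm_eV` (default 0.2 eV, the standard empirical broadening for
#' room-temperature ensembles of this kind) evaluated on a uniform energy
#' grid.  The default grid, 1.0-5.0 eV in 0.001 eV steps, covers the
#' visible range at a resolution far below the FWHM; the step is required
#' to be at most `fwhm_eV / 10` so the lineshape is always well resolved.
#'
#' @param fwhm_eV Full width at half maximum of the broadening Gaussian, eV.
#' @param grid_min_eV,grid_max_eV,grid_step_eV Energy grid, eV.
#' @return A `broadening_params` list.
#' @examples
#' broadening_params()
#' @export
broadening_params <- function(fwhm_eV = 0.2, grid_min_eV = 1, grid_max_eV = 5,
                              grid_step_eV = 0.001) {
  if (fwhm_eV <= 0) abort("fwhm_eV must be > 0", class = "specens_argument_error")
  if (grid_min_eV >= grid_max_eV) {
    abort("grid_min_eV must be below grid_max_eV", class = "specens_argument_error")
  }
  if (grid_step_eV <= 0 || grid_step_eV > fwhm_eV / 10) {
    abort("grid_step_eV must be positive and at most fwhm_eV / 10",
          class = "specens_argument_error")
  }
  structure(list(fwhm_eV = fwhm_eV, grid_min_eV = grid_min_eV,
                 grid_max_eV = grid_max_eV, grid_step_eV = grid_step_eV),
            class = "broadening_params")
}

#' @export
print.broadening_params <- function(x, ...) {
  cat(sprintf("<broadening_params> FWHM %g eV, grid %g-%g eV step %g eV\n",
              x$fwhm_eV, x$grid_min_eV, x$grid_max_eV, x$grid_step_eV))
  invisible(x)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Normalised Gaussian lineshape
#'
#' The unit-area Gaussian `g(E; E0, fwhm)` associated with each vertical
#' transition, with standard deviation `sigma = fwhm / (2 sqrt(2 ln 2))`.
#'
#' @param energy_eV Evaluation energies, eV.
#' @param center_eV Transition energy, eV.
#' @param fwhm_eV Full width at half maximum, eV.
#' @return Density per eV at `energy_eV`.
#' @examples
#' gaussian_lineshape(2.5, 2.5, 0.2) # peak height ~4.6986 per eV
#' @export
gaussian_lineshape <- function(energy_eV, center_eV, fwhm_eV) {
  if (fwhm_eV <= 0) abort("fwhm_eV must be > 0", class = "specens_argument_error")
  dnorm(energy_eV, mean = center_eV, sd = fwhm_to_sigma(fwhm_eV))
}

new_spectrum <- function(energy, intensity, params, ensemble = NULL,
                         normalized = FALSE, clipped = FALSE,
                         functional_tag = NULL, phase_tag = NULL,
                         n_conf = NULL) {
  sp <- tibble(energy_eV = energy, intensity = intensity)
  structure(sp,
            class = c("ens_spectrum", class(sp)),
            fwhm_eV = params$fwhm_eV,
            grid_step_eV = params$grid_step_eV,
            normalized = normalized,
            clipped = clipped,
            n_conformers = n_conf %||% if (!is.null(ensemble)) n_conformers(ensemble) else NA_integer_,
            functional_tag = functional_tag %||% if (!is.null(ensemble)) attr(ensemble, "functional_tag") else NA_character_,
            phase_tag = phase_tag %||% if (!is.null(ensemble)) attr(ensemble, "phase_tag") else NA_character_)
}

#' Reconstruct the nuclear-ensemble absorption spectrum
#'
#' Builds the absorption profile `A[E]` of an ensemble of sampled
#' geometries by summing, for every conformer `k` and every computed state
#' `L`, the unit-area Gaussian centred on the vertical excitation energy
#' and weighted by its oscillator strength, then averaging over the
#' conformers:
#'
#' `A[E] = (1/N_p) * sum_k sum_L f_kL * g(E; E_kL, fwhm)`
#'
#' where `N_p` is the number of sampled conformers.  The result is not
#' normalised; its trapezoidal area equals the conformer-mean total
#' oscillator strength when no band is clipped by the grid (see
#' [integrated_strength()]).  A warning is raised when a transition lies
#' outside the grid extended by five standard deviations.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param params A [broadening_params()] object.
#' @return An `ens_spectrum`: a tibble with columns `energy_eV` and
#'   `intensity`, carrying FWHM, grid, normalisation flag and ensemble
#'   provenance as attributes.
#' @examples
#' ens <- new_ensemble(tibble::tibble(
#'   conformer_id = "c1", state_index = 1L,
#'   energy_eV = 2.5, oscillator_strength = 1
#' ))
#' sp <- reconstruct_spectrum(ens, broadening_params(grid_min_eV = 1.5, grid_max_eV = 3.5))
#' lambda_max(sp)
#' @export
reconstruct_spectrum <- function(ensemble, params = broadening_params()) {
  stopifnot(is_ensemble(ensemble))
  if (nrow(ensemble) == 0) abort("no conformers", class = "specens_no_data")
  sigma <- fwhm_to_sigma(params$fwhm_eV)
  grid <- seq(params$grid_min_eV, params$grid_max_eV, by = params$grid_step_eV)
  clipped <- any(ensemble$energy_eV < params$grid_min_eV - 5 * sigma |
                   ensemble$energy_eV > params$grid_max_eV + 5 * sigma)
  if (clipped) {
    warn("transition(s) outside the grid by more than 5 sigma: band clipped")
  }
  np <- n_conformers(ensemble)
  a <- numeric(length(grid))
  for (i in seq_len(nrow(ensemble))) {
    a <- a + ensemble$oscillator_strength[i] *
      dnorm(grid, mean = ensemble$energy_eV[i], sd = sigma)
  }
  new_spectrum(grid, a / np, params, ensemble = ensemble, clipped = clipped)
}

#' Normalise a spectrum to unit maximum
#'
#' Divides the intensities by their maximum (the convention used when
#' overlaying spectra from different samplings or phases).  Idempotent;
#' the peak position is unchanged.
#'
#' @param spectrum An `ens_spectrum`.
#' @return The normalised `ens_spectrum` with its `normalized` flag set.
#' @export
normalize_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "ens_spectrum"))
  m <- max(spectrum$intensity)
  if (!is.finite(m) || m <= 0) {
    abort("cannot normalise an all-zero spectrum", class = "specens_argument_error")
  }
  out <- spectrum
  out$intensity <- out$intensity / m
  attr(out, "normalized") <- TRUE
  out
}

#' Wavelength of maximum absorbance
#'
#' Locates the grid argmax of the intensity, refines it by three-point
#' parabolic interpolation (the spectrum is convolved and reported on a
#' finite grid, and peak positions are quoted to 1 nm), and returns
#' `hc / E_peak`.  Exact ties are broken toward the lower energy, i.e. the
#' longer wavelength.
#'
#' @param spectrum An `ens_spectrum`.
#' @return The absorption maximum in nm.
#' @export
lambda_max <- function(spectrum) {
  HC_EV_NM / e_max(spectrum)
}

#' @rdname lambda_max
#' @return `e_max()`: the refined peak energy in eV.
#' @export
e_max <- function(spectrum) {
  stopifnot(inherits(spectrum, "ens_spectrum"))
  y <- spectrum$intensity
  if (diff(range(y)) == 0) {
    abort("flat spectrum has no defined maximum", class = "specens_argument_error")
  }
  m <- max(y)
  i <- min(which(y == m))  # tie -> lower energy (longer wavelength)
  e <- spectrum$energy_eV
  if (i > 1 && i < length(y)) {
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    offset <- if (denom < 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
    if (abs(offset) <= 0.5) {
      return(e[i] + offset * (e[2] - e[1]))
    }
  }
  e[i]
}

#' Integrated band strength
#'
#' For an unnormalised reconstructed spectrum, the trapezoidal integral
#' `int A dE`; because each transition carries a unit-area lineshape this
#' equals the conformer-mean total oscillator strength
#' `(1/N_p) sum_k sum_L f_kL` whenever every band lies inside the grid.
#' Called on an ensemble, it returns that reference value directly, so the
#' two can be compared as a consistency check of the reconstruction.
#'
#' @param x An `ens_spectrum` or a `conformer_ensemble`.
#' @return The integral (spectrum) or the mean total oscillator strength
#'   (ensemble), in eV-weighted units.  For a clipped or normalised
#'   spectrum a warning is raised and `NA` returned, since the areas are
#'   no longer comparable.
#' @export
integrated_strength <- function(x) {
  if (is_ensemble(x)) {
    return(sum(x$oscillator_strength) / n_conformers(x))
  }
  stopifnot(inherits(x, "ens_spectrum"))
  if (isTRUE(attr(x, "clipped")) || isTRUE(attr(x, "normalized"))) {
    warn("spectrum is clipped or normalised: area check skipped")
    return(NA_real_)
  }
  de <- diff(x$energy_eV)
  sum((head(x$intensity, -1) + tail(x$intensity, -1)) / 2 * de)
}

#' @export
print.ens_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ens_spectrum> %s/%s, N_p = %s, FWHM %g eV, %d grid points%s\n",
    attr(x, "functional_tag"), attr(x, "phase_tag"),
    attr(x, "n_conformers"), attr(x, "fwhm_eV"), nrow(x),
    if (isTRUE(attr(x, "normalized"))) ", normalised" else ""))
  NextMethod()
}

#' Tidy and summarise spectra
#'
#' `tidy()` returns the spectrum as a plain tibble with the wavelength
#' view added (`wavelength_nm = hc / energy_eV`, no Jacobian reweighting:
#' the convolution is defined in the energy domain).  `glance()` returns a
#' one-row summary with the absorption maximum.
#'
#' @param x An `ens_spectrum`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ens_spectrum <- function(x, ...) {
  tibble(
    energy_eV = x$energy_eV,
    wavelength_nm = HC_EV_NM / x$energy_eV,
    intensity = x$intensity
  )
}

#' @rdname tidy.ens_spectrum
#' @exportS3Method generics::glance
glance.ens_spectrum <- function(x, ...) {
  em <- e_max(x)
  tibble(
    lambda_max_nm = HC_EV_NM / em,
    e_max_eV = em,
    fwhm_eV = attr(x, "fwhm_eV"),
    n_conformers = attr(x, "n_conformers"),
    normalized = isTRUE(attr(x, "normalized")),
    functional_tag = attr(x, "functional_tag"),
    phase_tag = attr(x, "phase_tag")
  )
}

#' Plot a spectrum
#'
#' Intensity against wavelength (default) or energy, with the absorption
#' maximum marked.
#'
#' @param object An `ens_spectrum`.
#' @param axis `"wavelength"` or `"energy"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ens_spectrum <- function(object, axis = c("wavelength", "energy"), ...) {
  axis <- match.arg(axis)
  td <- tidy.ens_spectrum(object)
  lm <- lambda_max(object)
  if (axis == "wavelength") {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$wavelength_nm, y = .data$intensity)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = lm, linetype = 2, colour = "red3") +
      ggplot2::labs(x = "wavelength (nm)", y = "absorbance (arb.)",
                    subtitle = sprintf("lambda_max = %.1f nm", lm))
  } else {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$energy_eV, y = .data$intensity)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "energy (eV)", y = "absorbance (arb.)")
  }
}

#' Write a spectrum to a delimited file
#'
#' Two-column whitespace-delimited output `(energy_eV, intensity)`, or the
#' wavelength view `(wavelength_nm, intensity)`, preceded by provenance
#' header lines prefixed with `#`.
#'
#' @param spectrum An `ens_spectrum`.
#' @param path Output file.
#' @param axis `"energy"` or `"wavelength"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, axis = c("energy", "wavelength")) {
  axis <- match.arg(axis)
  stopifnot(inherits(spectrum, "ens_spectrum"))
  hdr <- c(
    sprintf("# specens spectrum (%s view)", axis),
    sprintf("# functional= %s phase= %s n_conformers= %s",
            attr(spectrum, "functional_tag"), attr(spectrum, "phase_tag"),
            attr(spectrum, "n_conformers")),
    sprintf("# fwhm_eV= %g normalized= %s", attr(spectrum, "fwhm_eV"),
            isTRUE(attr(spectrum, "normalized")))
  )
  body <- if (axis == "energy") {
    sprintf("%.6f %.10g", spectrum$energy_eV, spectrum$intensity)
  } else {
    sprintf("%.4f %.10g", HC_EV_NM / spectrum$energy_eV, spectrum$intensity)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
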