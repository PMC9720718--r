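#' Conformer ensembles of vertical excitations
#'
#' A `conformer_ensemble` holds the per-conformer vertical transitions that
#' feed the nuclear-ensemble spectrum: one row per excited state per
#' sampled geometry, with columns `conformer_id`, `state_index` (>= 1),
#' `energy_eV` (vertical excitation energy, > 0), `wavelength_nm`
#' (`hc / energy_eV`) and `oscillator_strength` (>= 0).  The level of
#' theory (`functional_tag`, e.g. `"B3LYP"`) and the phase (`phase_tag`,
#' `"gas"` or `"solution"`) are properties of the whole ensemble and are
#' stored as attributes; mixing levels of theory within one ensemble is
#' rejected.  Conformers may carry different numbers of states (some
#' protocols compute five states for most geometries and ten for a few);
#' `new_ensemble()` only warns in that case.
#'
#' @param states A data frame with columns `conformer_id`, `state_index`,
#'   `energy_eV`, `oscillator_strength`, and optionally `wavelength_nm`
#'   (filled from `energy_eV` when absent, cross-checked when present).
#'   Homogeneous `functional_tag`/`phase_tag` columns are accepted and
#'   promoted to attributes.
#' @param functional_tag,phase_tag Provenance tags for the whole ensemble.
#' @param source Free-text provenance.
#' @return A `conformer_ensemble` tibble; conformers keep their first-
#'   appearance order and states are sorted by `state_index` within each
#'   conformer.
#' @examples
#' new_ensemble(
#'   tibble::tibble(conformer_id = "c1", state_index = 1:2,
#'                  energy_eV = c(2.65, 3.1),
#'                  oscillator_strength = c(0.8, 0.02)),
#'   functional_tag = "B3LYP", phase_tag = "gas"
#' )
#' @export
new_ensemble <- function(states, functional_tag = "unknown", phase_tag = "gas",
                         source = NA_character_) {
  states <- as_tibble(states)
  needed <- c("conformer_id", "state_index", "energy_eV", "oscillator_strength")
  missing <- setdiff(needed, names(states))
  if (length(missing) > 0) {
    abort(paste0("states table lacks column(s): ", paste(missing, collapse = ", ")),
          class = "specens_argument_error")
  }
  if (nrow(states) == 0) abort("no conformers: empty states table", class = "specens_no_data")
  for (tagcol in c("functional_tag", "phase_tag")) {
    if (tagcol %in% names(states)) {
      vals <- unique(states[[tagcol]])
      if (length(vals) > 1) {
        abort(paste0("mixed ", tagcol, " values in one ensemble: ",
                     paste(vals, collapse = ", ")),
              class = "specens_validation_error")
      }
      if (tagcol == "functional_tag") functional_tag <- vals else phase_tag <- vals
      states[[tagcol]] <- NULL
    }
  }
  bad <- which(!is.finite(states$energy_eV) | states$energy_eV <= 0)
  if (length(bad) > 0) {
    abort(paste0("row ", bad[1], ": non-positive excitation energy"),
          class = "specens_validation_error")
  }
  bad <- which(!is.finite(states$oscillator_strength) | states$oscillator_strength < 0)
  if (length(bad) > 0) {
    abort(paste0("row ", bad[1], ": negative oscillator strength"),
          class = "specens_validation_error")
  }
  if ("wavelength_nm" %in% names(states)) {
    dev <- abs(states$wavelength_nm - HC_EV_NM / states$energy_eV)
    bad <- which(is.na(dev) | dev > 0.5)
    if (length(bad) > 0) {
      abort(sprintf(
        "conformer %s state %d: wavelength %.2f nm inconsistent with %.4f eV",
        states$conformer_id[bad[1]], states$state_index[bad[1]],
        states$wavelength_nm[bad[1]], states$energy_eV[bad[1]]),
        class = "specens_validation_error")
    }
  } else {
    states$wavelength_nm <- HC_EV_NM / states$energy_eV
  }
  states$conformer_id <- as.character(states$conformer_id)
  states$state_index <- as.integer(states$state_index)
  dup <- states |>
    dplyr::count(.data$conformer_id, .data$state_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate state index ", dup$state_index[1],
                 " for conformer ", dup$conformer_id[1]),
          class = "specens_validation_error")
  }
  # first-appearance conformer order, states ordered within conformer
  states <- states |>
    dplyr::mutate(.ord = match(.data$conformer_id, unique(.data$conformer_id))) |>
    dplyr::arrange(.data$.ord, .data$state_index) |>
    dplyr::select("conformer_id", "state_index", "energy_eV", "wavelength_nm",
                  "oscillator_strength")
  ns <- states |> dplyr::count(.data$conformer_id)
  if (length(unique(ns$n)) > 1) {
    warn(paste0("heterogeneous state counts across conformers: ",
                paste(sort(unique(ns$n)), collapse = ", ")))
  }
  structure(states,
            class = c("conformer_ensemble", class(states)),
            functional_tag = functional_tag,
            phase_tag = phase_tag,
            source = source)
}

#' @rdname new_ensemble
#' @param x Object to test.
#' @export
is_ensemble <- function(x) inherits(x, "conformer_ensemble")

#' Number of sampled conformers in an ensemble
#'
#' @param ensemble A `conformer_ensemble`.
#' @return Integer count of distinct conformers (the ensemble-average
#'   denominator of the spectrum reconstruction).
#' @export
n_conformers <- function(ensemble) length(unique(ensemble$conformer_id))

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d conformer(s), %d state row(s), %s / %s\n",
              n_conformers(x), nrow(x),
              attr(x, "functional_tag"), attr(x, "phase_tag")))
  NextMethod()
}

# dplyr/[ operations drop to plain tibble; re-attach class explicitly where
# needed via new_ensemble().

#' Parse excited states from quantum-chemistry log output
#'
#' Extracts vertical transitions from the excited-state summary lines of a
#' Gaussian-style TD-DFT log excerpt, of the form
#' `Excited State 3: Singlet-A 2.6500 eV 467.86 nm f=0.8012`.  Lines not
#' matching this pattern are ignored, so whole log fragments can be fed in
#' directly.  When a state index is re-printed later in the stream (as in
#' restarted or stateful jobs) the later block supersedes the earlier one.
#' Every parsed state is cross-checked for energy/wavelength consistency
#' (`|lambda - hc/E| <= 0.5` nm, the printed-precision slack).
#'
#' @param input A file path, or a character vector of log lines.
#' @param conformer_id Identifier of the geometry the calculation was run
#'   on; defaults to the file name (or `"conf"` for raw lines).
#' @param functional_tag,phase_tag,source Provenance, as in [new_ensemble()].
#' @return A single-conformer `conformer_ensemble` (a conformer record).
#' @examples
#' rec <- parse_gaussian_excited_states(c(
#'   " Excited State   1:      Singlet-A      2.6500 eV  467.86 nm  f=0.8012",
#'   " Excited State   2:      Singlet-A      3.0500 eV  406.51 nm  f=0.0210"
#' ), conformer_id = "c1")
#' bright_state(rec)
#' @export
parse_gaussian_excited_states <- function(input, conformer_id = NULL,
                                          functional_tag = "unknown",
                                          phase_tag = "gas",
                                          source = NULL) {
  if (length(input) == 1 && file.exists(input)) {
    lines <- readLines(input)
    conformer_id <- conformer_id %||% sub("\\.[^.]*$", "", basename(input))
    source <- source %||% input
  } else {
    lines <- input
    conformer_id <- conformer_id %||% "conf"
    source <- source %||% "text stream"
  }
  pat <- "Excited State\\s+([0-9]+):\\s+\\S+\\s+(\\S+)\\s+eV\\s+(\\S+)\\s+nm\\s+f=(\\S+)"
  hits <- regmatches(lines, regexec(pat, lines))
  keep <- which(lengths(hits) == 5)
  if (length(keep) == 0) {
    abort("no excited states found in input", class = "specens_no_data")
  }
  fields <- lapply(keep, function(i) hits[[i]][-1])
  num <- suppressWarnings(
    lapply(fields, function(f) as.numeric(f))
  )
  bad <- which(vapply(num, anyNA, logical(1)))
  if (length(bad) > 0) {
    abort(paste0("line ", keep[bad[1]], ": unparsable numeric field in '",
                 trimws(lines[keep[bad[1]]]), "'"),
          class = "specens_parse_error")
  }
  parsed <- tibble(
    state_index = vapply(num, function(f) as.integer(f[1]), integer(1)),
    energy_eV = vapply(num, `[[`, numeric(1), 2),
    wavelength_nm = vapply(num, `[[`, numeric(1), 3),
    oscillator_strength = vapply(num, `[[`, numeric(1), 4)
  )
  # later re-prints of a state supersede earlier ones
  parsed <- parsed |>
    dplyr::group_by(.data$state_index) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  new_ensemble(
    dplyr::mutate(parsed, conformer_id = conformer_id),
    functional_tag = functional_tag, phase_tag = phase_tag, source = source
  )
}

#' Read and write delimited state tables
#'
#' The on-disk exchange format for ensembles is a CSV with header
#' `conformer_id,state_index,energy_eV,oscillator_strength` (and optionally
#' `functional_tag,phase_tag` provenance columns, written by
#' `write_state_table()`).  `read_state_table()` groups rows into conformer
#' records preserving first-appearance order; `write_state_table()` is the
#' exact inverse.
#'
#' @param path CSV file path.
#' @param ensemble A `conformer_ensemble`.
#' @param functional_tag,phase_tag Tags used when the file carries no
#'   provenance columns.
#' @return `read_state_table()`: a `conformer_ensemble`.
#'   `write_state_table()`: `path`, invisibly.
#' @export
read_state_table <- function(path, functional_tag = NULL, phase_tag = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("conformer_id", "state_index", "energy_eV", "oscillator_strength")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    abort(paste0("state table lacks column(s): ", paste(missing, collapse = ", ")),
          class = "specens_parse_error")
  }
  args <- list(states = tab, source = path)
  if (!is.null(functional_tag)) args$functional_tag <- functional_tag
  if (!is.null(phase_tag)) args$phase_tag <- phase_tag
  do.call(new_ensemble, args)
}

#' @rdname read_state_table
#' @export
write_state_table <- function(ensemble, path) {
  stopifnot(is_ensemble(ensemble))
  ensemble |>
    as_tibble() |>
    dplyr::select("conformer_id", "state_index", "energy_eV", "oscillator_strength") |>
    dplyr::mutate(functional_tag = attr(ensemble, "functional_tag"),
                  phase_tag = attr(ensemble, "phase_tag")) |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}

#' Brightest transition of each conformer
#'
#' For each conformer record, the state with maximal oscillator strength;
#' ties are broken toward the lowest state index.  In the systems this
#' package targets a single bright excitation dominates the visible
#' absorption band, so this is the state whose energy tracks the
#' conformational coordinate.
#'
#' @param ensemble A `conformer_ensemble`.
#' @return A tibble with one row per conformer (same columns as the
#'   ensemble), in ensemble order.
#' @export
bright_state <- function(ensemble) {
  stopifnot(is_ensemble(ensemble))
  ensemble |>
    as_tibble() |>
    dplyr::mutate(.ord = match(.data$conformer_id, unique(.data$conformer_id))) |>
    dplyr::group_by(.data$.ord, .data$conformer_id) |>
    dplyr::arrange(dplyr::desc(.data$oscillator_strength), .data$state_index,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord")
}
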