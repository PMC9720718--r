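#' Trajectory frames as a tidy table
#'
#' Throughout the package a set of trajectory frames is an ordinary tibble
#' in long format with one row per atom per frame and columns
#' `frame_index` (integer, >= 0), `time_ps` (saved time in picoseconds),
#' `atom` (text label, e.g. `"C11"`, unique within a frame) and the
#' Cartesian coordinates `x`, `y`, `z` in Angstrom.  `validate_frames()`
#' checks these invariants and returns its input invisibly so it can sit in
#' a pipe.
#'
#' @param frames A frames tibble as described above.
#' @return `frames`, invisibly.
#' @examples
#' f <- tibble::tibble(
#'   frame_index = 0L, time_ps = 0,
#'   atom = c("A", "B", "C", "D"),
#'   x = c(0, 0, 1, 1), y = c(1, 0, 0, 1), z = 0
#' )
#' validate_frames(f)
#' @export
validate_frames <- function(frames) {
  needed <- c("frame_index", "time_ps", "atom", "x", "y", "z")
  missing <- setdiff(needed, names(frames))
  if (length(missing) > 0) {
    abort(paste0("frames table lacks column(s): ", paste(missing, collapse = ", ")),
          class = "specens_argument_error")
  }
  dup <- frames |>
    dplyr::count(.data$frame_index, .data$atom) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate atom label '", dup$atom[1], "' in frame ",
                 dup$frame_index[1]),
          class = "specens_argument_error")
  }
  if (any(!is.finite(frames$x) | !is.finite(frames$y) | !is.finite(frames$z))) {
    abort("non-finite coordinates in frames table", class = "specens_argument_error")
  }
  invisible(frames)
}

# Extract an n_frames x 3 coordinate matrix for one atom label, with rows in
# frame order.  Errors if the label is absent from any frame.
atom_coords <- function(frames, label, frame_order) {
  sel <- frames[frames$atom == label, , drop = FALSE]
  if (nrow(sel) == 0) {
    abort(paste0("unknown atom '", label, "'"), class = "specens_unknown_atom")
  }
  idx <- match(frame_order, sel$frame_index)
  if (anyNA(idx)) {
    abort(paste0("unknown atom '", label, "' in frame ",
                 frame_order[which(is.na(idx))[1]]),
          class = "specens_unknown_atom")
  }
  cbind(sel$x[idx], sel$y[idx], sel$z[idx])
}

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

row_norm <- function(m) sqrt(rowSums(m * m))

#' Signed dihedral angle over trajectory frames
#'
#' Computes the signed torsion angle defined by four atom labels for every
#' frame of a trajectory, using the two-plane atan2 formulation
#' `atan2((n1 x n2) . b2hat, n1 . n2)` with `n1 = b1 x b2`, `n2 = b2 x b3`
#' and bond vectors `b1 = B-A`, `b2 = C-B`, `b3 = D-C`.  The positive sense
#' is a right-hand rotation of the far bond C-D about the B->C axis away
#' from the cis (0 degree) arrangement; the cis planar geometry gives 0 and
#' the trans planar geometry +180.  Values lie in (-180, 180], with -180
#' mapped to +180.
#'
#' @param frames A frames tibble (see [validate_frames()]).
#' @param atoms Character vector of four distinct atom labels, in bonded
#'   order A-B-C-D.
#' @param name Optional name for the angle (defaults to the labels joined
#'   by dashes); stored in the `angle_name` column.
#' @return A tibble with columns `frame_index`, `time_ps`, `angle_name`,
#'   `angle_deg` (one row per frame, in frame order): an angle series.
#' @examples
#' f <- tibble::tibble(
#'   frame_index = 0L, time_ps = 0,
#'   atom = c("A", "B", "C", "D"),
#'   x = c(0, 0, 1, 1), y = c(1, 0, 0, 1), z = 0
#' )
#' compute_dihedral(f, c("A", "B", "C", "D")) # cis: 0 degrees
#' @export
compute_dihedral <- function(frames, atoms, name = NULL) {
  validate_frames(frames)
  if (length(atoms) != 4 || anyDuplicated(atoms)) {
    abort("`atoms` must be four distinct atom labels", class = "specens_argument_error")
  }
  key <- frames |> dplyr::distinct(.data$frame_index, .data$time_ps)
  ord <- key$frame_index
  A <- atom_coords(frames, atoms[1], ord)
  B <- atom_coords(frames, atoms[2], ord)
  C <- atom_coords(frames, atoms[3], ord)
  D <- atom_coords(frames, atoms[4], ord)
  b1 <- B - A
  b2 <- C - B
  b3 <- D - C
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  scale <- pmax(row_norm(b1), row_norm(b2), row_norm(b3))
  degen <- row_norm(n1) <= 1e-10 * scale^2 | row_norm(n2) <= 1e-10 * scale^2
  if (any(degen)) {
    abort(paste0("degenerate geometry (collinear atoms) for dihedral ",
                 paste(atoms, collapse = "-"), " in frame ",
                 ord[which(degen)[1]]),
          class = "specens_degenerate_geometry")
  }
  b2hat <- b2 / row_norm(b2)
  y <- rowSums(cross3(n1, n2) * b2hat)
  x <- rowSums(n1 * n2)
  tibble(
    frame_index = key$frame_index,
    time_ps = key$time_ps,
    angle_name = name %||% paste(atoms, collapse = "-"),
    angle_deg = wrap_deg(atan2(y, x) * 180 / pi)
  )
}

#' Interatomic distance over trajectory frames
#'
#' Euclidean distance in Angstrom between two labelled atoms, per frame.
#' Used e.g. to monitor the separation of the two thioether chain termini
#' of the probe (the C27-C26 interchain distance).
#'
#' @param frames A frames tibble (see [validate_frames()]).
#' @param atoms Character vector of two atom labels.
#' @param name Optional name stored in the `pair_name` column.
#' @return A tibble with columns `frame_index`, `time_ps`, `pair_name`,
#'   `distance_A`.
#' @examples
#' f <- tibble::tibble(
#'   frame_index = 0L, time_ps = 0, atom = c("P", "Q"),
#'   x = c(0, 3), y = c(0, 4), z = 0
#' )
#' compute_distance(f, c("P", "Q")) # 5 Angstrom
#' @export
compute_distance <- function(frames, atoms, name = NULL) {
  validate_frames(frames)
  if (length(atoms) != 2) {
    abort("`atoms` must be two atom labels", class = "specens_argument_error")
  }
  key <- frames |> dplyr::distinct(.data$frame_index, .data$time_ps)
  P <- atom_coords(frames, atoms[1], key$frame_index)
  Q <- atom_coords(frames, atoms[2], key$frame_index)
  tibble(
    frame_index = key$frame_index,
    time_ps = key$time_ps,
    pair_name = name %||% paste(atoms, collapse = "-"),
    distance_A = row_norm(P - Q)
  )
}

#' Default monitored torsions and distance of the probe
#'
#' The four backbone/substituent torsions monitored along the trajectories
#' of the studied fluorophore, as named atom quadruples: delta
#' (C11-C36-C32-C35), epsilon (C04-N28-C29-C07), zeta (C16-N40-C15-C37)
#' and eta (C18-N40-C15-C37), plus the interchain terminal-carbon pair
#' C27-C26.
#'
#' @return `default_dihedrals()`: a tibble with columns `angle_name`, `a1`,
#'   `a2`, `a3`, `a4`.  `default_distance_pair()`: a character vector of two
#'   labels.
#' @examples
#' default_dihedrals()
#' @export
default_dihedrals <- function() {
  tibble(
    angle_name = c("delta", "epsilon", "zeta", "eta"),
    a1 = c("C11", "C04", "C16", "C18"),
    a2 = c("C36", "N28", "N40", "N40"),
    a3 = c("C32", "C29", "C15", "C15"),
    a4 = c("C35", "C07", "C37", "C37")
  )
}

#' @rdname default_dihedrals
#' @export
default_distance_pair <- function() c("C27", "C26")

#' Compute several named dihedral series at once
#'
#' Maps [compute_dihedral()] over a table of named atom quadruples and
#' binds the resulting angle series into one long tibble.
#'
#' @param frames A frames tibble.
#' @param specs A tibble with columns `angle_name`, `a1`..`a4`; defaults to
#'   [default_dihedrals()].
#' @return A long tibble with columns `frame_index`, `time_ps`,
#'   `angle_name`, `angle_deg`.
#' @export
dihedral_series <- function(frames, specs = default_dihedrals()) {
  purrr::pmap(specs, function(angle_name, a1, a2, a3, a4, ...) {
    compute_dihedral(frames, c(a1, a2, a3, a4), name = angle_name)
  }) |> purrr::list_rbind()
}

#' Read and write multi-frame XYZ trajectories
#'
#' `read_xyz_frames()` parses the standard multi-frame XYZ dialect: for
#' each frame an atom-count line, a comment line (a `t= <ps>` token, if
#' present, is taken as the saved time), then one `label x y z` line per
#' atom.  Labels are kept verbatim as atom identifiers.
#' `write_xyz_frames()` is the inverse.
#'
#' @param path File path.
#' @param frames A frames tibble (see [validate_frames()]).
#' @return `read_xyz_frames()`: a frames tibble with `frame_index` numbered
#'   from 0 in file order.  `write_xyz_frames()`: `path`, invisibly.
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  fi <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) {
      abort(paste0("line ", i, ": expected an atom count"), class = "specens_parse_error")
    }
    if (i + 1L + n > length(lines)) {
      abort(paste0("truncated frame starting at line ", i), class = "specens_parse_error")
    }
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
    time_ps <- if (length(tm) == 2) as.numeric(tm[2]) else NA_real_
    body <- lines[(i + 2L):(i + 1L + n)]
    fields <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(fields) < 4)
    if (length(bad) > 0) {
      abort(paste0("line ", i + 1L + bad[1], ": expected 'label x y z'"),
            class = "specens_parse_error")
    }
    m <- vapply(fields, function(f) as.numeric(f[2:4]), numeric(3))
    out[[length(out) + 1L]] <- tibble(
      frame_index = fi, time_ps = time_ps,
      atom = vapply(fields, `[[`, character(1), 1L),
      x = m[1, ], y = m[2, ], z = m[3, ]
    )
    fi <- fi + 1L
    i <- i + 2L + n
  }
  if (length(out) == 0) abort("no frames found", class = "specens_parse_error")
  validate_frames(purrr::list_rbind(out))
}

#' @rdname read_xyz_frames
#' @export
write_xyz_frames <- function(frames, path) {
  validate_frames(frames)
  con <- file(path, "w")
  on.exit(close(con))
  frames |>
    dplyr::group_by(.data$frame_index) |>
    dplyr::group_walk(function(g, key) {
      t <- g$time_ps[1]
      writeLines(c(
        as.character(nrow(g)),
        sprintf("frame %d t= %.6g ps", key$frame_index, t),
        sprintf("%s %.8f %.8f %.8f", g$atom, g$x, g$y, g$z)
      ), con)
    })
  invisible(path)
}
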