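#' Circular histogram of a dihedral-angle series
#'
#' Bins an angle series on the circle and normalises to a unit circular
#' integral, so that `sum(density * bin_width) == 1`.  Bin centers sit at
#' `-180 + k * bin_width` (integers for the default 1 degree width, matching
#' the granularity at which torsional maxima are reported); the -180/+180
#' seam is one bin, with -180 identified with +180.
#'
#' @param series An angle series: a data frame with a column of angles in
#'   degrees in (-180, 180] (by default `angle_deg`, as produced by
#'   [compute_dihedral()] or [gen_angle_series()]), or a bare numeric
#'   vector.
#' @param bin_width Bin width in degrees; must divide 360 evenly.  Default 1.
#' @param col Name of the angle column when `series` is a data frame.
#' @return An `angular_distribution`: a tibble with columns `bin_center`
#'   (degrees in (-180, 180]) and `density` (per degree), carrying the bin
#'   width, sample size and angle name as attributes.
#' @examples
#' h <- angular_histogram(tibble::tibble(angle_deg = c(-76, -76.2, -75.9)))
#' sum(h$density) * attr(h, "bin_width")
#' @export
angular_histogram <- function(series, bin_width = 1, col = "angle_deg") {
  values <- if (is.data.frame(series)) {
    if (!col %in% names(series)) {
      abort(paste0("no '", col, "' column in series"), class = "specens_argument_error")
    }
    series[[col]]
  } else {
    as.numeric(series)
  }
  if (length(values) == 0) abort("no data: empty angle series", class = "specens_no_data")
  if (bin_width <= 0 || abs(360 / bin_width - round(360 / bin_width)) > 1e-9) {
    abort("bin_width must be positive and divide 360 evenly",
          class = "specens_argument_error")
  }
  n_bins <- as.integer(round(360 / bin_width))
  values <- wrap_deg(values)
  idx <- round((values + 180) / bin_width) %% n_bins  # 0 .. n_bins-1; 0 is the +180 bin
  idx[idx == 0] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  dist <- tibble(
    bin_center = -180 + seq_len(n_bins) * bin_width,
    density = counts / (length(values) * bin_width)
  )
  structure(dist,
            class = c("angular_distribution", class(dist)),
            bin_width = bin_width,
            n = length(values),
            angle_name = if (is.data.frame(series) && "angle_name" %in% names(series)) {
              series$angle_name[1]
            } else NA_character_)
}

#' Modes of a circular angular distribution
#'
#' Detects local maxima of the binned circular density: bins at least as
#' high as both circular neighbours and strictly higher than one of them,
#' with density at least `min_prominence_fraction` of the global maximum.
#' Candidates closer than `min_separation_deg` on the circle are merged,
#' keeping the denser one.  A flat (e.g. uniform) density yields no modes.
#' Each mode's position uncertainty is reported as plus/minus half a bin
#' width, the histogram's resolution.
#'
#' @param dist An `angular_distribution` from [angular_histogram()].
#' @param min_separation_deg Minimum circular separation between reported
#'   modes, degrees.  Default 20.
#' @param min_prominence_fraction Discard candidates below this fraction of
#'   the maximum density.  Default 0.1.
#' @param smooth_deg Half-width, in degrees, of the triangular kernel used
#'   to smooth the binned density before peak detection (circular
#'   convolution; the kernel is symmetric so an isolated spike stays on its
#'   bin and a uniform density stays flat).  Finite-sample bin noise
#'   otherwise jitters and splits maxima.  Set to 0 to detect on the raw
#'   bins.  Default 5.
#' @return A tibble with columns `center_deg`, `half_width_deg` and
#'   `density` (the smoothed density at the mode), sorted by density
#'   descending.
#' @examples
#' h <- angular_histogram(rep(-76, 100))
#' find_modes(h) # one mode at -76
#' @export
find_modes <- function(dist, min_separation_deg = 20, min_prominence_fraction = 0.1,
                       smooth_deg = 5) {
  if (!inherits(dist, "angular_distribution")) {
    abort("`dist` must come from angular_histogram()", class = "specens_argument_error")
  }
  d <- dist$density
  n <- length(d)
  k <- round(smooth_deg / attr(dist, "bin_width"))
  if (k >= 1 && n > 2 * k + 1) {
    w <- (k + 1) - abs(seq(-k, k))  # triangular kernel
    w <- w / sum(w)
    idx <- outer(seq_len(n), seq(-k, k), function(i, j) ((i + j - 1) %% n) + 1)
    d <- as.vector(matrix(d[idx], nrow = n) %*% w)
  }
  left <- d[c(n, seq_len(n - 1))]
  right <- d[c(seq_len(n - 1) + 1, 1)]
  cand <- which(d >= left & d >= right & (d > left | d > right) &
                  d >= min_prominence_fraction * max(d) & d > 0)
  bw <- attr(dist, "bin_width")
  if (length(cand) == 0) {
    return(tibble(center_deg = numeric(0), half_width_deg = numeric(0),
                  density = numeric(0)))
  }
  cand <- cand[order(-d[cand], dist$bin_center[cand])]
  kept <- integer(0)
  for (i in cand) {
    sep <- abs(circ_diff_deg(dist$bin_center[i], dist$bin_center[kept]))
    if (length(kept) == 0 || all(sep >= min_separation_deg)) kept <- c(kept, i)
  }
  tibble(
    center_deg = dist$bin_center[kept],
    half_width_deg = bw / 2,
    density = d[kept]
  )
}

#' @export
print.angular_distribution <- function(x, ...) {
  cat(sprintf("<angular_distribution> %s: %d bins of %g deg, n = %d\n",
              attr(x, "angle_name") %||% "angle",
              nrow(x), attr(x, "bin_width"), attr(x, "n")))
  NextMethod()
}

#' Plot an angular distribution
#'
#' Line plot of the circular density against the bin center, with detected
#' modes marked.
#'
#' @param object An `angular_distribution`.
#' @param modes Optional mode table from [find_modes()]; computed with
#'   defaults when `NULL`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.angular_distribution <- function(object, modes = NULL, ...) {
  modes <- modes %||% find_modes(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, by = 60)) +
    ggplot2::labs(x = "dihedral angle (deg)", y = "density (1/deg)",
                  title = attr(object, "angle_name"))
  if (nrow(modes) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = modes$center_deg, linetype = 2,
                                 colour = "red3")
  }
  p
}
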