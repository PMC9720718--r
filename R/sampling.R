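#' Saved-frame times of a sampling schedule
#'
#' Times at which a production trajectory of a given length writes
#' coordinates: `k * save_interval_ps` for `k = 1 .. floor(duration /
#' save_interval)`, with the initial t = 0 frame prepended when
#' `include_initial` is set.  The reference protocol (a 5 ns accumulation
#' run saved every 4 ps) yields 1250 post-initial frames, or 1251 frames
#' counting the initial configuration.
#'
#' @param duration_ps Trajectory length in ps (>= 0).
#' @param save_interval_ps Interval between saved frames in ps (> 0);
#'   default 4.
#' @param include_initial Prepend the t = 0 frame?  Default `FALSE`.
#' @return A numeric vector of times in ps.
#' @examples
#' length(saved_frame_times(5000, 4)) # 1250
#' length(saved_frame_times(5000, 4, include_initial = TRUE)) # 1251
#' @export
saved_frame_times <- function(duration_ps, save_interval_ps = 4, include_initial = FALSE) {
  if (duration_ps < 0) abort("duration_ps must be >= 0", class = "specens_argument_error")
  if (save_interval_ps <= 0) abort("save_interval_ps must be > 0", class = "specens_argument_error")
  n <- floor(duration_ps / save_interval_ps + 1e-9)
  times <- if (n >= 1) seq_len(n) * save_interval_ps else numeric(0)
  if (include_initial) times <- c(0, times)
  times
}

#' Equispaced decimation of saved frames
#'
#' Zero-based indices of the frames kept when extracting one configuration
#' for every `stride`, starting at `offset`: `offset, offset + stride, ...`
#' below `n_frames`.  With the full 1251-frame convention (t = 0 plus 1250
#' saves) and stride 10, 126 conformers are extracted.
#'
#' @param n_frames Number of saved frames (>= 0).
#' @param stride Keep one frame in every `stride` (integer >= 1); default 10.
#' @param offset First kept index (0 <= offset < stride); default 0.
#' @return An integer vector of ascending zero-based indices.
#' @examples
#' length(decimation_indices(1251, 10)) # 126
#' @export
decimation_indices <- function(n_frames, stride = 10, offset = 0) {
  if (n_frames < 0) abort("n_frames must be >= 0", class = "specens_argument_error")
  if (stride < 1 || stride != floor(stride)) {
    abort("stride must be an integer >= 1", class = "specens_argument_error")
  }
  if (offset < 0 || offset >= stride) {
    abort("offset must satisfy 0 <= offset < stride", class = "specens_argument_error")
  }
  if (n_frames <= offset) return(integer(0))
  as.integer(seq.int(offset, n_frames - 1, by = stride))
}
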