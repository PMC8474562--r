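#' PET time-frame binning scheme
#'
#' A frame scheme describes how a dynamic PET acquisition is binned into
#' contiguous time frames. The default corresponds to a 120-minute dynamic
#' acquisition reconstructed into 20 frames: 1 x 120 s, 2 x 60 s, 3 x 120 s,
#' 6 x 300 s and 8 x 600 s.
#'
#' @param groups A two-column matrix or data frame: `count` (number of frames)
#'   and `duration_s` (frame duration in seconds), or a list of `c(count,
#'   duration_s)` pairs.
#' @return An object of class `frame_scheme` with elements `frame_start_s`,
#'   `frame_end_s`, `frame_mid_s`, `frame_dur_s` and `n_frames`. Frames are
#'   contiguous from time 0.
#' @examples
#' sch <- default_frame_scheme()
#' sch$n_frames        # 20
#' max(sch$frame_end_s) # 7200
#' @export
frame_scheme <- function(groups) {
  if (is.list(groups) && !is.data.frame(groups)) {
    groups <- do.call(rbind, groups)
  }
  groups <- as.matrix(groups)
  if (ncol(groups) != 2) stopf("'groups' must have two columns: count, duration_s")
  counts <- as.integer(groups[, 1])
  durs <- as.numeric(groups[, 2])
  if (any(counts < 1) || any(durs <= 0)) stopf("frame counts must be >= 1 and durations > 0")
  frame_dur <- rep(durs, counts)
  frame_end <- cumsum(frame_dur)
  frame_start <- c(0, frame_end[-length(frame_end)])
  structure(list(
    groups = data.frame(count = counts, duration_s = durs),
    frame_start_s = frame_start,
    frame_end_s = frame_end,
    frame_mid_s = (frame_start + frame_end) / 2,
    frame_dur_s = frame_dur,
    n_frames = length(frame_dur),
    total_s = frame_end[length(frame_end)]
  ), class = "frame_scheme")
}

#' @rdname frame_scheme
#' @export
default_frame_scheme <- function() {
  frame_scheme(list(c(1, 120), c(2, 60), c(3, 120), c(6, 300), c(8, 600)))
}

#' @export
print.frame_scheme <- function(x, ...) {
  cat(sprintf("PET frame scheme: %d frames, %.0f s total\n", x$n_frames, x$total_s))
  for (i in seq_len(nrow(x$groups))) {
    cat(sprintf("  %d x %.0f s\n", x$groups$count[i], x$groups$duration_s[i]))
  }
  invisible(x)
}
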