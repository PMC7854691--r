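#' Standard 400 m track geometry
#'
#' Describes the running track as a curvature function of distance from the
#' start: alternating half-circle bends and straights. On a standard outdoor
#' track a lap is 400 m, with two 84 m straights and two 116 m bends, and the
#' bend curvature is `1 / 36.5` per metre. 10,000 m races start at the
#' beginning of a bend, so the default `start_segment` is `"bend"`.
#'
#' `race_distance` need not be a whole number of laps (the default 10,000 m
#' is exactly 25 laps); the last segment is truncated if it is not. A
#' bend-free course for testing can be obtained with `bend_radius = Inf`,
#' which keeps the segmentation but makes the curvature zero everywhere.
#'
#' @param lap_length Lap length in metres.
#' @param straight_length Length of each straight in metres.
#' @param bend_length Length of each bend in metres. Must satisfy
#'   `2 * (straight_length + bend_length) == lap_length`.
#' @param bend_radius Radius of the bends in metres. `Inf` gives a
#'   curvature-free course.
#' @param race_distance Total race distance in metres.
#' @param start_segment `"bend"` (default, as for 10,000 m races) or
#'   `"straight"`.
#'
#' @return An object of class `track_geometry`.
#' @examples
#' trk <- track_geometry()
#' curvature_at(trk, 0)     # first bend
#' curvature_at(trk, 116)   # first straight
#' @export
track_geometry <- function(lap_length = 400,
                           straight_length = 84,
                           bend_length = 116,
                           bend_radius = 36.5,
                           race_distance = 10000,
                           start_segment = c("bend", "straight")) {
  start_segment <- match.arg(start_segment)
  if (!isTRUE(all.equal(2 * (straight_length + bend_length), lap_length))) {
    abort("2 * (straight_length + bend_length) must equal lap_length")
  }
  if (!(bend_radius > 0)) abort("bend_radius must be > 0")
  if (!(race_distance > 0)) abort("race_distance must be > 0")
  structure(
    list(
      lap_length = lap_length,
      straight_length = straight_length,
      bend_length = bend_length,
      bend_radius = bend_radius,
      race_distance = race_distance,
      start_segment = start_segment
    ),
    class = "track_geometry"
  )
}

#' @export
print.track_geometry <- function(x, ...) {
  cat(sprintf(
    "<track_geometry> %g m race on %g m laps (%g m bends R = %g m, %g m straights), starts on a %s\n",
    x$race_distance, x$lap_length, x$bend_length, x$bend_radius,
    x$straight_length, x$start_segment
  ))
  invisible(x)
}

#' Curvature at a distance from the start
#'
#' Curvature of the running line at distance `s` from the start:
#' `1 / bend_radius` on bends, `0` on straights. Distances are reduced
#' modulo the lap length, so the function is periodic. Segments are
#' half-open `[start, end)`.
#'
#' @param track A [track_geometry()].
#' @param s Distance(s) from the start in metres, in
#'   `[0, race_distance]`.
#' @return Curvature in 1/m, vectorised over `s`.
#' @export
curvature_at <- function(track, s) {
  stopifnot(inherits(track, "track_geometry"))
  if (any(s < 0 | s > track$race_distance)) {
    abort("s must lie in [0, race_distance]")
  }
  sm <- s %% track$lap_length
  half <- track$bend_length + track$straight_length
  pos <- sm %% half
  first_half <- if (track$start_segment == "bend") {
    pos < track$bend_length
  } else {
    pos >= track$straight_length
  }
  ifelse(first_half, 1 / track$bend_radius, 0)
}

#' Bend/straight segmentation of the race
#'
#' Splits `[0, race_distance]` into the alternating bend and straight
#' segments crossed during the race: a contiguous, non-overlapping,
#' half-open cover starting with the track's `start_segment`. Over the
#' default 10,000 m race this yields 50 bends and 50 straights.
#'
#' @param track A [track_geometry()].
#' @return A tibble with columns `start_m`, `end_m`, `type`
#'   (`"bend"`/`"straight"`).
#' @export
segment_boundaries <- function(track) {
  stopifnot(inherits(track, "track_geometry"))
  lens <- if (track$start_segment == "bend") {
    c(track$bend_length, track$straight_length)
  } else {
    c(track$straight_length, track$bend_length)
  }
  types <- if (track$start_segment == "bend") {
    c("bend", "straight")
  } else {
    c("straight", "bend")
  }
  n_rep <- ceiling(track$race_distance / sum(lens)) + 1
  ends <- cumsum(rep(lens, n_rep))
  starts <- c(0, ends[-length(ends)])
  type <- rep(types, n_rep)
  keep <- starts < track$race_distance
  starts <- starts[keep]; ends <- ends[keep]; type <- type[keep]
  ends[length(ends)] <- min(ends[length(ends)], track$race_distance)
  tibble::tibble(start_m = starts, end_m = ends, type = type)
}

#' Total distance run on bends or straights
#'
#' @param track A [track_geometry()].
#' @param type `"bend"` or `"straight"`.
#' @return Total length in metres of segments of the requested type. For the
#'   default 10,000 m race this is 5,800 m of bends and 4,200 m of straights.
#' @export
total_distance_by_type <- function(track, type = c("bend", "straight")) {
  type <- match.arg(type)
  seg <- segment_boundaries(track)
  sum(seg$end_m[seg$type == type] - seg$start_m[seg$type == type])
}

#' Export the segmentation as CSV
#'
#' Writes the bend/straight segmentation to a 3-column CSV
#' (`start_m`, `end_m`, `type`).
#'
#' @param track A [track_geometry()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(track, path) {
  write.csv(as.data.frame(segment_boundaries(track)), path, row.names = FALSE)
  invisible(path)
}
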