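#' Construct a split series
#'
#' A split series records, for each fixed-length segment of the race (100 m
#' by default), the time `T_k` taken and the mean speed
#' `v_k = segment_length / T_k` — the observable that championship split
#' data provide and that the model is fitted to.
#'
#' @param times Per-segment times `T_k` in seconds.
#' @param segment_length Segment length in metres.
#' @return A `split_series`: a tibble with columns `segment_index`,
#'   `distance_end_m`, `time_s`, `mean_speed_mps` and attributes
#'   `segment_length` and `race_distance`.
#' @export
split_series <- function(times, segment_length = 100) {
  if (any(times <= 0)) abort("split times must be positive")
  n <- length(times)
  out <- tibble::tibble(
    segment_index = seq_len(n),
    distance_end_m = segment_length * seq_len(n),
    time_s = as.numeric(times),
    mean_speed_mps = segment_length / as.numeric(times)
  )
  structure(
    out,
    class = c("split_series", class(out)),
    segment_length = segment_length,
    race_distance = segment_length * n
  )
}

#' @export
print.split_series <- function(x, ...) {
  cat(sprintf(
    "<split_series> %d x %g m segments, total %s (%.2f s)\n",
    nrow(x), attr(x, "segment_length"),
    format_race_time(sum(x$time_s)), sum(x$time_s)
  ))
  NextMethod()
}

# elapsed time at arbitrary distances, exact for the piecewise-linear
# speed profile of a trajectory grid
elapsed_time_at <- function(traj_s, traj_v, query_s) {
  n <- length(traj_s)
  tcum <- time_quadrature(traj_s, traj_v)
  k <- findInterval(query_s, traj_s, rightmost.closed = TRUE)
  k[k >= n] <- n - 1
  k[k < 1] <- 1
  s1 <- traj_s[k]; s2 <- traj_s[k + 1]
  v1 <- traj_v[k]; v2 <- traj_v[k + 1]
  h <- s2 - s1
  m <- (v2 - v1) / h
  x <- query_s - s1
  vx <- v1 + m * x
  partial <- ifelse(abs(v2 - v1) > 1e-9 * (v1 + v2) / 2,
                    log(vx / v1) / m,
                    x / ((v1 + vx) / 2))
  tcum[k] + partial
}

#' Compute 100 m splits from a trajectory
#'
#' The time for the k-th segment is the quadrature of `1/v(s)` over that
#' segment, evaluated exactly for the piecewise-linear speed profile on
#' the trajectory grid; the mean speed is `segment_length / T_k`. Split
#' times are additive, so they sum to the trajectory's final time.
#'
#' @param traj A `race_trajectory` from [solve_race()] (or any tibble with
#'   columns `s_m` and `v_mps` covering the race).
#' @param segment_length Segment length in metres; must divide the race
#'   distance.
#' @return A [split_series()].
#' @export
compute_splits <- function(traj, segment_length = 100) {
  s <- traj$s_m
  v <- traj$v_mps
  D <- max(s)
  if (min(s) > 0) abort("trajectory must start at s = 0")
  n_seg <- D / segment_length
  if (abs(n_seg - round(n_seg)) > 1e-9) {
    abort("segment_length must divide the race distance")
  }
  n_seg <- round(n_seg)
  if (max(diff(s)) > segment_length) {
    abort("trajectory grid is coarser than the requested segments")
  }
  marks <- segment_length * (0:n_seg)
  tm <- elapsed_time_at(s, v, marks)
  split_series(diff(tm), segment_length = segment_length)
}

#' Read and write split-series CSV files
#'
#' The on-disk format has a header
#' `segment_index,distance_end_m,time_s,mean_speed_mps`. The reader
#' validates the file (positive times, contiguous equally spaced
#' distances, consistent indices), names the offending row in its errors,
#' recomputes the mean speeds from the times, and warns if the stored
#' speeds disagree by more than 0.1%. Round-tripping a series through
#' `write_splits()`/`read_splits()` is lossless to better than 1e-9.
#'
#' @param path CSV file path.
#' @param race_distance Optional expected race distance (m); if given, the
#'   reader errors when the file does not cover it.
#' @return `read_splits()` returns a [split_series()];
#'   `write_splits()` returns `path` invisibly.
#' @export
read_splits <- function(path, race_distance = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- read.csv(path)
  needed <- c("segment_index", "distance_end_m", "time_s", "mean_speed_mps")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("splits file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) abort("splits file has no rows")
  bad <- which(!(df$time_s > 0))
  if (length(bad) > 0) {
    abort(sprintf("non-positive time_s at row %d", bad[1]))
  }
  if (any(diff(df$distance_end_m) <= 0)) {
    abort(sprintf("non-monotone distance_end_m at row %d",
                  which(diff(df$distance_end_m) <= 0)[1] + 1))
  }
  seg_len <- df$distance_end_m[1]
  expected <- seg_len * seq_len(nrow(df))
  off <- which(abs(df$distance_end_m - expected) > 1e-6)
  if (length(off) > 0) {
    abort(sprintf("distance_end_m at row %d is not contiguous (expected %g)",
                  off[1], expected[off[1]]))
  }
  if (!is.null(race_distance)) {
    n_expected <- round(race_distance / seg_len)
    if (nrow(df) != n_expected) {
      abort(sprintf("expected %d rows for a %g m race, found %d",
                    n_expected, race_distance, nrow(df)))
    }
  }
  out <- split_series(df$time_s, segment_length = seg_len)
  rel <- abs(out$mean_speed_mps - df$mean_speed_mps) / out$mean_speed_mps
  if (any(rel > 1e-3)) {
    warn(sprintf(
      "stored mean_speed_mps disagrees with segment_length/time_s by up to %.2g%% (first at row %d); recomputed values are used",
      100 * max(rel), which(rel > 1e-3)[1]
    ))
  }
  out
}

#' @rdname read_splits
#' @param series A [split_series()].
#' @export
write_splits <- function(series, path) {
  stopifnot(inherits(series, "split_series"))
  df <- as.data.frame(series)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a tactical speed corridor from observed splits
#'
#' Championship racing is tactical: simulated optimal pacing is confined
#' to a corridor around the (smoothed) observed speed profile, wide where
#' the athlete was free-running and tight where a strategic speed is
#' imposed (the start surge and the mid-race surge). The centreline is a
#' centred moving average of the observed mean speeds (truncated at the
#' edges); bounds are `centreline +/- delta_wide`, overridden to
#' `+/- delta_tight` inside the tight windows. Bounds are piecewise
#' constant per split segment.
#'
#' @param observed A [split_series()].
#' @param smooth_window Moving-average window in segments.
#' @param delta_wide Half-width of the wide bounds (m/s).
#' @param tight_windows List of `c(start_m, end_m)` windows where the
#'   tight bounds apply; must not overlap.
#' @param delta_tight Half-width inside tight windows (m/s).
#' @return A `speed_corridor`: a tibble with columns `start_m`, `end_m`,
#'   `v_lo`, `v_hi` and attribute `race_distance`.
#' @export
build_corridor <- function(observed,
                           smooth_window = 4,
                           delta_wide = 0.3,
                           tight_windows = list(c(0, 200), c(4000, 6000)),
                           delta_tight = 0.1) {
  stopifnot(inherits(observed, "split_series"))
  n <- nrow(observed)
  if (n < smooth_window) {
    abort("observed must have at least smooth_window segments")
  }
  if (length(tight_windows) > 1) {
    tw <- do.call(rbind, tight_windows)
    tw <- tw[order(tw[, 1]), , drop = FALSE]
    if (any(tw[-1, 1] < tw[-nrow(tw), 2])) {
      abort("tight_windows must not overlap")
    }
  }
  v <- observed$mean_speed_mps
  back <- floor((smooth_window - 1) / 2)
  fwd <- floor(smooth_window / 2)
  centre <- vapply(seq_len(n), function(i) {
    mean(v[max(1, i - back):min(n, i + fwd)])
  }, numeric(1))
  seg_len <- attr(observed, "segment_length")
  start_m <- seg_len * (seq_len(n) - 1)
  end_m <- seg_len * seq_len(n)
  mid <- (start_m + end_m) / 2
  delta <- rep(delta_wide, n)
  for (w in tight_windows) {
    delta[mid > w[1] & mid < w[2]] <- delta_tight
  }
  corridor <- tibble::tibble(
    start_m = start_m, end_m = end_m,
    v_lo = centre - delta, v_hi = centre + delta
  )
  structure(
    corridor,
    class = c("speed_corridor", class(corridor)),
    race_distance = attr(observed, "race_distance")
  )
}

#' @export
print.speed_corridor <- function(x, ...) {
  cat(sprintf(
    "<speed_corridor> %d segments over %g m, speed %.2f-%.2f m/s\n",
    nrow(x), max(x$end_m), min(x$v_lo), max(x$v_hi)
  ))
  NextMethod()
}

#' Export a corridor as CSV
#'
#' @param corridor A `speed_corridor`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corridor <- function(corridor, path) {
  stopifnot(inherits(corridor, "speed_corridor"))
  write.csv(as.data.frame(corridor), path, row.names = FALSE)
  invisible(path)
}
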