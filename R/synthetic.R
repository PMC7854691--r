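#' Built-in tactic templates
#'
#' Championship 10,000 m races are not evenly paced: typical profiles show
#' a fast start, a slightly slower variable cruise, a strategic surge
#' between about 4,000 and 6,000 m, a lull, and an endspurt from about
#' 7,000 m with a very fast last lap. A *tactic template* encodes such a
#' shape as a piecewise-constant target-speed multiplier (relative to the
#' race-mean speed) plus the windows in which the corridor bounds are
#' tight (strategically imposed speeds).
#'
#' Three templates are provided:
#' * `even` — flat profile, wide bounds everywhere;
#' * `championship_surge` — fast start, cruise, +2% surge at
#'   4,000-6,000 m, lull, endspurt from 7,000 m, fast last 400 m;
#' * `fast_finish` — even cruise with a monotone speed increase after
#'   7,000 m.
#'
#' Multipliers are harmonically normalised so the template's total race
#' time at multiplier 1 equals the time at the mean speed.
#'
#' @return A named list of `tactic_template` objects with fields
#'   `name`, `profile` (tibble `start_m`, `end_m`, `rel_speed`),
#'   `tight_windows`, `delta_wide`, `delta_tight`.
#' @export
default_tactics <- function() {
  mk <- function(name, breaks, rel, tight_windows,
                 delta_wide = 0.3, delta_tight = 0.1) {
    profile <- tibble::tibble(
      start_m = breaks[-length(breaks)],
      end_m = breaks[-1],
      rel_speed = rel
    )
    # harmonic normalisation: time at mean pace is preserved
    wts <- (profile$end_m - profile$start_m) / max(profile$end_m)
    profile$rel_speed <- profile$rel_speed / (1 / sum(wts / profile$rel_speed))
    structure(
      list(name = name, profile = profile, tight_windows = tight_windows,
           delta_wide = delta_wide, delta_tight = delta_tight),
      class = "tactic_template"
    )
  }
  list(
    even = mk(
      "even",
      breaks = c(0, 10000),
      rel = 1,
      tight_windows = list()
    ),
    championship_surge = mk(
      "championship_surge",
      breaks = c(0, 200, 4000, 6000, 7000, 7800, 8600, 9600, 10000),
      rel = c(1.05, 0.993, 1.02, 0.985, 1.0, 1.015, 1.03, 1.07),
      tight_windows = list(c(0, 200), c(4000, 6000))
    ),
    fast_finish = mk(
      "fast_finish",
      breaks = c(0, 7000, 7800, 8600, 9400, 10000),
      rel = c(0.99, 1.01, 1.025, 1.04, 1.06),
      tight_windows = list()
    )
  )
}

#' @export
print.tactic_template <- function(x, ...) {
  cat(sprintf("<tactic_template> '%s' (%d pieces, %d tight windows)\n",
              x$name, nrow(x$profile), length(x$tight_windows)))
  invisible(x)
}

# cruise-pace estimate from the energy balance: sustained running at speed
# v costs v^2/tau per unit time against the plateau aerobic supply
# sigma_max plus the anaerobic store spread over the race, so
# D*v/tau = e0 + sigma_max*D/v. (The start ramp and final drop of the
# aerobic curve shave only a few J/kg off the effective store and are
# ignored here.) This matches the cruise speed of unconstrained
# minimum-time solves to within ~0.1%.
cruise_pace_estimate <- function(params, D) {
  sm <- params$sigma$sigma_max
  (params$e0 + sqrt(params$e0^2 + 4 * sm * D^2 / params$tau)) /
    (2 * D / params$tau)
}

#' Build a speed corridor from a tactic template
#'
#' Anchors the template's relative speed profile at an absolute pace
#' estimated from the runner's energy balance (anaerobic store plus mean
#' aerobic power against the friction cost `v^2/tau`), then applies the
#' template's wide/tight bounds per 100 m segment.
#'
#' @param tactic A `tactic_template` (see [default_tactics()]) or the name
#'   of a built-in template.
#' @param params A [runner_params()].
#' @param track A [track_geometry()].
#' @param segment_length Corridor resolution in metres.
#' @param pace_margin Multiplier applied to the estimated cruise pace; the
#'   default 0.995 leaves a small reserve so that shaped profiles (which
#'   cost more than even pacing at the same mean) remain feasible.
#' @return A `speed_corridor`.
#' @export
tactic_corridor <- function(tactic, params, track,
                            segment_length = 100, pace_margin = 0.995) {
  if (is.character(tactic)) {
    tactics <- default_tactics()
    if (!tactic %in% names(tactics)) {
      abort(sprintf("unknown tactic '%s' (have: %s)", tactic,
                    paste(names(tactics), collapse = ", ")))
    }
    tactic <- tactics[[tactic]]
  }
  stopifnot(inherits(tactic, "tactic_template"))
  D <- track$race_distance
  vbar <- pace_margin * cruise_pace_estimate(params, D)
  n <- round(D / segment_length)
  start_m <- segment_length * (0:(n - 1))
  end_m <- segment_length * (1:n)
  mid <- (start_m + end_m) / 2
  # template profiles are defined on [0, 10000]; rescale to the race
  scale <- D / max(tactic$profile$end_m)
  pk <- findInterval(mid / scale, tactic$profile$start_m)
  centre <- vbar * tactic$profile$rel_speed[pk]
  delta <- rep(tactic$delta_wide, n)
  for (w in tactic$tight_windows) {
    if (any(sel <- mid > w[1] * scale & mid < w[2] * scale)) {
      delta[sel] <- tactic$delta_tight
    }
  }
  corridor <- tibble::tibble(
    start_m = start_m, end_m = end_m,
    v_lo = centre - delta, v_hi = centre + delta
  )
  structure(
    corridor,
    class = c("speed_corridor", class(corridor)),
    race_distance = D
  )
}

#' Generate a synthetic championship race with known ground truth
#'
#' Builds a tactical corridor from the template, solves the optimal race
#' for the true parameters, computes 100 m splits, and adds independent
#' zero-mean Gaussian timing noise to each split time (re-drawing any
#' split that would become non-positive, which never happens at realistic
#' scales). The returned truth record carries everything needed to close
#' the loop in a parameter-recovery experiment.
#'
#' @param params_true The generating [runner_params()].
#' @param tactic A tactic template or name (see [default_tactics()]).
#' @param track A [track_geometry()].
#' @param options A [solver_options()].
#' @param noise_sd Standard deviation of the per-split timing noise in
#'   seconds (0.05 s reflects the plausible resolution of video-derived
#'   splits).
#' @param seed Integer seed for the timing noise.
#' @return An object of class `synthetic_race`: a list with elements
#'   `splits` (noisy [split_series()]), `truth` (list with `params`,
#'   `tactic`, `seed`, `noise_sd`, `noise_free_splits`, `corridor`,
#'   `trajectory`, `final_time`), and `n_redrawn`.
#' @export
generate_race <- function(params_true,
                          tactic = "championship_surge",
                          track = track_geometry(),
                          options = solver_options(),
                          noise_sd = 0.05,
                          seed = 1L) {
  stopifnot(noise_sd >= 0)
  corridor <- tactic_corridor(tactic, params_true, track)
  traj <- solve_race(params_true, track, corridor = corridor,
                     options = options)
  if (attr(traj, "solve_status") != "converged") {
    w <- first_infeasible_window(corridor, params_true)
    hint <- if (is.null(w)) {
      ""
    } else {
      sprintf("; the anaerobic store runs out near %g-%g m under the corridor's minimum pace",
              w[1], w[2])
    }
    abort(sprintf(
      "tactic is infeasible for these parameters (solver status '%s')%s",
      attr(traj, "solve_status"), hint
    ))
  }
  clean <- compute_splits(traj)
  noisy <- add_timing_noise(clean, noise_sd, seed)
  structure(
    list(
      splits = noisy,
      truth = list(
        params = params_true,
        tactic = if (is.character(tactic)) tactic else tactic$name,
        seed = seed,
        noise_sd = noise_sd,
        noise_free_splits = clean,
        corridor = corridor,
        trajectory = traj,
        final_time = attr(traj, "final_time")
      ),
      n_redrawn = attr(noisy, "n_redrawn")
    ),
    class = "synthetic_race"
  )
}

# walk the energy balance along the corridor's lower bound and report the
# segment window where the store would first run out (NULL if it never
# does); a cheap diagnostic for infeasible tactics
first_infeasible_window <- function(corridor, params) {
  e <- params$e0
  sp <- params$sigma
  for (k in seq_len(nrow(corridor))) {
    v <- max(corridor$v_lo[k], 0.1)
    dt <- (corridor$end_m[k] - corridor$start_m[k]) / v
    drain <- v^2 / params$tau - sigma_eval(min(max(e, 0), params$e0),
                                           params$e0, sp)
    e <- min(e - drain * dt, params$e0)
    if (e < 0) return(c(corridor$start_m[k], corridor$end_m[k]))
  }
  NULL
}

#' Add timing noise to a split series
#'
#' Adds independent zero-mean Gaussian noise (in seconds) to each split
#' time, emulating the resolution of video-derived timing, and recomputes
#' the mean speeds. Any split whose noisy time would be non-positive is
#' re-drawn (and counted in the `n_redrawn` attribute); at realistic
#' scales this never happens. The global random-number state is restored
#' on exit.
#'
#' @param splits A [split_series()].
#' @param noise_sd Standard deviation of the noise (s).
#' @param seed Integer seed.
#' @return A [split_series()] with attribute `n_redrawn`.
#' @export
add_timing_noise <- function(splits, noise_sd, seed = 1L) {
  stopifnot(inherits(splits, "split_series"), noise_sd >= 0)
  times <- splits$time_s
  n_redrawn <- 0L
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    times <- times + rnorm(length(times), 0, noise_sd)
    while (any(times <= 0)) {
      bad <- which(times <= 0)
      n_redrawn <- n_redrawn + length(bad)
      inform(sprintf("re-drawing %d non-positive noisy split(s)",
                     length(bad)))
      times[bad] <- splits$time_s[bad] + rnorm(length(bad), 0, noise_sd)
    }
  }
  out <- split_series(times, attr(splits, "segment_length"))
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' @export
print.synthetic_race <- function(x, ...) {
  cat(sprintf(
    "<synthetic_race> tactic '%s', noise sd %.3g s, true final time %s\n",
    x$truth$tactic, x$truth$noise_sd, format_race_time(x$truth$final_time)
  ))
  invisible(x)
}
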