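#' Perturb one physiological parameter
#'
#' Returns a copy of the parameter set with a single field scaled by
#' `factor`, re-validating all invariants (an error is raised if the
#' scaled set is invalid). Scaling `tau` down models a runner with a
#' higher cost of running (worse running economy: at steady state the
#' energetic cost per metre is `v / tau`); scaling `e0` down models a
#' reduced anaerobic capacity. `"sigma_max"` scales the plateau only;
#' `"sigma"` scales the whole aerobic curve.
#'
#' @param params A [runner_params()].
#' @param field One of `"e0"`, `"f_max"`, `"tau"`, `"u_plus"`,
#'   `"u_minus"`, `"sigma_max"`, `"sigma"`.
#' @param factor Positive multiplier.
#' @return A [runner_params()].
#' @examples
#' p <- default_winner_params()
#' perturb_params(p, "e0", 0.95)   # 5% smaller anaerobic store
#' @export
perturb_params <- function(params, field, factor) {
  stopifnot(inherits(params, "runner_params"))
  if (!(factor > 0)) abort("factor must be > 0")
  fields <- c("e0", "f_max", "tau", "u_plus", "u_minus",
              "sigma_max", "sigma")
  if (!field %in% fields) {
    abort(paste0("field must be one of: ", paste(fields, collapse = ", ")))
  }
  sig <- params$sigma
  if (field == "sigma_max") {
    sig <- sigma_profile(
      sigma_max = sig$sigma_max * factor,
      sigma_rest = sig$sigma_rest, sigma_final = sig$sigma_final,
      phi_ramp = sig$phi_ramp, phi_final = sig$phi_final
    )
  } else if (field == "sigma") {
    sig <- sigma_profile(
      sigma_max = sig$sigma_max * factor,
      sigma_rest = sig$sigma_rest * factor,
      sigma_final = sig$sigma_final * factor,
      phi_ramp = sig$phi_ramp, phi_final = sig$phi_final
    )
  }
  vals <- list(
    e0 = params$e0, f_max = params$f_max, tau = params$tau,
    u_plus = params$u_plus, u_minus = params$u_minus
  )
  if (field %in% names(vals)) vals[[field]] <- vals[[field]] * factor
  runner_params(
    e0 = vals$e0, f_max = vals$f_max, tau = vals$tau,
    u_plus = vals$u_plus, u_minus = vals$u_minus, sigma = sig
  )
}

# widen the wide (free-running) corridor segments by +50% of their
# half-width, keeping strategic tight windows; tightness is classified
# relative to the narrowest segment
widen_corridor <- function(corridor, factor = 1.5) {
  half <- (corridor$v_hi - corridor$v_lo) / 2
  centre <- (corridor$v_hi + corridor$v_lo) / 2
  tight <- half <= 1.5 * min(half)
  if (all(tight)) tight <- rep(FALSE, length(tight))
  half[!tight] <- half[!tight] * factor
  out <- corridor
  out$v_lo <- centre - half
  out$v_hi <- centre + half
  out
}

#' Per-lap bend and straight speeds
#'
#' Averages the instantaneous speed over the bend nodes and the straight
#' nodes of each lap — the quantity in which the bend-running effect shows
#' up (straights faster than bends when the centripetal constraint is
#' active).
#'
#' @param traj A `race_trajectory`.
#' @param track The [track_geometry()] (default from the trajectory).
#' @return A tibble with columns `lap`, `v_bend`, `v_straight`, `gap`
#'   (`v_straight - v_bend`).
#' @export
bend_straight_speeds <- function(traj, track = attr(traj, "track")) {
  stopifnot(inherits(traj, "race_trajectory"))
  seg <- segment_boundaries(track)
  seg$lap <- ceiling(seg$end_m / track$lap_length)
  idx <- findInterval(traj$s_m, seg$start_m, rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  idx[idx > nrow(seg)] <- nrow(seg)
  df <- tibble::tibble(
    lap = seg$lap[idx],
    type = seg$type[idx],
    v = traj$v_mps
  )
  out <- df |>
    dplyr::group_by(.data$lap, .data$type) |>
    dplyr::summarise(v = mean(.data$v), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "type", values_from = "v",
                       names_prefix = "v_")
  out$gap <- out$v_straight - out$v_bend
  out
}

#' Compare a baseline runner with a perturbed variant
#'
#' Solves the race for both parameter sets under the same tactical
#' corridor and summarises the strategic consequences: the finish-time
#' difference, the per-split speed differences, an endspurt summary (mean
#' speed over the last 400 m minus the race-mean speed), and the per-lap
#' bend/straight speed gaps. If the variant cannot follow the baseline
#' corridor, the wide (free-running) bounds are automatically relaxed by
#' +50% — keeping the strategic tight windows — and the report is flagged.
#'
#' @param base Baseline [runner_params()].
#' @param variant Perturbed [runner_params()] (see [perturb_params()]).
#' @param track A [track_geometry()].
#' @param corridor A `speed_corridor` (e.g. from [tactic_corridor()] for
#'   the baseline); `NULL` solves both runs unconstrained.
#' @param options A [solver_options()].
#' @return A `scenario_report`: list with `t_base`, `t_variant`,
#'   `delta_t` (variant minus base, s), `splits` (per-segment tibble),
#'   `endspurt_base`, `endspurt_variant`, `bend_straight_base`,
#'   `bend_straight_variant`, `corridor_widened`, and both trajectories.
#' @export
compare_scenarios <- function(base, variant, track = track_geometry(),
                              corridor = NULL,
                              options = solver_options()) {
  t_base <- solve_race(base, track, corridor = corridor, options = options)
  if (attr(t_base, "solve_status") != "converged") {
    abort(sprintf("baseline solve failed (status '%s')",
                  attr(t_base, "solve_status")))
  }
  widened <- FALSE
  cor_var <- corridor
  t_var <- solve_race(variant, track, corridor = cor_var, options = options)
  if (attr(t_var, "solve_status") != "converged" && !is.null(corridor)) {
    widened <- TRUE
    cor_var <- widen_corridor(corridor)
    t_var <- solve_race(variant, track, corridor = cor_var,
                        options = options)
  }
  if (attr(t_var, "solve_status") != "converged") {
    abort(sprintf("variant solve failed (status '%s') even %s",
                  attr(t_var, "solve_status"),
                  if (widened) "after widening the corridor" else
                    "without a corridor"))
  }
  sp_base <- compute_splits(t_base)
  sp_var <- compute_splits(t_var)
  splits <- tibble::tibble(
    segment_index = sp_base$segment_index,
    distance_end_m = sp_base$distance_end_m,
    v_base = sp_base$mean_speed_mps,
    v_variant = sp_var$mean_speed_mps,
    dv = sp_var$mean_speed_mps - sp_base$mean_speed_mps
  )
  endspurt <- function(traj) {
    D <- track$race_distance
    tm <- elapsed_time_at(traj$s_m, traj$v_mps, c(0, D - 400, D))
    last400 <- 400 / (tm[3] - tm[2])
    race_mean <- D / tm[3]
    last400 - race_mean
  }
  structure(
    list(
      t_base = attr(t_base, "final_time"),
      t_variant = attr(t_var, "final_time"),
      delta_t = attr(t_var, "final_time") - attr(t_base, "final_time"),
      splits = splits,
      endspurt_base = endspurt(t_base),
      endspurt_variant = endspurt(t_var),
      bend_straight_base = bend_straight_speeds(t_base, track),
      bend_straight_variant = bend_straight_speeds(t_var, track),
      corridor_widened = widened,
      trajectory_base = t_base,
      trajectory_variant = t_var
    ),
    class = "scenario_report"
  )
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf(
    paste0("<scenario_report> base %s, variant %s, delta_t = %+.2f s\n",
           "  endspurt (last 400 m minus race mean): base %+.3f, ",
           "variant %+.3f m/s\n"),
    format_race_time(x$t_base), format_race_time(x$t_variant), x$delta_t,
    x$endspurt_base, x$endspurt_variant
  ))
  if (x$corridor_widened) {
    cat("  note: variant needed a widened (+50%) corridor\n")
  }
  invisible(x)
}

#' @describeIn compare_scenarios Per-split comparison as a tibble.
#' @param x A `scenario_report`.
#' @param ... Unused.
#' @export
tidy.scenario_report <- function(x, ...) {
  x$splits
}

#' @describeIn compare_scenarios One-row summary of the comparison.
#' @export
glance.scenario_report <- function(x, ...) {
  tibble::tibble(
    t_base = x$t_base,
    t_variant = x$t_variant,
    delta_t = x$delta_t,
    endspurt_base = x$endspurt_base,
    endspurt_variant = x$endspurt_variant,
    corridor_widened = x$corridor_widened
  )
}

#' Write a scenario report to JSON (plus per-split CSV)
#'
#' @param report A `scenario_report`.
#' @param path Output JSON path.
#' @param splits_path Optional CSV path for the per-split comparison.
#' @return `path`, invisibly.
#' @export
write_scenario_report <- function(report, path, splits_path = NULL) {
  stopifnot(inherits(report, "scenario_report"))
  x <- list(
    t_base = report$t_base,
    t_variant = report$t_variant,
    delta_t = report$delta_t,
    endspurt_base = report$endspurt_base,
    endspurt_variant = report$endspurt_variant,
    corridor_widened = report$corridor_widened
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(splits_path)) {
    write.csv(as.data.frame(report$splits), splits_path, row.names = FALSE)
  }
  invisible(path)
}
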