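#' Discrepancy between simulated and observed splits
#'
#' Solves the optimal race for the candidate parameters inside a corridor
#' built from the observed data (the same tactical constraints the athlete
#' faced) and returns the root-mean-square error between simulated and
#' observed per-segment mean speeds. Infeasible or non-converged solves
#' return `Inf` (with a message naming the solver status) so that an
#' outer optimiser can move away from them.
#'
#' @param params Candidate [runner_params()].
#' @param observed Observed [split_series()].
#' @param track A [track_geometry()].
#' @param corridor Optional `speed_corridor`; built from `observed` via
#'   [build_corridor()] when omitted.
#' @param options A [solver_options()].
#' @param metric `"speed"` (RMSE of mean speeds, m/s; default) or
#'   `"time"` (RMSE of split times, s).
#' @param warm_cache Internal: an environment used by [calibrate()] to
#'   warm-start solves. The first converged trajectory is stored and every
#'   later evaluation warm-starts from that same fixed reference, so the
#'   objective stays a deterministic, path-independent function of the
#'   parameters (a chained warm start would make it depend on evaluation
#'   order).
#' @return The RMSE (scalar). The residual vector and the simulated splits
#'   are attached as attributes `residuals` and `simulated`.
#' @export
fit_error <- function(params, observed, track = track_geometry(),
                      corridor = NULL, options = solver_options(),
                      metric = c("speed", "time"), warm_cache = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(observed, "split_series"))
  if (is.null(corridor)) corridor <- build_corridor(observed)
  warm <- if (!is.null(warm_cache)) warm_cache$ref else NULL
  traj <- solve_race(params, track, corridor = corridor, options = options,
                     warm = warm)
  if (attr(traj, "solve_status") != "converged") {
    inform(sprintf("fit_error: solve status '%s' -> Inf",
                   attr(traj, "solve_status")))
    return(Inf)
  }
  if (!is.null(warm_cache) && is.null(warm_cache$ref)) warm_cache$ref <- traj
  sim <- compute_splits(traj, attr(observed, "segment_length"))
  res <- if (metric == "speed") {
    sim$mean_speed_mps - observed$mean_speed_mps
  } else {
    sim$time_s - observed$time_s
  }
  rmse <- sqrt(mean(res^2))
  attr(rmse, "residuals") <- res
  attr(rmse, "simulated") <- sim
  rmse
}

# parameter vector <-> runner_params (sigma_rest kept proportional to
# sigma_max; phi fractions frozen)
theta_names <- c("e0", "f_max", "tau", "u_plus", "u_minus",
                 "sigma_max", "sigma_final")

params_to_theta <- function(params) {
  c(params$e0, params$f_max, params$tau, params$u_plus, params$u_minus,
    params$sigma$sigma_max, params$sigma$sigma_final)
}

theta_to_params <- function(theta, template) {
  theta <- unname(theta)
  rest_ratio <- template$sigma$sigma_rest / template$sigma$sigma_max
  runner_params(
    e0 = theta[1], f_max = theta[2], tau = theta[3],
    u_plus = theta[4], u_minus = theta[5],
    sigma = sigma_profile(
      sigma_max = theta[6],
      sigma_rest = rest_ratio * theta[6],
      sigma_final = theta[7],
      phi_ramp = template$sigma$phi_ramp,
      phi_final = template$sigma$phi_final
    )
  )
}

#' Calibrate runner parameters to an observed split series
#'
#' Identifies the physiological parameter vector
#' (`e0`, `f_max`, `tau`, `u_plus`, `u_minus`, `sigma_max`,
#' `sigma_final`) that best reproduces an observed 100 m split series, by
#' bounded derivative-free minimisation of [fit_error()]. The aerobic
#' curve's shape fractions (`phi_ramp`, `phi_final` and the
#' `sigma_rest/sigma_max` ratio) are held at their initial values to curb
#' non-identifiability. The search runs a Nelder-Mead simplex in a
#' logit-transformed box, restarted deterministically from the initial
#' guess scaled by 0.9, 1.0 and 1.1; consecutive solves are warm-started.
#' The whole procedure is deterministic given `init` and `budget`.
#'
#' @param observed Observed [split_series()].
#' @param init Initial [runner_params()].
#' @param bounds Named list of `c(lo, hi)` intervals per parameter
#'   (defaults: a generous multiplicative box around `init`).
#' @param budget Maximal total number of race solves (objective
#'   evaluations) across all restarts.
#' @param track A [track_geometry()].
#' @param corridor Optional `speed_corridor` to fit under (e.g. the
#'   generating corridor from a synthetic race's truth record, closing
#'   the recovery loop exactly); when `NULL` it is rebuilt from the
#'   observed splits, which adds a small smoothing bias to the fit floor.
#' @param options A [solver_options()].
#' @param metric Passed to [fit_error()].
#' @param n_restarts Number of deterministic restarts (scaled inits;
#'   restarts after the first continue from the best point found so far).
#' @return A `pace_fit` object: list with `params` (best-found
#'   [runner_params()]), `rmse`, `residuals`, `n_solves`, `converged`
#'   (`FALSE` when the budget interrupted the search), `history`
#'   (objective value per evaluation), `observed`, `metric`.
#' @export
calibrate <- function(observed, init,
                      bounds = NULL,
                      budget = 200,
                      track = track_geometry(),
                      corridor = NULL,
                      options = solver_options(),
                      metric = c("speed", "time"),
                      n_restarts = 3) {
  metric <- match.arg(metric)
  stopifnot(inherits(init, "runner_params"), budget >= 1)
  theta0 <- params_to_theta(init)
  names(theta0) <- theta_names
  if (is.null(bounds)) {
    bounds <- list(
      e0 = theta0[["e0"]] * c(0.5, 2),
      f_max = theta0[["f_max"]] * c(0.6, 1.6),
      tau = theta0[["tau"]] * c(0.6, 1.6),
      u_plus = theta0[["u_plus"]] * c(0.4, 2.5),
      u_minus = theta0[["u_minus"]] * c(0.4, 2.5),
      sigma_max = theta0[["sigma_max"]] * c(0.7, 1.3),
      sigma_final = theta0[["sigma_final"]] * c(0.5, 1.25)
    )
  }
  lo <- vapply(theta_names, function(k) bounds[[k]][1], numeric(1))
  hi <- vapply(theta_names, function(k) bounds[[k]][2], numeric(1))
  if (any(theta0 < lo | theta0 > hi)) {
    abort("init must lie within bounds")
  }
  if (is.null(corridor)) corridor <- build_corridor(observed)

  # logit transform keeps the simplex inside the box
  to_x <- function(th) stats::qlogis(pmin(pmax((th - lo) / (hi - lo),
                                               1e-6), 1 - 1e-6))
  to_theta <- function(x) lo + (hi - lo) * stats::plogis(x)

  state <- new.env(parent = emptyenv())
  state$best_rmse <- Inf
  state$best_theta <- theta0
  state$best_res <- NULL
  state$n <- 0L
  state$history <- numeric(0)

  objective <- function(x, sub_budget) {
    if (state$n >= sub_budget) stop(budget_exhausted_condition())
    th <- to_theta(x)
    state$n <- state$n + 1L
    # every evaluation is a cold continuation solve: slower than chained
    # warm starts but a deterministic, path-independent objective
    val <- tryCatch({
      p <- theta_to_params(th, init)
      fit_error(p, observed, track = track, corridor = corridor,
                options = options, metric = metric)
    }, error = function(e) Inf)
    v <- as.numeric(val)
    state$history <- c(state$history, v)
    if (v < state$best_rmse) {
      state$best_rmse <- v
      state$best_theta <- th
      state$best_res <- attr(val, "residuals")
    }
    if (is.finite(v)) v else 1e6
  }

  # staged search: the energetic triple (e0, tau, sigma_max) dominates
  # the split profile and is fitted first in a 3-d simplex; the full
  # 7-parameter vector is then polished from that point. Remaining budget
  # funds deterministic restarts of the polish from scaled points.
  run_simplex <- function(active, start_th, sub_budget) {
    if (state$n >= sub_budget) return(TRUE)
    obj_masked <- function(x_active) {
      th <- state$stage_base
      th[active] <- to_theta_masked(x_active, active)
      objective_theta(th, sub_budget)
    }
    state$stage_base <- start_th
    tryCatch({
      optim(to_x(start_th)[active], obj_masked,
            method = "Nelder-Mead",
            control = list(maxit = 10 * sub_budget, reltol = 1e-6))
      TRUE
    }, budget_exhausted = function(e) FALSE)
  }
  to_theta_masked <- function(x_active, active) {
    (lo + (hi - lo) * stats::plogis(x_active_full(x_active, active)))[active]
  }
  x_active_full <- function(x_active, active) {
    x <- rep(0, length(theta_names))
    x[active] <- x_active
    x
  }
  objective_theta <- function(th, sub_budget) {
    objective(to_x(th), sub_budget)
  }

  finished <- TRUE
  triple <- match(c("e0", "tau", "sigma_max"), theta_names)
  all7 <- seq_along(theta_names)

  # phase 0 - coarse scan of overall strength: when every parameter is
  # too generous the simulation saturates the corridor bounds and the
  # objective is locally flat, so a local search cannot start. Probing
  # the diagonal theta0 * s locates the responsive region first.
  if (budget > 30) {
    for (s in seq(0.80, 1.20, by = 0.05)) {
      if (state$n >= ceiling(0.15 * budget)) break
      th_s <- pmin(pmax(theta0 * s, lo), hi)
      tryCatch(objective_theta(th_s, budget),
               budget_exhausted = function(e) NULL)
    }
  }

  # phase 1 - the energetic triple (e0, tau, sigma_max) dominates the
  # split profile; phase 2 polishes all seven parameters; any remaining
  # budget funds deterministic restarts from scaled best points.
  finished <- run_simplex(triple, state$best_theta,
                          ceiling(0.5 * budget)) && finished
  finished <- run_simplex(all7, state$best_theta,
                          ceiling(0.85 * budget)) && finished
  scales <- c(0.97, 1.03)[seq_len(max(0, n_restarts - 1))]
  for (sc in scales) {
    if (state$n >= budget) break
    th_i <- pmin(pmax(state$best_theta * sc, lo), hi)
    finished <- run_simplex(all7, th_i, budget) && finished
  }

  best_params <- theta_to_params(state$best_theta, init)
  residuals <- state$best_res
  if (is.null(residuals)) residuals <- rep(NA_real_, nrow(observed))
  structure(
    list(
      params = best_params,
      rmse = state$best_rmse,
      residuals = residuals,
      n_solves = state$n,
      converged = finished,
      history = state$history,
      observed = observed,
      metric = metric,
      bounds = bounds
    ),
    class = "pace_fit"
  )
}

budget_exhausted_condition <- function() {
  structure(
    class = c("budget_exhausted", "error", "condition"),
    list(message = "evaluation budget exhausted", call = NULL)
  )
}

#' @export
print.pace_fit <- function(x, ...) {
  cat(sprintf(
    "<pace_fit> rmse %.4f %s after %d solves (%s)\n",
    x$rmse, if (x$metric == "speed") "m/s" else "s", x$n_solves,
    if (x$converged) "converged" else "budget exhausted"
  ))
  print(x$params)
  invisible(x)
}

#' @describeIn calibrate Tidy the fitted parameters into a tibble with
#'   columns `term` and `estimate`.
#' @param x A `pace_fit`.
#' @param ... Unused.
#' @export
tidy.pace_fit <- function(x, ...) {
  tibble::tibble(
    term = theta_names,
    estimate = params_to_theta(x$params)
  )
}

#' @describeIn calibrate One-row model summary (`rmse`, `n_solves`,
#'   `converged`, simulated final time).
#' @export
glance.pace_fit <- function(x, ...) {
  tibble::tibble(
    rmse = x$rmse,
    n_solves = x$n_solves,
    converged = x$converged,
    n_segments = nrow(x$observed),
    observed_time_s = sum(x$observed$time_s)
  )
}

#' Write a calibration result to JSON
#'
#' Stores the fitted parameters, the rmse, and the full residual vector
#' (for plotting) in one JSON file.
#'
#' @param fit A `pace_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "pace_fit"))
  x <- list(
    params = setNames(as.list(params_to_theta(fit$params)), theta_names),
    sigma_shape = list(
      sigma_rest = fit$params$sigma$sigma_rest,
      phi_ramp = fit$params$sigma$phi_ramp,
      phi_final = fit$params$sigma$phi_final
    ),
    rmse = fit$rmse,
    metric = fit$metric,
    n_solves = fit$n_solves,
    converged = fit$converged,
    residuals = fit$residuals
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
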