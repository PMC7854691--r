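#' Aerobic power curve sigma(e)
#'
#' The aerobic (oxidative) power per unit mass available to the runner,
#' modelled as a function of the *remaining* anaerobic energy `e`. Because
#' `e` decreases monotonically through most of a hard race, it acts as a
#' proxy for race phase: the curve rises from `sigma_rest` at `e = e0`
#' (oxygen-uptake kinetics at the gun) to a plateau `sigma_max`, and drops
#' towards `sigma_final` as the anaerobic store empties near exhaustion.
#' The curve is continuous and piecewise linear:
#'
#' * ramp: `e` in `[phi_ramp * e0, e0]`, linear from `sigma_max` down to
#'   `sigma_rest` at `e = e0`;
#' * plateau: `e` in `[phi_final * e0, phi_ramp * e0]`, constant
#'   `sigma_max`;
#' * final drop: `e` in `[0, phi_final * e0]`, linear down to
#'   `sigma_final` at `e = 0`.
#'
#' Defaults place the plateau at 85% of a VO2max of 85 mL/kg/min (see
#' [vo2_to_power()]), with `sigma_rest = 0.3 * sigma_max` and
#' `sigma_final = 0.8 * sigma_max`.
#'
#' @param sigma_max Plateau aerobic power (W/kg).
#' @param sigma_rest Aerobic power at the race start, `e = e0` (W/kg).
#' @param sigma_final Aerobic power at exhaustion, `e = 0` (W/kg).
#' @param phi_ramp Fraction of `e0` at which the start ramp ends, in (0, 1).
#' @param phi_final Fraction of `e0` below which the end drop begins, in
#'   (0, `phi_ramp`).
#' @return An object of class `sigma_profile`.
#' @export
sigma_profile <- function(sigma_max = vo2_to_power(0.85 * 85),
                          sigma_rest = 0.3 * sigma_max,
                          sigma_final = 0.8 * sigma_max,
                          phi_ramp = 0.9,
                          phi_final = 0.2) {
  if (!(sigma_max > 0)) abort("sigma_max must be > 0")
  if (sigma_rest < 0 || sigma_rest > sigma_max) {
    abort("sigma_rest must lie in [0, sigma_max]")
  }
  if (sigma_final < 0 || sigma_final > sigma_max) {
    abort("sigma_final must lie in [0, sigma_max]")
  }
  if (!(phi_final > 0 && phi_final < phi_ramp && phi_ramp < 1)) {
    abort("need 0 < phi_final < phi_ramp < 1")
  }
  structure(
    list(
      sigma_max = sigma_max, sigma_rest = sigma_rest,
      sigma_final = sigma_final, phi_ramp = phi_ramp, phi_final = phi_final
    ),
    class = "sigma_profile"
  )
}

#' Evaluate the aerobic power curve
#'
#' @param e Remaining anaerobic energy (J/kg), in `[0, e0]`.
#' @param e0 Total anaerobic energy store (J/kg).
#' @param profile A [sigma_profile()].
#' @return Aerobic power (W/kg), vectorised over `e`.
#' @export
sigma_of_e <- function(e, e0, profile) {
  stopifnot(inherits(profile, "sigma_profile"))
  if (any(e < 0 | e > e0)) abort("e must lie in [0, e0]")
  sigma_eval(e, e0, profile)
}

# unchecked evaluation (solver-internal; tolerates e slightly outside [0, e0])
sigma_eval <- function(e, e0, sp) {
  b1 <- sp$phi_final * e0
  b2 <- sp$phi_ramp * e0
  out <- numeric(length(e))
  hi <- e >= b2
  mid <- e >= b1 & e < b2
  lo <- e < b1
  out[hi] <- sp$sigma_max +
    (sp$sigma_rest - sp$sigma_max) * (e[hi] - b2) / (e0 - b2)
  out[mid] <- sp$sigma_max
  out[lo] <- sp$sigma_final + (sp$sigma_max - sp$sigma_final) * pmax(e[lo], 0) / b1
  out
}

sigma_deriv <- function(e, e0, sp) {
  b1 <- sp$phi_final * e0
  b2 <- sp$phi_ramp * e0
  out <- numeric(length(e))
  out[e >= b2] <- (sp$sigma_rest - sp$sigma_max) / (e0 - b2)
  out[e < b1] <- (sp$sigma_max - sp$sigma_final) / b1
  out
}

# distance-average of sigma over a full linear depletion of the store,
# integral of sigma(e) de / e0; used for the cruise-pace estimate
sigma_mean_over_store <- function(sp) {
  sp$sigma_max * (
    (1 - sp$phi_ramp) * (sp$sigma_rest / sp$sigma_max + 1) / 2 +
      (sp$phi_ramp - sp$phi_final) +
      sp$phi_final * (1 + sp$sigma_final / sp$sigma_max) / 2
  )
}

#' Convert oxygen uptake to aerobic power per unit mass
#'
#' Converts an oxygen uptake in mL O2 per kg per minute into a mechanical
#' power equivalent in W/kg using an energetic equivalent per mL of oxygen
#' (default 20.9 J/mL).
#'
#' @param vo2 Oxygen uptake (mL O2/kg/min), non-negative.
#' @param energy_equivalent Energy released per mL O2 (J/mL).
#' @return Power per unit mass (W/kg).
#' @examples
#' vo2_to_power(85)          # a world-class VO2max
#' vo2_to_power(0.85 * 85)   # championship 10,000 m race intensity
#' @export
vo2_to_power <- function(vo2, energy_equivalent = 20.9) {
  if (any(vo2 < 0)) abort("vo2 must be non-negative")
  if (!(energy_equivalent > 0)) abort("energy_equivalent must be > 0")
  vo2 * energy_equivalent / 60
}

#' Physiological parameters of a runner
#'
#' The parameter vector of the pacing model:
#'
#' * `e0` — total anaerobic energy store per unit mass (J/kg), the maximal
#'   accumulated oxygen deficit;
#' * `f_max` — maximal propulsive force per unit mass (N/kg);
#' * `tau` — global friction coefficient (s), lumping all joint/track
#'   dissipation; `f_max * tau` is the maximal (sprint) speed, and the
#'   steady-state energetic cost per metre at speed `v` is `v / tau`;
#' * `u_plus`, `u_minus` — maximal rates of increase and decrease of the
#'   propulsive force (N/kg/s), a motor-control limit (`u_minus` is stored
#'   positive);
#' * `sigma` — the aerobic power curve, a [sigma_profile()].
#'
#' @param e0 Anaerobic energy store (J/kg).
#' @param f_max Maximal propulsive force (N/kg).
#' @param tau Friction coefficient (s).
#' @param u_plus Maximal force increase rate (N/kg/s).
#' @param u_minus Maximal force decrease rate (N/kg/s, positive).
#' @param sigma A [sigma_profile()].
#' @return An object of class `runner_params`.
#' @examples
#' p <- default_winner_params()
#' max_speed(p)
#' @export
runner_params <- function(e0, f_max, tau, u_plus, u_minus,
                          sigma = sigma_profile()) {
  fields <- c(e0 = e0, f_max = f_max, tau = tau,
              u_plus = u_plus, u_minus = u_minus)
  bad <- names(fields)[!(fields > 0)]
  if (length(bad) > 0) {
    abort(paste0("runner_params fields must be strictly positive: ",
                 paste(bad, collapse = ", ")))
  }
  vmax <- f_max * tau
  if (vmax < 2 || vmax > 15) {
    abort(sprintf(
      "f_max * tau = %.2f m/s is outside the human sanity window [2, 15]",
      vmax
    ))
  }
  stopifnot(inherits(sigma, "sigma_profile"))
  structure(
    list(e0 = e0, f_max = f_max, tau = tau,
         u_plus = u_plus, u_minus = u_minus, sigma = sigma),
    class = "runner_params"
  )
}

#' @export
print.runner_params <- function(x, ...) {
  cat(sprintf(
    paste0("<runner_params> e0 = %.0f J/kg, f_max = %.2f N/kg, tau = %.2f s ",
           "(max speed %.2f m/s),\n  u+ = %.2f, u- = %.2f N/kg/s, ",
           "sigma_max = %.2f W/kg\n"),
    x$e0, x$f_max, x$tau, max_speed(x), x$u_plus, x$u_minus,
    x$sigma$sigma_max
  ))
  invisible(x)
}

#' Maximal speed implied by the parameters
#'
#' At force `f_max` the equation of motion `dv/dt = f - v/tau` equilibrates
#' at `v = f_max * tau`, the runner's absolute speed ceiling on a straight.
#'
#' @param params A [runner_params()].
#' @return Speed in m/s.
#' @export
max_speed <- function(params) {
  stopifnot(inherits(params, "runner_params"))
  params$f_max * params$tau
}

#' Time derivatives of the race state
#'
#' The coupled equations of motion and energy balance:
#' `dv/dt = f - v/tau` (Newton's second law with linear friction),
#' `df/dt = u` (rate-limited force control), and
#' `de/dt = sigma(e) - f v` (anaerobic store drains when the propulsive
#' power exceeds the aerobic supply). Positive `de/dt` means partial
#' re-synthesis of the anaerobic store at low intensity.
#'
#' @param v Speed (m/s), non-negative.
#' @param f Propulsive force (N/kg).
#' @param e Remaining anaerobic energy (J/kg), in `[0, e0]`.
#' @param u Force rate control (N/kg/s), in `[-u_minus, u_plus]`.
#' @param params A [runner_params()].
#' @return A tibble with columns `dv_dt`, `df_dt`, `de_dt` (vectorised).
#' @export
dynamics_rhs <- function(v, f, e, u, params) {
  stopifnot(inherits(params, "runner_params"))
  if (any(v < 0)) abort("v must be non-negative")
  if (any(e < 0 | e > params$e0)) abort("e must lie in [0, e0]")
  if (any(u < -params$u_minus - 1e-12 | u > params$u_plus + 1e-12)) {
    abort("u must lie in [-u_minus, u_plus]")
  }
  tibble::tibble(
    dv_dt = f - v / params$tau,
    df_dt = u,
    de_dt = sigma_eval(e, params$e0, params$sigma) - f * v
  )
}

#' Maximal propulsive force on a curve
#'
#' On a bend of radius `R` part of the force budget is spent on the
#' centripetal acceleration `v^2 / R`, leaving at most
#' `sqrt(f_max^2 - v^4 / R^2)` for propulsion (the constraint
#' `f^2 + v^4/R^2 <= f_max^2`). On straights (`R = Inf`) the full `f_max`
#' is available; when `v^2 >= f_max * R` the centripetal demand saturates
#' the budget and no propulsive force remains.
#'
#' @param v Speed (m/s), non-negative.
#' @param R Radius of curvature (m), `Inf` for a straight.
#' @param f_max Maximal force (N/kg).
#' @return The propulsive force cap (N/kg), vectorised.
#' @examples
#' bend_force_cap(7, 36.5, 8)
#' bend_force_cap(7, Inf, 8)
#' @export
bend_force_cap <- function(v, R, f_max) {
  if (any(v < 0)) abort("v must be non-negative")
  if (!(all(f_max > 0))) abort("f_max must be > 0")
  cent <- ifelse(is.infinite(R), 0, v^4 / R^2)
  sqrt(pmax(0, f_max^2 - cent))
}

#' Default championship-winner parameter anchor
#'
#' A parameter set producing a world-class 10,000 m performance
#' (roughly 26.5 minutes) used as the default starting point for
#' simulations and calibration. Read from the packaged
#' `default_winner.json` configuration. These are tuning anchors for a
#' generic elite runner, not measurements of any specific athlete.
#'
#' @return A [runner_params()].
#' @export
default_winner_params <- function() {
  path <- system.file("extdata", "default_winner.json", package = "trackpace")
  read_runner_params(path)
}

#' Bend-limited parameter variant
#'
#' A parameter set whose force ceiling leaves only a thin margin over the
#' centripetal demand at cruise speed, so that the bend constraint is
#' active during steady running. This is the regime in which the model
#' reproduces the characteristic bend-vs-straight speed oscillation of
#' championship split profiles; with a generous `f_max` the constraint is
#' slack at cruise speed and the model is curvature-blind.
#'
#' @return A [runner_params()].
#' @export
bend_limited_params <- function() {
  path <- system.file("extdata", "bend_limited.json", package = "trackpace")
  read_runner_params(path)
}

#' Read/write runner parameters as JSON
#'
#' Runner parameters serialise to a flat JSON object in SI units with keys
#' `e0`, `f_max`, `tau`, `u_plus`, `u_minus`, `sigma_max`, `sigma_rest`,
#' `sigma_final`, `phi_ramp`, `phi_final`. The reader validates all
#' invariants and names the offending key on failure.
#'
#' @param path JSON file path.
#' @return `read_runner_params()` returns a [runner_params()];
#'   `write_runner_params()` returns `path` invisibly.
#' @export
read_runner_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$runner)) raw <- raw$runner
  needed <- c("e0", "f_max", "tau", "u_plus", "u_minus")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0("runner config is missing key(s): ",
                 paste(missing, collapse = ", ")))
  }
  sig_args <- raw[intersect(
    c("sigma_max", "sigma_rest", "sigma_final", "phi_ramp", "phi_final"),
    names(raw)
  )]
  sigma <- do.call(sigma_profile, sig_args)
  runner_params(
    e0 = raw$e0, f_max = raw$f_max, tau = raw$tau,
    u_plus = raw$u_plus, u_minus = raw$u_minus, sigma = sigma
  )
}

#' @rdname read_runner_params
#' @param params A [runner_params()].
#' @export
write_runner_params <- function(params, path) {
  stopifnot(inherits(params, "runner_params"))
  x <- list(
    e0 = params$e0, f_max = params$f_max, tau = params$tau,
    u_plus = params$u_plus, u_minus = params$u_minus,
    sigma_max = params$sigma$sigma_max,
    sigma_rest = params$sigma$sigma_rest,
    sigma_final = params$sigma$sigma_final,
    phi_ramp = params$sigma$phi_ramp,
    phi_final = params$sigma$phi_final
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
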