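#' Options for the optimal-control solver
#'
#' The race is transcribed by direct collocation on a distance grid over
#' `[0, race_distance]` (trapezoidal rule) and solved as a nonlinear
#' program by an augmented-Lagrangian method with analytic gradients,
#' using box-constrained L-BFGS for the inner minimisations.
#'
#' The grid has `n_nodes` nominally uniform nodes plus a geometric
#' refinement ramp at the start (spacing growing from `start_ramp_h0`
#' metres) so the standing-start transient is resolved. By default the
#' problem is first solved on a coarse continuation grid and the result is
#' propagated to the full grid through an exact forward re-integration;
#' this makes the solution grid-consistent and is entirely deterministic.
#'
#' @param n_nodes Number of nominal grid nodes (>= 50).
#' @param nlp_tol Convergence tolerance on the scaled collocation defects
#'   and path-constraint violation (state-difference units). Residuals
#'   that stagnate while already below `min(1e-4, 1e3 * nlp_tol)` —
#'   orders of magnitude under the discretisation error — are accepted
#'   as converged.
#' @param reg_eps Weight of the control-smoothing term
#'   `reg_eps * integral(u^2 / v ds)` added to the race time; suppresses
#'   bang-bang chattering and contributes well under 0.01 s to the default
#'   race objective.
#' @param v_floor Lower path bound on speed (m/s).
#' @param v_init Initial speed at the gun (m/s). The sub-second standing
#'   start is below the fidelity of 100 m splits, so the race starts from a
#'   small positive roll rather than an exact standstill (which is
#'   singular in the distance domain).
#' @param max_iter Iteration cap for each inner L-BFGS solve.
#' @param max_outer Cap on augmented-Lagrangian multiplier updates.
#' @param continuation Use the coarse-to-fine continuation start
#'   (recommended; the standing-start arc otherwise admits poor local
#'   optima on fine grids).
#' @param coarse_nodes Nodes of the continuation grid.
#' @param start_ramp_h0 First grid spacing at the start (m).
#' @param start_ramp_growth Geometric growth factor of the start ramp.
#' @param resynthesis `"taper"` (default) lets the anaerobic store recover
#'   when `sigma(e) > f v` with the recovery rate tapering linearly to
#'   zero over the top `taper_frac` of the store (keeping the state cap
#'   `e <= e0` consistent with the dynamics); `"clip"` forbids recovery
#'   entirely.
#' @param taper_frac Width of the re-synthesis taper band as a fraction of
#'   `e0`.
#' @param mu0,mu_max Initial and maximal quadratic penalty weight.
#' @param corridor_start_relax_m Length of the initial stretch over which a
#'   corridor's lower speed bound is relaxed to `v_floor` so the standing
#'   start is feasible (the corridor's upper bound still applies).
#' @param verbose Print outer-iteration diagnostics.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(n_nodes = 1000,
                           nlp_tol = 1e-7,
                           reg_eps = 1e-4,
                           v_floor = 0.5,
                           v_init = 1.0,
                           max_iter = 3000,
                           max_outer = 40,
                           continuation = TRUE,
                           coarse_nodes = 201,
                           start_ramp_h0 = 0.25,
                           start_ramp_growth = 1.3,
                           resynthesis = c("taper", "clip"),
                           taper_frac = 0.02,
                           mu0 = 1e4,
                           mu_max = 1e7,
                           corridor_start_relax_m = 100,
                           verbose = FALSE) {
  resynthesis <- match.arg(resynthesis)
  if (n_nodes < 50) abort("n_nodes must be >= 50")
  stopifnot(nlp_tol > 0, reg_eps >= 0, v_floor > 0, v_init >= v_floor)
  structure(
    list(
      n_nodes = n_nodes, nlp_tol = nlp_tol, reg_eps = reg_eps,
      v_floor = v_floor, v_init = v_init, max_iter = max_iter,
      max_outer = max_outer, continuation = continuation,
      coarse_nodes = coarse_nodes, start_ramp_h0 = start_ramp_h0,
      start_ramp_growth = start_ramp_growth, resynthesis = resynthesis,
      taper_frac = taper_frac, mu0 = mu0, mu_max = mu_max,
      corridor_start_relax_m = corridor_start_relax_m, verbose = verbose
    ),
    class = "solver_options"
  )
}

# distance grid: geometric ramp at the start, a half-spacing transition
# zone while the start arc is still curving, then nominally uniform
ocp_grid <- function(D, n_nodes, h0 = 0.25, growth = 1.3,
                     transition_to = 300) {
  base <- seq(0, D, length.out = n_nodes)
  H <- base[2] - base[1]
  if (h0 >= H) return(base)
  hs <- h0 * growth^(0:400)
  hs <- hs[hs < H / 2]
  fine <- cumsum(hs)
  fine <- fine[fine < D]
  top <- max(fine)
  mid <- seq(top, min(transition_to, D), by = H / 2)
  pts <- c(0, fine, mid, base[base > max(mid)])
  sort(unique(pts))
}

# exact elapsed time for piecewise-linear speed: dt over an interval where
# v goes linearly v1 -> v2 is h * log(v2/v1) / (v2 - v1)
time_quadrature <- function(s, v) {
  n <- length(s)
  h <- diff(s)
  dv <- diff(v)
  vm <- (v[-n] + v[-1]) / 2
  dt <- ifelse(abs(dv) > 1e-9 * vm, h * log(v[-1] / v[-n]) / dv, h / vm)
  c(0, cumsum(dt))
}

# energy rhs de/ds = w(v,f,e); psi tapers re-synthesis near the full store
energy_rhs <- function(v, f, e, e0, sp, mode, de0) {
  r <- sigma_eval(e, e0, sp) - f * v
  psi <- if (mode == "clip") {
    as.numeric(r <= 0)
  } else {
    ifelse(r > 0, pmin(1, pmax(0, (e0 - e) / de0)), 1)
  }
  list(w = r * psi / v, r = r, psi = psi)
}

# corridor bounds evaluated at grid nodes (piecewise constant, [start,end))
corridor_bounds_at <- function(corridor, s) {
  idx <- findInterval(s, corridor$start_m, rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  idx[idx > nrow(corridor)] <- nrow(corridor)
  list(lo = corridor$v_lo[idx], hi = corridor$v_hi[idx])
}

# Core augmented-Lagrangian collocation solve on a fixed grid.
# Returns list(s, v, f, e, u, viol, nfev, outer, converged, lam, mu).
ocp_core <- function(params, sgrid, kappa, lo_v, hi_v, options,
                     warm = NULL) {
  sp <- params$sigma
  e0 <- params$e0
  fM <- params$f_max
  tau <- params$tau
  N <- length(sgrid)
  h <- diff(sgrid)
  sc_e <- 10
  de0 <- options$taper_frac * e0
  mode <- options$resynthesis
  reg_eps <- options$reg_eps
  iv <- 1:N; iff <- N + 1:N; ie <- 2 * N + 1:N; iu <- 3 * N + 1:N

  lower <- c(lo_v, rep(0, N), rep(0, N), rep(-params$u_minus, N))
  upper <- c(hi_v, rep(fM, N), rep(e0, N), rep(params$u_plus, N))
  lower[2 * N + 1] <- e0
  upper[2 * N + 1] <- e0

  if (!is.null(warm)) {
    z <- pmin(pmax(warm$z, lower), upper)
    lamv <- warm$lam$lamv; lamf <- warm$lam$lamf
    lame <- warm$lam$lame; eta <- warm$lam$eta
    mu <- warm$mu
  } else {
    # initial guess: maximal-acceleration arc blended into the
    # energy-balance cruise pace (or the corridor midline)
    vbar <- pmin(pmax((lo_v + hi_v) / 2, lo_v), hi_v)
    v0 <- numeric(N); v0[1] <- lo_v[1]
    for (k in 2:N) {
      acc <- (fM - v0[k - 1] / tau) / v0[k - 1]
      v0[k] <- min(v0[k - 1] + h[k - 1] * acc, vbar[k])
      v0[k] <- min(max(v0[k], lo_v[k]), hi_v[k])
    }
    f0 <- pmin(v0 / tau, fM)
    # seed the endspurt: ramp the initial force guess towards f_max over
    # the closing stretch at the admissible rate (the optimiser trims it
    # back to whatever the remaining store affords)
    D_end <- sgrid[N]
    dist_left <- D_end - sgrid
    f_ramp <- fM - params$u_plus * dist_left / pmax(v0, 1)
    f0 <- pmax(f0, pmin(f_ramp, fM))
    # seed the store-exhausting basin: racing optima spend the whole
    # anaerobic store, and an energy-conserving initial path can trap the
    # solver in a slow local optimum that never unlocks the plateau
    ee <- seq(e0, 0.02 * e0, length.out = N)
    u0 <- pmin(pmax(c(diff(f0) / h, 0) * v0, -params$u_minus), params$u_plus)
    z <- c(v0, f0, ee, u0)
    lamv <- lamf <- lame <- numeric(N - 1)
    eta <- numeric(N)
    mu <- options$mu0
  }

  kap2 <- kappa^2
  has_bend <- any(kap2 > 0)
  wq <- c(h / 2, 0) + c(0, h / 2)
  # variable scaling for the inner quasi-Newton solves
  pscale <- c(rep(1, N), rep(1, N), rep(e0 / 15, N),
              rep(max(params$u_plus, params$u_minus), N))

  # the compiled merit evaluator returns value and gradient together;
  # optim() asks for them separately at the same point, so memoise
  memo <- new.env(parent = emptyenv())
  memo$z <- NULL
  al_eval <- function(z, want_defects = FALSE) {
    .ocp_al_eval(
      z, h, lamv, lamf, lame, eta, mu,
      tau, fM, e0,
      sp$sigma_max, sp$sigma_rest, sp$sigma_final,
      sp$phi_ramp, sp$phi_final,
      de0, mode == "clip",
      kap2, wq, sc_e, reg_eps, has_bend, want_defects
    )
  }
  obj_al <- function(z) {
    memo$z <- z
    memo$res <- al_eval(z)
    memo$res$value
  }
  grad_al <- function(z) {
    if (is.null(memo$z) || !identical(memo$z, z)) {
      memo$z <- z
      memo$res <- al_eval(z)
    }
    memo$res$grad
  }

  # safeguarded multiplier updates: accept the iterate (and update the
  # multipliers) only when the violation has dropped enough; otherwise
  # raise the penalty weight moderately and re-solve with the same
  # multipliers. Keeping mu bounded preserves inner conditioning.
  best_viol <- Inf
  nfev <- 0
  viol <- Inf
  viol_hist <- numeric(0)
  stall_accept <- min(1e-4, 1e3 * options$nlp_tol)
  maxit_inner <- min(2000, options$max_iter)
  inner_factr <- 1e6
  for (outer in seq_len(options$max_outer)) {
    fit <- optim(z, obj_al, grad_al, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = maxit_inner, factr = inner_factr,
                                parscale = pscale, lmm = 10))
    nfev <- nfev + fit$counts[[1]]
    z <- fit$par
    d <- al_eval(z, want_defects = TRUE)
    viol <- d$viol
    if (options$verbose) {
      inform(sprintf(
        "  AL outer %2d  mu %.1e  viol %.3e  J %.4f  fev %d",
        outer, mu, viol, d$objective, fit$counts[[1]]
      ))
    }
    viol_hist <- c(viol_hist, viol)
    if (viol < options$nlp_tol) {
      lamv <- lamv + mu * d$cv
      lamf <- lamf + mu * d$cf
      lame <- lame + mu * d$ce
      if (has_bend) eta <- pmax(0, eta + mu * d$g)
      break
    }
    # residuals occasionally stagnate just above nlp_tol at a kink or a
    # degenerate active set; once they are orders of magnitude below the
    # discretisation error and no longer improving, stop
    if (outer >= 6 && viol < stall_accept &&
        viol > 0.99 * viol_hist[outer - 5]) {
      break
    }
    # infeasible or hopeless problems: violation refuses to fall over a
    # long window -> bail out instead of grinding out the outer budget
    if (outer >= 8 && viol > stall_accept &&
        viol > 0.9 * viol_hist[outer - 7]) {
      break
    }
    if (viol <= 0.5 * best_viol || viol < 10 * options$nlp_tol) {
      lamv <- lamv + mu * d$cv
      lamf <- lamf + mu * d$cf
      lame <- lame + mu * d$ce
      if (has_bend) eta <- pmax(0, eta + mu * d$g)
      best_viol <- viol
    } else {
      mu <- min(mu * 4, options$mu_max)
    }
  }
  v <- z[iv]; f <- z[iff]; e <- z[ie]; u <- z[iu]
  list(
    s = sgrid, v = v, f = f, e = e, u = u,
    viol = viol, nfev = nfev, outer = outer,
    converged = viol < max(options$nlp_tol, stall_accept),
    lam = list(lamv = lamv, lamf = lamf, lame = lame, eta = eta),
    mu = mu, z = z
  )
}

# forward re-integration of solved dynamics onto target grid nodes
# (classical RK4 via deSolve, driving f by interpolation of the solved
# force profile); returns v, e, t at the target nodes
reintegrate_states <- function(sol, params, target_s, options, refine = 6) {
  sp <- params$sigma
  e0 <- params$e0
  tau <- params$tau
  de0 <- options$taper_frac * e0
  mode <- options$resynthesis
  f_of_s <- approxfun(sol$s, sol$f, rule = 2)
  rhs <- function(s, y, parms) {
    v <- y[1]; e <- y[2]
    f <- f_of_s(s)
    w <- energy_rhs(v, f, e, e0, sp, mode, de0)$w
    list(c(v = (f - v / tau) / v, e = w, t = 1 / v))
  }
  # fine step sequence containing every target node
  steps <- unlist(lapply(seq_len(length(target_s) - 1), function(k) {
    seq(target_s[k], target_s[k + 1], length.out = refine + 1)[-(refine + 1)]
  }))
  steps <- c(steps, target_s[length(target_s)])
  out <- deSolve::ode(
    y = c(v = sol$v[1], e = sol$e[1], t = 0),
    times = steps, func = rhs, parms = NULL, method = "rk4"
  )
  idx <- match(target_s, steps)
  list(v = out[idx, "v"], e = out[idx, "e"], t = out[idx, "t"])
}

#' Solve the minimum-time race
#'
#' Finds the pacing strategy minimising the finish time subject to the
#' equations of motion, the energy balance, the centripetal force
#' constraint on bends, the force-rate (motor control) bounds and, if
#' given, a tactical [speed corridor][build_corridor]. The transcription
#' works in the distance domain with states `(v, f, e)` and control
#' `u = df/dt` on a fixed grid; elapsed time is recovered exactly for the
#' piecewise-linear speed profile, so the reported `final_time` equals the
#' quadrature of `1/v` over the race.
#'
#' @param params A [runner_params()].
#' @param track A [track_geometry()].
#' @param corridor Optional [speed corridor][build_corridor] restricting
#'   the speed between distance-dependent bounds. The lower bound is
#'   relaxed near the start (see
#'   [solver_options()]`$corridor_start_relax_m`) so the standing start is
#'   feasible.
#' @param options A [solver_options()].
#' @param warm Optional warm start: a previous `race_trajectory` for the
#'   same track and grid settings (used heavily during calibration).
#' @return A `race_trajectory`: a tibble with columns `s_m`, `t_s`,
#'   `v_mps`, `f_Nkg`, `e_Jkg`, `u_Nkgs`, `curvature_1pm` and attributes
#'   `final_time`, `solve_status` (`"converged"`, `"not_converged"` or
#'   `"infeasible"`), `viol`, `nfev`, `params`, `track`, `options`,
#'   `corridor`.
#' @examples
#' \donttest{
#' trk <- track_geometry(race_distance = 1500, bend_radius = Inf)
#' traj <- solve_race(default_winner_params(), trk,
#'                    options = solver_options(n_nodes = 150))
#' attr(traj, "final_time")
#' }
#' @export
solve_race <- function(params, track, corridor = NULL,
                       options = solver_options(), warm = NULL) {
  stopifnot(inherits(params, "runner_params"),
            inherits(track, "track_geometry"),
            inherits(options, "solver_options"))
  D <- track$race_distance

  if (!is.null(corridor)) {
    if (!inherits(corridor, "speed_corridor")) {
      abort("corridor must be a speed_corridor (see build_corridor())")
    }
    if (max(corridor$end_m) < D || min(corridor$start_m) > 0) {
      abort("corridor must cover [0, race_distance]")
    }
    if (any(corridor$v_lo > corridor$v_hi)) {
      abort("infeasible corridor: v_lo > v_hi")
    }
    if (any(corridor$v_lo > max_speed(params))) {
      return(failed_trajectory(params, track, corridor, options,
                               status = "infeasible",
                               reason = "corridor lower bound exceeds f_max * tau"))
    }
  }

  node_bounds <- function(sgrid) {
    N <- length(sgrid)
    lo <- rep(options$v_floor, N)
    hi <- rep(max_speed(params), N)
    if (!is.null(corridor)) {
      cb <- corridor_bounds_at(corridor, sgrid)
      # taper the lower bound up from v_floor over the start-relax
      # stretch so the standing start joins the corridor without a jump
      relax <- options$corridor_start_relax_m
      ramp <- if (relax > 0) pmin(1, sgrid / relax) else 1
      lo_c <- pmax(options$v_floor, cb$lo * ramp)
      lo <- pmax(lo, lo_c)
      hi <- pmin(hi, cb$hi)
    }
    lo[1] <- options$v_init
    hi[1] <- options$v_init
    if (any(lo > hi)) abort("infeasible speed bounds (corridor vs v limits)")
    list(lo = lo, hi = hi)
  }
  kappa_mid <- function(sgrid) {
    # curvature at interval midpoints avoids constraint jumps exactly on
    # segment boundaries; the last node reuses the final midpoint
    mids <- pmin(sgrid + c(diff(sgrid) / 2, 0), D)
    curvature_at(track, mids)
  }

  sgrid <- ocp_grid(D, options$n_nodes, options$start_ramp_h0,
                    options$start_ramp_growth)
  bnd <- node_bounds(sgrid)

  if (!is.null(warm) && inherits(warm, "race_trajectory") &&
      isTRUE(all.equal(attr(warm, "sgrid"), sgrid))) {
    core <- ocp_core(params, sgrid, kappa_mid(sgrid), bnd$lo, bnd$hi,
                     options,
                     warm = list(z = attr(warm, "z"),
                                 lam = attr(warm, "lam"),
                                 mu = min(attr(warm, "mu"), 1e6)))
  } else if (options$continuation &&
             options$coarse_nodes < options$n_nodes) {
    cg <- ocp_grid(D, options$coarse_nodes, options$start_ramp_h0,
                   options$start_ramp_growth)
    cb <- node_bounds(cg)
    coarse <- ocp_core(params, cg, kappa_mid(cg), cb$lo, cb$hi, options)
    # propagate to the full grid through exact forward integration of the
    # coarse control, then polish
    ri <- reintegrate_states(coarse, params, sgrid, options)
    f_i <- approx(coarse$s, coarse$f, sgrid, rule = 2)$y
    v_i <- pmin(pmax(ri$v, bnd$lo), bnd$hi)
    e_i <- pmin(pmax(ri$e, 0), params$e0)
    u_i <- pmin(pmax(c(diff(f_i) / diff(sgrid), 0) * v_i,
                     -params$u_minus), params$u_plus)
    core <- ocp_core(params, sgrid, kappa_mid(sgrid), bnd$lo, bnd$hi,
                     options,
                     warm = list(z = c(v_i, f_i, e_i, u_i),
                                 lam = list(
                                   lamv = approx(coarse$s[-1], coarse$lam$lamv,
                                                 sgrid[-1], rule = 2)$y,
                                   lamf = approx(coarse$s[-1], coarse$lam$lamf,
                                                 sgrid[-1], rule = 2)$y,
                                   lame = approx(coarse$s[-1], coarse$lam$lame,
                                                 sgrid[-1], rule = 2)$y,
                                   eta = approx(coarse$s, coarse$lam$eta,
                                                sgrid, rule = 2)$y
                                 ),
                                 mu = options$mu0))
  } else {
    core <- ocp_core(params, sgrid, kappa_mid(sgrid), bnd$lo, bnd$hi,
                     options)
  }

  t <- time_quadrature(core$s, core$v)
  status <- if (core$converged) {
    "converged"
  } else if (core$viol > 1e-3) {
    "infeasible"
  } else {
    "not_converged"
  }
  traj <- tibble::tibble(
    s_m = core$s,
    t_s = t,
    v_mps = core$v,
    f_Nkg = core$f,
    e_Jkg = core$e,
    u_Nkgs = core$u,
    curvature_1pm = curvature_at(track, pmin(core$s, D))
  )
  structure(
    traj,
    class = c("race_trajectory", class(traj)),
    final_time = t[length(t)],
    solve_status = status,
    viol = core$viol,
    nfev = core$nfev,
    outer = core$outer,
    params = params,
    track = track,
    options = options,
    corridor = corridor,
    sgrid = sgrid,
    z = core$z,
    lam = core$lam,
    mu = core$mu
  )
}

failed_trajectory <- function(params, track, corridor, options, status,
                              reason) {
  traj <- tibble::tibble(
    s_m = numeric(), t_s = numeric(), v_mps = numeric(),
    f_Nkg = numeric(), e_Jkg = numeric(), u_Nkgs = numeric(),
    curvature_1pm = numeric()
  )
  structure(
    traj,
    class = c("race_trajectory", class(traj)),
    final_time = NA_real_,
    solve_status = status,
    reason = reason,
    viol = Inf,
    params = params, track = track, options = options,
    corridor = corridor
  )
}

#' @export
print.race_trajectory <- function(x, ...) {
  st <- attr(x, "solve_status")
  ft <- attr(x, "final_time")
  cat(sprintf("<race_trajectory> status: %s", st))
  if (!is.na(ft)) {
    cat(sprintf(", final time %.2f s (%s), %d nodes",
                ft, format_race_time(ft), nrow(x)))
  }
  cat("\n")
  if (!is.null(attr(x, "reason"))) cat("  ", attr(x, "reason"), "\n")
  NextMethod()
}

#' Check a solved trajectory against the continuous dynamics
#'
#' Independent consistency oracle: re-integrates the equations of motion
#' forward with a fine fixed-step classical Runge-Kutta scheme, driving
#' the propulsive force by the solved profile, and reports the deviation
#' of speed, energy and elapsed time at every 100 m segment end together
#' with the energy-balance residual `|e(D) - e0 - integral(sigma - f v) dt|`.
#'
#' @param traj A converged `race_trajectory` from [solve_race()].
#' @param params,track The inputs used for the solve (defaults taken from
#'   the trajectory's attributes).
#' @param v_tol,e_tol_frac,segment_length Tolerances: maximal speed
#'   deviation at segment ends (m/s) and maximal energy residual as a
#'   fraction of `e0`.
#' @param refine RK4 sub-steps per trajectory grid interval.
#' @return An object of class `trajectory_verification`: a list with the
#'   per-quantity maximal deviations, the energy residual, a per-segment
#'   tibble, and `ok`.
#' @export
verify_trajectory <- function(traj,
                              params = attr(traj, "params"),
                              track = attr(traj, "track"),
                              v_tol = 1e-2,
                              e_tol_frac = 0.01,
                              segment_length = 100,
                              refine = 6) {
  stopifnot(inherits(traj, "race_trajectory"))
  if (attr(traj, "solve_status") != "converged") {
    abort("verify_trajectory() needs a converged trajectory")
  }
  options <- attr(traj, "options")
  sol <- list(s = traj$s_m, v = traj$v_mps, f = traj$f_Nkg, e = traj$e_Jkg)
  ri <- reintegrate_states(sol, params, traj$s_m, options, refine = refine)
  D <- track$race_distance
  marks <- seq(segment_length, D, by = segment_length)
  idx <- vapply(marks, function(m) which.min(abs(traj$s_m - m)), integer(1))
  dv <- ri$v - traj$v_mps
  de <- ri$e - traj$e_Jkg
  dt <- ri$t - traj$t_s
  # energy-balance residual of the solved profile, measured against the
  # re-integrated energy (which by construction equals
  # e0 + integral of (sigma - f v) dt along the re-integrated path)
  n <- length(traj$s_m)
  energy_residual <- abs(traj$e_Jkg[n] - ri$e[n])
  per_segment <- tibble::tibble(
    distance_end_m = marks,
    dv_mps = dv[idx],
    de_Jkg = de[idx],
    dt_s = dt[idx]
  )
  res <- list(
    max_dv_at_segments = max(abs(dv[idx])),
    max_de_at_segments = max(abs(de[idx])),
    max_dt_at_segments = max(abs(dt[idx])),
    energy_residual = energy_residual,
    energy_residual_frac = energy_residual / params$e0,
    final_time_deviation = abs(dt[n]),
    per_segment = per_segment,
    v_tol = v_tol,
    e_tol_frac = e_tol_frac
  )
  res$ok <- res$max_dv_at_segments < v_tol &&
    res$energy_residual_frac < e_tol_frac
  structure(res, class = "trajectory_verification")
}

#' @export
print.trajectory_verification <- function(x, ...) {
  cat(sprintf(
    paste0("<trajectory_verification> %s\n",
           "  max |dv| at segment ends: %.2e m/s (tol %.1e)\n",
           "  energy residual: %.3g J/kg (%.3g%% of e0, tol %.1f%%)\n",
           "  final-time deviation: %.3g s\n"),
    if (x$ok) "OK" else "VIOLATION",
    x$max_dv_at_segments, x$v_tol,
    x$energy_residual, 100 * x$energy_residual_frac, 100 * x$e_tol_frac,
    x$final_time_deviation
  ))
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' @param traj A `race_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "race_trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV file path.
#' @return A tibble with the trajectory columns (without solver
#'   attributes).
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- read.csv(path)
  needed <- c("s_m", "t_s", "v_mps", "f_Nkg", "e_Jkg")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("trajectory file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tibble::as_tibble(df)
}
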