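# Solver behaviour on short courses; the full-race experiments live in
# the acceptance suite.

test_that("the merit-function gradient matches finite differences", {
  set.seed(42)
  p <- default_winner_params()
  D <- 800
  sg <- trackpace:::ocp_grid(D, 60)
  N <- length(sg)
  h <- diff(sg)
  wq <- c(h / 2, 0) + c(0, h / 2)
  kap <- curvature_at(track_geometry(race_distance = D),
                      pmin(sg + c(h / 2, 0), D))
  z <- c(runif(N, 4, 7), runif(N, 2, 6),
         seq(p$e0, 100, length.out = N), runif(N, -0.2, 0.2))
  lam <- list(lamv = rnorm(N - 1), lamf = rnorm(N - 1),
              lame = rnorm(N - 1), eta = abs(rnorm(N)))
  ev <- function(z) {
    trackpace:::.ocp_al_eval(
      z, h, lam$lamv, lam$lamf, lam$lame, lam$eta, 100,
      p$tau, p$f_max, p$e0,
      p$sigma$sigma_max, p$sigma$sigma_rest, p$sigma$sigma_final,
      p$sigma$phi_ramp, p$sigma$phi_final,
      0.02 * p$e0, FALSE, kap^2, wq, 10, 1e-4, TRUE, FALSE
    )
  }
  g <- ev(z)$grad
  idx <- sample(length(z), 50)
  fd <- vapply(idx, function(i) {
    d <- 1e-6 * max(1, abs(z[i]))
    zp <- z; zp[i] <- z[i] + d
    zm <- z; zm[i] <- z[i] - d
    (ev(zp)$value - ev(zm)$value) / (2 * d)
  }, numeric(1))
  expect_lt(max(abs(fd - g[idx]) / pmax(1e-6, abs(fd))), 1e-4)
})

test_that("a corridor pinning the speed reproduces distance/speed timing", {
  trk <- flat_track(1000)
  p <- default_winner_params()
  corridor <- structure(
    tibble::tibble(start_m = 0, end_m = 1000, v_lo = 6, v_hi = 6),
    class = c("speed_corridor", "tbl_df", "tbl", "data.frame"),
    race_distance = 1000
  )
  traj <- solve_race(p, trk, corridor = corridor,
                     options = fast_options(n_nodes = 100, coarse_nodes = 51,
                                            v_init = 6,
                                            corridor_start_relax_m = 0))
  expect_equal(attr(traj, "solve_status"), "converged")
  expect_equal(attr(traj, "final_time"), 1000 / 6,
               tolerance = 1e-3)
})

test_that("the solution is consistent under grid refinement", {
  trk <- flat_track(1500)
  p <- default_winner_params()
  t_coarse <- attr(solve_race(p, trk, options = fast_options(150)),
                   "final_time")
  t_fine <- attr(solve_race(p, trk, options = fast_options(600)),
                 "final_time")
  expect_equal(t_coarse, t_fine, tolerance = 2e-3)
})

test_that("converged trajectories satisfy the path constraints", {
  p <- default_winner_params()
  trk <- track_geometry(race_distance = 800)
  opt <- fast_options(n_nodes = 200, coarse_nodes = 81)
  traj <- solve_race(p, trk, options = opt)
  expect_equal(attr(traj, "solve_status"), "converged")
  tol <- 1e-3
  expect_true(all(diff(traj$t_s) > 0))
  expect_equal(traj$t_s[1], 0)
  expect_equal(tail(traj$t_s, 1), attr(traj, "final_time"))
  expect_true(all(traj$v_mps >= opt$v_floor - tol))
  expect_true(all(traj$e_Jkg >= -tol))
  expect_true(all(traj$f_Nkg >= -tol))
  expect_true(all(traj$u_Nkgs >= -p$u_minus - tol &
                    traj$u_Nkgs <= p$u_plus + tol))
  # centripetal force budget at every node
  kap <- curvature_at(trk, pmin(traj$s_m + c(diff(traj$s_m) / 2, 0), 800))
  expect_true(all(traj$f_Nkg^2 + traj$v_mps^4 * kap^2 <=
                    p$f_max^2 * (1 + 1e-3)))
})

test_that("the reported final time is the quadrature of 1/v", {
  trk <- flat_track(1500)
  traj <- solve_race(default_winner_params(), trk,
                     options = fast_options())
  tq <- trackpace:::time_quadrature(traj$s_m, traj$v_mps)
  expect_equal(attr(traj, "final_time"), tail(tq, 1), tolerance = 1e-9)
  expect_equal(traj$t_s, tq, tolerance = 1e-9)
})

test_that("forward re-integration reproduces short-course solutions", {
  trk <- flat_track(1500)
  p <- default_winner_params()
  traj <- solve_race(p, trk, options = fast_options(300))
  v <- verify_trajectory(traj, segment_length = 100)
  expect_true(v$ok)
  expect_lt(v$max_dv_at_segments, 1e-2)
  expect_lt(v$energy_residual_frac, 0.01)
})

test_that("a corrupted force profile is flagged by verification", {
  trk <- flat_track(1500)
  p <- default_winner_params()
  traj <- solve_race(p, trk, options = fast_options(300))
  bad <- traj
  bad$f_Nkg <- bad$f_Nkg * 1.1
  vb <- verify_trajectory(bad)
  expect_false(vb$ok)
})

test_that("more anaerobic energy never slows the optimum", {
  trk <- flat_track(1500)
  p <- default_winner_params()
  opt <- fast_options(150)
  t1 <- attr(solve_race(p, trk, options = opt), "final_time")
  t95 <- attr(solve_race(perturb_params(p, "e0", 0.95), trk,
                         options = opt), "final_time")
  t90 <- attr(solve_race(perturb_params(p, "e0", 0.90), trk,
                         options = opt), "final_time")
  expect_gte(t95, t1 - 1e-6)
  expect_gte(t90, t95 - 1e-6)
})

test_that("better economy or force never slows the optimum", {
  trk <- flat_track(1500)
  p <- default_winner_params()
  opt <- fast_options(150)
  t_base <- attr(solve_race(p, trk, options = opt), "final_time")
  t_tau <- attr(solve_race(perturb_params(p, "tau", 1.05), trk,
                           options = opt), "final_time")
  t_f <- attr(solve_race(perturb_params(p, "f_max", 1.05), trk,
                         options = opt), "final_time")
  expect_lte(t_tau, t_base + 1e-6)
  expect_lte(t_f, t_base + 0.01)
})

test_that("an unreachable corridor reports infeasibility, not a result", {
  p <- default_winner_params()
  trk <- flat_track(1000)
  fast <- structure(
    tibble::tibble(start_m = 0, end_m = 1000, v_lo = 13, v_hi = 14),
    class = c("speed_corridor", "tbl_df", "tbl", "data.frame"),
    race_distance = 1000
  )
  traj <- solve_race(p, trk, corridor = fast, options = fast_options(100))
  expect_equal(attr(traj, "solve_status"), "infeasible")
  expect_true(is.na(attr(traj, "final_time")))

  crossed <- structure(
    tibble::tibble(start_m = 0, end_m = 1000, v_lo = 6, v_hi = 5),
    class = c("speed_corridor", "tbl_df", "tbl", "data.frame"),
    race_distance = 1000
  )
  expect_error(solve_race(p, trk, corridor = crossed), "infeasible")
})

test_that("trajectories round-trip through CSV", {
  trk <- flat_track(1500)
  traj <- solve_race(default_winner_params(), trk,
                     options = fast_options())
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  df <- read_trajectory(path)
  expect_equal(df$v_mps, traj$v_mps, tolerance = 1e-9)
  expect_error(read_trajectory(
    withr::local_tempfile(lines = "a,b\n1,2", fileext = ".csv")
  ), "missing column")
})
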