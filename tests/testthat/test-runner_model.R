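test_that("sigma(e) hits its anchor values and interpolates linearly", {
  e0 <- 1500
  sp <- sigma_profile(sigma_max = 25, sigma_rest = 7.5, sigma_final = 20,
                      phi_ramp = 0.9, phi_final = 0.2)
  expect_equal(sigma_of_e(e0, e0, sp), 7.5)            # gun: rest uptake
  expect_equal(sigma_of_e(0, e0, sp), 20)              # exhaustion
  expect_equal(sigma_of_e(0.9 * e0, e0, sp), 25)       # plateau edges
  expect_equal(sigma_of_e(0.2 * e0, e0, sp), 25)
  expect_equal(sigma_of_e(0.5 * e0, e0, sp), 25)       # plateau interior
  # midpoint of the final drop
  expect_equal(sigma_of_e(0.5 * 0.2 * e0, e0, sp), (20 + 25) / 2)
  expect_error(sigma_of_e(-1, e0, sp), "e must lie")
})

test_that("sigma(e) is continuous at both breakpoints", {
  e0 <- 1234
  sp <- sigma_profile()
  for (b in c(sp$phi_final, sp$phi_ramp) * e0) {
    eps <- 1e-9 * e0
    expect_equal(sigma_of_e(b - eps, e0, sp), sigma_of_e(b + eps, e0, sp),
                 tolerance = 1e-6)
  }
})

test_that("oxygen uptake converts to mechanical power", {
  expect_equal(vo2_to_power(0), 0)
  expect_equal(vo2_to_power(85), 85 * 20.9 / 60, tolerance = 1e-12)
  expect_equal(vo2_to_power(0.85 * 85), 25.1670833, tolerance = 1e-6)
  expect_error(vo2_to_power(-1), "non-negative")
})

test_that("dynamics follow Newton's law and the energy balance", {
  p <- default_winner_params()
  # steady state: f = v/tau gives no acceleration
  d <- dynamics_rhs(v = 6, f = 6 / p$tau, e = 750, u = 0.1, p)
  expect_equal(d$dv_dt, 0)
  expect_equal(d$df_dt, 0.1)
  # mid-plateau energy balance: de/dt = sigma_max - f*v
  d2 <- dynamics_rhs(v = 6, f = 4, e = 750, u = 0, p)
  expect_equal(d2$de_dt, p$sigma$sigma_max - 24)
  # energy-neutral cruise: f*v = sigma_max at steady state means
  # v = sqrt(sigma_max * tau)
  v_star <- sqrt(p$sigma$sigma_max * p$tau)
  d3 <- dynamics_rhs(v = v_star, f = v_star / p$tau, e = 750, u = 0, p)
  expect_equal(d3$de_dt, 0, tolerance = 1e-9)
  expect_equal(d3$dv_dt, 0)
})

test_that("energy drains exactly when propulsive power exceeds sigma", {
  p <- default_winner_params()
  grid <- expand.grid(v = c(2, 5, 8), f = c(1, 4, 7), e = c(100, 750, 1400))
  d <- dynamics_rhs(grid$v, grid$f, grid$e, 0, p)
  sig <- sigma_of_e(grid$e, p$e0, p$sigma)
  expect_equal(d$de_dt > 0, sig > grid$f * grid$v)
})

test_that("bend force cap follows the centripetal trade-off", {
  expect_equal(bend_force_cap(7, Inf, 8), 8)
  expect_equal(bend_force_cap(0, 36.5, 8), 8)
  expect_equal(bend_force_cap(7, 36.5, 8), sqrt(64 - 2401 / 36.5^2))
  expect_equal(bend_force_cap(7, 36.5, 8), 7.8866, tolerance = 1e-4)
  expect_lt(bend_force_cap(sqrt(8 * 36.5), 36.5, 8), 1e-6)
  expect_equal(bend_force_cap(18, 36.5, 8), 0)   # beyond saturation
  # monotone: non-increasing in v, non-decreasing in R and f_max
  v <- seq(0, 15, by = 0.25)
  cap <- bend_force_cap(v, 36.5, 8)
  expect_true(all(diff(cap) <= 1e-12))
  expect_true(all(bend_force_cap(6, c(20, 36.5, 50, Inf), 8) ==
                    cummax(bend_force_cap(6, c(20, 36.5, 50, Inf), 8))))
  expect_true(bend_force_cap(6, 36.5, 9) >= bend_force_cap(6, 36.5, 8))
})

test_that("maximal speed is f_max * tau and exceeds the aerobic cruise", {
  p <- default_winner_params()
  expect_equal(max_speed(p), p$f_max * p$tau)
  expect_equal(max_speed(runner_params(1500, 8, 1.5, 0.25, 0.25)), 12)
  expect_gt(max_speed(p), sqrt(p$sigma$sigma_max * p$tau))
})

test_that("parameter invariants are enforced with the offending key named", {
  expect_error(runner_params(-1, 8, 1.55, 0.25, 0.25), "e0")
  expect_error(runner_params(1500, 8, 0.1, 0.25, 0.25), "sanity window")
  expect_error(sigma_profile(sigma_rest = 30, sigma_max = 25), "sigma_rest")
  expect_error(sigma_profile(phi_ramp = 0.2, phi_final = 0.5), "phi_final")
})

test_that("runner parameters round-trip through JSON", {
  p <- runner_params(1321, 7.5, 1.61, 0.21, 0.31,
                     sigma_profile(24.5, 8.1, 19.9, 0.88, 0.18))
  path <- withr::local_tempfile(fileext = ".json")
  write_runner_params(p, path)
  q <- read_runner_params(path)
  expect_equal(q$e0, p$e0)
  expect_equal(q$tau, p$tau)
  expect_equal(q$sigma$sigma_final, p$sigma$sigma_final)
  expect_equal(q$sigma$phi_ramp, p$sigma$phi_ramp)
})

test_that("reading an incomplete runner config names the missing key", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(e0 = 1500, tau = 1.5), path, auto_unbox = TRUE)
  expect_error(read_runner_params(path), "f_max")
})
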