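# Calibration mechanics on a short course; the full parameter-recovery
# experiment runs in the acceptance suite.

short_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- default_winner_params()
      trk <- flat_track(2000)
      opt <- fast_options(n_nodes = 200, coarse_nodes = 101)
      race <- generate_race(p, "even", trk, opt, noise_sd = 0, seed = 5)
      cache <<- list(p = p, trk = trk, opt = opt,
                     obs = race$splits, corridor = race$truth$corridor)
    }
    cache
  }
})

test_that("fit_error is deterministic and zero at the generating truth", {
  fx <- short_fixture()
  r1 <- fit_error(fx$p, fx$obs, fx$trk, corridor = fx$corridor,
                  options = fx$opt)
  r2 <- fit_error(fx$p, fx$obs, fx$trk, corridor = fx$corridor,
                  options = fx$opt)
  expect_identical(as.numeric(r1), as.numeric(r2))
  expect_lt(as.numeric(r1), 0.02)
  expect_length(attr(r1, "residuals"), 20)
})

test_that("perturbing the generating parameters increases the fit error", {
  fx <- short_fixture()
  r_true <- as.numeric(fit_error(fx$p, fx$obs, fx$trk,
                                 corridor = fx$corridor, options = fx$opt))
  r_less <- as.numeric(fit_error(perturb_params(fx$p, "e0", 0.9),
                                 fx$obs, fx$trk, corridor = fx$corridor,
                                 options = fx$opt))
  expect_gt(r_less, r_true)
})

test_that("a budget of one returns the initial evaluation", {
  fx <- short_fixture()
  init <- scaled_params(fx$p, 1.05)
  fit <- calibrate(fx$obs, init, budget = 1, track = fx$trk,
                   corridor = fx$corridor, options = fx$opt)
  expect_equal(fit$n_solves, 1L)
  expect_equal(trackpace:::params_to_theta(fit$params),
               trackpace:::params_to_theta(init), tolerance = 1e-5)
  # the logit box transform clips by one part in a million, so the
  # evaluated parameters agree to that level rather than exactly
  r_init <- as.numeric(fit_error(init, fx$obs, fx$trk,
                                 corridor = fx$corridor, options = fx$opt))
  expect_equal(fit$rmse, r_init, tolerance = 1e-4)
})

test_that("calibrate honours bounds and reports tidy summaries", {
  fx <- short_fixture()
  init <- fx$p
  bounds <- list(
    e0 = init$e0 * c(0.9, 1.1),
    f_max = init$f_max * c(0.9, 1.1),
    tau = init$tau * c(0.9, 1.1),
    u_plus = init$u_plus * c(0.9, 1.1),
    u_minus = init$u_minus * c(0.9, 1.1),
    sigma_max = init$sigma$sigma_max * c(0.9, 1.1),
    sigma_final = init$sigma$sigma_final * c(0.9, 1.1)
  )
  fit <- calibrate(fx$obs, init, bounds = bounds, budget = 12,
                   track = fx$trk, corridor = fx$corridor,
                   options = fx$opt)
  th <- trackpace:::params_to_theta(fit$params)
  lo <- vapply(trackpace:::theta_names, function(k) bounds[[k]][1],
               numeric(1))
  hi <- vapply(trackpace:::theta_names, function(k) bounds[[k]][2],
               numeric(1))
  expect_true(all(th >= lo - 1e-9 & th <= hi + 1e-9))
  expect_lte(fit$n_solves, 12)
  expect_length(fit$history, fit$n_solves)

  td <- tidy(fit)
  expect_equal(td$term, trackpace:::theta_names)
  expect_equal(td$estimate, unname(th))
  g <- glance(fit)
  expect_equal(g$n_solves, fit$n_solves)
  expect_equal(g$n_segments, 20)

  expect_error(
    calibrate(fx$obs, scaled_params(init, 1.5), bounds = bounds,
              budget = 2, track = fx$trk, options = fx$opt),
    "within bounds"
  )
})

test_that("fit results serialise to JSON with the residual vector", {
  fx <- short_fixture()
  fit <- calibrate(fx$obs, fx$p, budget = 1, track = fx$trk,
                   corridor = fx$corridor, options = fx$opt)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$params$e0, fit$params$e0)
  expect_length(x$residuals, 20)
  expect_equal(x$rmse, fit$rmse)
})
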