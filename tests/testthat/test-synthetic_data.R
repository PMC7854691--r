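test_that("tactic templates have the documented shapes", {
  tac <- default_tactics()
  expect_setequal(names(tac),
                  c("even", "championship_surge", "fast_finish"))

  ev <- tac$even
  expect_equal(nrow(ev$profile), 1)
  expect_equal(ev$profile$rel_speed, 1)
  expect_length(ev$tight_windows, 0)

  cs <- tac$championship_surge
  # the mid-race surge is elevated about 2% over the cruise pieces
  surge <- cs$profile$rel_speed[cs$profile$start_m == 4000]
  cruise <- cs$profile$rel_speed[cs$profile$start_m == 200]
  expect_equal(surge / cruise, 1.02 / 0.993, tolerance = 1e-6)
  expect_true(any(vapply(cs$tight_windows, function(w) {
    w[1] == 4000 && w[2] == 6000
  }, logical(1))))

  ff <- tac$fast_finish
  after <- ff$profile[ff$profile$start_m >= 7000, ]
  expect_true(all(diff(after$rel_speed) > 0))
  expect_gt(min(after$rel_speed), max(ff$profile$rel_speed[1]))
})

test_that("templates are harmonically normalised (time-preserving)", {
  for (t in default_tactics()) {
    p <- t$profile
    w <- (p$end_m - p$start_m) / max(p$end_m)
    expect_equal(sum(w / p$rel_speed), 1, tolerance = 1e-9)
  }
})

test_that("tactic corridors scale to the race and respect tight windows", {
  p <- default_winner_params()
  trk <- track_geometry()
  cor <- tactic_corridor("championship_surge", p, trk)
  expect_equal(nrow(cor), 100)
  expect_equal(max(cor$end_m), 10000)
  width <- cor$v_hi - cor$v_lo
  mid <- (cor$start_m + cor$end_m) / 2
  expect_equal(unique(width[mid > 4000 & mid < 6000]), 0.2)
  expect_equal(unique(width[mid > 2000 & mid < 4000]), 0.6)
  # anchored near the energy-balance cruise pace
  vbar <- mean((cor$v_lo + cor$v_hi) / 2)
  expect_gt(vbar, 5.5)
  expect_lt(vbar, 7)
  expect_error(tactic_corridor("no_such", p, trk), "unknown tactic")
})

test_that("timing noise has the advertised per-split magnitude", {
  clean <- split_series(rep(16, 100))
  reps <- vapply(1:200, function(i) {
    add_timing_noise(clean, noise_sd = 0.05, seed = 1000 + i)$time_s
  }, numeric(100))
  sds <- apply(reps, 1, sd)
  # every split's replicate sd is within 15% of the nominal 0.05 s...
  expect_true(all(abs(sds - 0.05) / 0.05 < 0.15))
  # ...and unbiased
  expect_equal(mean(reps), 16, tolerance = 1e-3)
})

test_that("noise never leaves non-positive splits (re-draw path)", {
  tiny <- split_series(rep(0.05, 20))
  suppressMessages(
    noisy <- add_timing_noise(tiny, noise_sd = 0.1, seed = 3)
  )
  expect_true(all(noisy$time_s > 0))
  expect_gt(attr(noisy, "n_redrawn"), 0)
})

test_that("noise application preserves the global RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(add_timing_noise(split_series(rep(16, 10)), 0.05, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("an infeasible tactic is rejected with the failing window named", {
  # built-in corridors anchor to the runner's own sustainable pace, so an
  # impossible tactic needs a pathological template: a closing 2,000 m at
  # 40% above the anchor pace is far beyond the aerobic ceiling
  suicide <- structure(
    list(
      name = "suicide_finish",
      profile = tibble::tibble(start_m = c(0, 8000),
                               end_m = c(8000, 10000),
                               rel_speed = c(0.95, 1.4)),
      tight_windows = list(),
      delta_wide = 0.3, delta_tight = 0.1
    ),
    class = "tactic_template"
  )
  expect_error(
    generate_race(default_winner_params(), suicide, track_geometry(),
                  solver_options(n_nodes = 300, coarse_nodes = 151),
                  noise_sd = 0),
    "infeasible.*store runs out near 8[0-9]{3}"
  )
})

test_that("zero-noise generation is seed-independent and self-described", {
  p <- default_winner_params()
  trk <- track_geometry()
  opt <- solver_options(n_nodes = 300, coarse_nodes = 151)
  r1 <- generate_race(p, "even", trk, opt, noise_sd = 0, seed = 1)
  r2 <- generate_race(p, "even", trk, opt, noise_sd = 0, seed = 999)
  expect_equal(r1$splits$time_s, r2$splits$time_s)
  expect_equal(r1$splits$time_s, r1$truth$noise_free_splits$time_s)
  expect_equal(r1$truth$tactic, "even")
  expect_s3_class(r1$truth$corridor, "speed_corridor")
  expect_equal(sum(r1$splits$time_s), r1$truth$final_time,
               tolerance = 1e-6)
})
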