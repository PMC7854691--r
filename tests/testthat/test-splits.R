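test_that("constant-speed trajectories give equal splits", {
  traj <- constant_speed_trajectory(v = 5, D = 1000)
  sp <- compute_splits(traj)
  expect_equal(nrow(sp), 10)
  expect_equal(sp$time_s, rep(20, 10))
  expect_equal(sp$mean_speed_mps, rep(5, 10))
})

test_that("splits are exact for a linear speed ramp (closed-form integral)", {
  # v rising linearly 4 -> 6 m/s over one 100 m segment:
  # T = 100 * log(6/4) / 2
  s <- seq(0, 100, by = 5)
  traj <- tibble::tibble(s_m = s, v_mps = 4 + 2 * s / 100)
  sp <- compute_splits(traj)
  expect_equal(sp$time_s, 100 * log(6 / 4) / 2, tolerance = 1e-9)
  expect_equal(sp$time_s, 20.2733, tolerance = 1e-4)
})

test_that("split times are additive: they sum to the final time", {
  trk <- flat_track(1500)
  traj <- solve_race(default_winner_params(), trk, options = fast_options())
  sp <- compute_splits(traj)
  expect_equal(sum(sp$time_s), attr(traj, "final_time"),
               tolerance = 1e-9)
  expect_equal(sp$mean_speed_mps * sp$time_s, rep(100, nrow(sp)),
               tolerance = 1e-9)
})

test_that("splits refuse inconsistent geometry", {
  traj <- constant_speed_trajectory(v = 5, D = 1000, by = 250)
  expect_error(compute_splits(traj), "coarser")
  expect_error(compute_splits(constant_speed_trajectory(D = 950)),
               "divide")
})

test_that("split series round-trip the CSV format losslessly", {
  sp <- split_series(16 + sin(1:100) * 0.8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_splits(sp, path)
  sp2 <- read_splits(path)
  expect_equal(sp2$time_s, sp$time_s, tolerance = 1e-9)
  expect_equal(sp2$mean_speed_mps, sp$mean_speed_mps, tolerance = 1e-9)
})

test_that("the splits reader validates structure and names the row", {
  sp <- split_series(rep(16, 100))
  df <- as.data.frame(sp)

  p1 <- withr::local_tempfile(fileext = ".csv")
  df1 <- df; df1$time_s[17] <- 0
  write.csv(df1, p1, row.names = FALSE)
  expect_error(read_splits(p1), "row 17")

  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[-60, ], p2, row.names = FALSE)   # 99 rows with a gap
  expect_error(read_splits(p2), "not contiguous")

  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[1:99, ], p3, row.names = FALSE)  # truncated file
  expect_error(read_splits(p3, race_distance = 10000), "expected 100")

  p4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, -3], p4, row.names = FALSE)
  expect_error(read_splits(p4), "time_s")

  p5 <- withr::local_tempfile(fileext = ".csv")
  df5 <- df; df5$mean_speed_mps[3] <- df5$mean_speed_mps[3] * 1.01
  write.csv(df5, p5, row.names = FALSE)
  expect_warning(read_splits(p5), "disagrees")
})

test_that("corridor bounds wrap a moving-average centreline", {
  sp <- split_series(rep(100 / 6, 100))      # constant 6 m/s
  cor <- build_corridor(sp, delta_wide = 0.3)
  expect_equal(nrow(cor), 100)
  wide <- cor$start_m >= 200 & (cor$start_m < 4000 | cor$start_m >= 6000)
  expect_equal(cor$v_lo[wide], rep(5.7, sum(wide)))
  expect_equal(cor$v_hi[wide], rep(6.3, sum(wide)))
  # tight windows at the start and the mid-race surge
  tight <- !wide
  expect_equal(cor$v_lo[tight], rep(5.9, sum(tight)))
  expect_equal(cor$v_hi[tight], rep(6.1, sum(tight)))
})

test_that("the corridor centreline is the centred moving average", {
  v <- 5 + (1:12)                      # strictly increasing speeds
  sp <- split_series(100 / v)
  cor <- build_corridor(sp, smooth_window = 3, delta_wide = 0.3,
                        tight_windows = list())
  centre <- (cor$v_lo + cor$v_hi) / 2
  # interior points: mean of the three neighbouring speeds
  for (i in 2:11) expect_equal(centre[i], mean(v[(i - 1):(i + 1)]))
  # truncated edges
  expect_equal(centre[1], mean(v[1:2]))
})

test_that("tight windows equal to the wide delta change nothing", {
  sp <- split_series(100 / (6 + sin(1:100) / 5))
  c1 <- build_corridor(sp, delta_wide = 0.25, delta_tight = 0.25)
  c2 <- build_corridor(sp, delta_wide = 0.25, tight_windows = list())
  expect_equal(c1$v_lo, c2$v_lo)
  expect_equal(c1$v_hi, c2$v_hi)
})

test_that("overlapping tight windows are rejected", {
  sp <- split_series(rep(16, 100))
  expect_error(
    build_corridor(sp, tight_windows = list(c(0, 300), c(200, 500))),
    "overlap"
  )
})
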