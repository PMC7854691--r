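# Shared fixtures. Tests favour short races and coarse grids so the whole
# suite stays fast; the acceptance tests run the full-scale experiments.

fast_options <- function(n_nodes = 150, coarse_nodes = 76, ...) {
  solver_options(n_nodes = n_nodes, coarse_nodes = coarse_nodes, ...)
}

# a short bend-free course: curvature zero everywhere, same segmentation
flat_track <- function(race_distance = 1500) {
  track_geometry(race_distance = race_distance, bend_radius = Inf)
}

# constant-speed trajectory covering [0, D]
constant_speed_trajectory <- function(v = 5, D = 1000, by = 10) {
  s <- seq(0, D, by = by)
  tibble::tibble(
    s_m = s,
    t_s = s / v,
    v_mps = rep(v, length(s)),
    f_Nkg = rep(v / 1.55, length(s)),
    e_Jkg = seq(1500, 1000, length.out = length(s)),
    u_Nkgs = rep(0, length(s)),
    curvature_1pm = rep(0, length(s))
  )
}

# scale a parameter vector multiplicatively, clipping tau so the maximal
# speed stays inside the sanity window
scaled_params <- function(params, factor) {
  th <- trackpace:::params_to_theta(params) * factor
  th[3] <- min(th[3], 14.9 / th[2])
  trackpace:::theta_to_params(th, params)
}
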