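#' Parse and format race times
#'
#' Athletics results are printed as `min:s` (e.g. `"26:49.51"`) or
#' `h:min:s`. `parse_race_time()` converts such a string to seconds;
#' `format_race_time()` does the reverse.
#'
#' @param x A character vector of times like `"26:49.51"`.
#' @return Seconds as a numeric vector.
#' @examples
#' parse_race_time("26:49.51") - parse_race_time("26:46.57")
#' format_race_time(1609.51)
#' @export
parse_race_time <- function(x) {
  vapply(x, function(s) {
    parts <- suppressWarnings(as.numeric(strsplit(s, ":", fixed = TRUE)[[1]]))
    if (any(is.na(parts)) || length(parts) < 1 || length(parts) > 3) {
      abort(sprintf("cannot parse race time '%s'", s))
    }
    sum(parts * 60^(rev(seq_along(parts)) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname parse_race_time
#' @param seconds Numeric seconds.
#' @param digits Decimal places for the seconds field.
#' @export
format_race_time <- function(seconds, digits = 2) {
  vapply(seconds, function(t) {
    m <- floor(t / 60)
    s <- t - 60 * m
    sprintf(paste0("%d:%0", 3 + digits, ".", digits, "f"), m, s)
  }, character(1), USE.NAMES = FALSE)
}

#' Read a pipeline configuration file
#'
#' A single JSON file can configure the whole pipeline under the keys
#' `track` (passed to [track_geometry()]), `runner` (see
#' [read_runner_params()]), `solver` (passed to [solver_options()]) and
#' `tactic` (a name from [default_tactics()]). All keys are optional;
#' omitted sections fall back to package defaults. Validation errors name
#' the offending key.
#'
#' @param path JSON file path.
#' @return A list with elements `track`, `runner`, `solver`, `tactic`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  track <- if (!is.null(raw$track)) {
    do.call(track_geometry, raw$track)
  } else {
    track_geometry()
  }
  runner <- if (!is.null(raw$runner)) {
    sig_keys <- c("sigma_max", "sigma_rest", "sigma_final",
                  "phi_ramp", "phi_final")
    sigma <- do.call(sigma_profile, raw$runner[intersect(sig_keys, names(raw$runner))])
    core <- raw$runner[intersect(c("e0", "f_max", "tau", "u_plus", "u_minus"),
                                 names(raw$runner))]
    do.call(runner_params, c(core, list(sigma = sigma)))
  } else {
    default_winner_params()
  }
  solver <- if (!is.null(raw$solver)) {
    do.call(solver_options, raw$solver)
  } else {
    solver_options()
  }
  tactic <- raw$tactic %||% "championship_surge"
  list(track = track, runner = runner, solver = solver, tactic = tactic)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
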