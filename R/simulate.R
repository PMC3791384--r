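# Two-state correlated-random-walk simulator of arena trajectories.
#
# Each animal alternates between pause and movement states of a discrete
# Markov chain; while moving it takes steps with positive-truncated-normal
# length and a persistent heading that is (i) perturbed by a Gaussian
# circular deviate whose spread is set by the turning concentration and
# (ii) pulled toward (or pushed away from) the stimulus partition and along
# the nearest wall, with configurable weights. Walls reflect, so no
# artificial dwell accumulates at the boundary beyond what wall affinity
# produces.

#' Movement parameters of one behavioral phase
#'
#' @param p_start_move Per-second probability of leaving the pause state.
#' @param p_stop_move Per-second probability of ending a movement bout.
#' @param speed_mean Mean speed while moving, cm/s (positive).
#' @param speed_sd Step-to-step speed standard deviation, cm/s.
#' @param turn_concentration Directional persistence of the heading
#'   (>= 0); the per-step heading perturbation has standard deviation
#'   `1/sqrt(turn_concentration)` radians, and 0 means a fresh uniform
#'   heading every step.
#' @param stimulus_bias In `[-1, 1]`: weight with which the heading is mixed
#'   toward (positive) or away from (negative) the stimulus partition.
#' @param wall_affinity In `[0, 1]`: weight with which the heading is mixed
#'   along the nearest wall (thigmotaxis). `abs(stimulus_bias) +
#'   wall_affinity` must not exceed 1.
#' @return An object of class `"phase_params"`.
#' @export
phase_params <- function(p_start_move, p_stop_move, speed_mean,
                         speed_sd = speed_mean / 3, turn_concentration = 4,
                         stimulus_bias = 0, wall_affinity = 0) {
  if (p_start_move < 0 || p_start_move > 1 || p_stop_move < 0 || p_stop_move > 1)
    .lp_stop("transition probabilities must lie in [0, 1]", "lp_contract_error")
  if (speed_mean <= 0 || speed_sd < 0)
    .lp_stop("`speed_mean` must be positive, `speed_sd` non-negative",
             "lp_contract_error")
  if (turn_concentration < 0)
    .lp_stop("`turn_concentration` must be >= 0", "lp_contract_error")
  if (abs(stimulus_bias) > 1 || wall_affinity < 0 || wall_affinity > 1)
    .lp_stop("`stimulus_bias` in [-1,1], `wall_affinity` in [0,1]",
             "lp_contract_error")
  if (abs(stimulus_bias) + wall_affinity > 1)
    .lp_stop("|stimulus_bias| + wall_affinity must not exceed 1",
             "lp_contract_error")
  structure(list(p_start_move = p_start_move, p_stop_move = p_stop_move,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 turn_concentration = turn_concentration,
                 stimulus_bias = stimulus_bias, wall_affinity = wall_affinity),
            class = "phase_params")
}

#' Default phase parameterizations
#'
#' Movement statistics of real nymphs are not standardized across studies;
#' these defaults are stipulations chosen so the qualitative phase contrast
#' emerges robustly: gregarious animals are active (mostly moving, 3 cm/s)
#' and attracted to the stimulus wall, solitary animals are largely
#' inactive (brief rare bouts, 1.5 cm/s), repulsed by the stimulus and
#' wall-following.
#'
#' @param phase `"gregarious"` or `"solitary"`.
#' @return A [phase_params()] object.
#' @export
default_phase_params <- function(phase = c("gregarious", "solitary")) {
  switch(match.arg(phase),
    gregarious = phase_params(p_start_move = 0.5, p_stop_move = 0.1,
                              speed_mean = 3, stimulus_bias = 0.6,
                              wall_affinity = 0),
    solitary = phase_params(p_start_move = 0.05, p_stop_move = 0.5,
                            speed_mean = 1.5, stimulus_bias = -0.4,
                            wall_affinity = 0.5))
}

#' Cohort simulation settings
#'
#' @param gregarious,solitary [phase_params()] for the two phases.
#' @param duration Trial length in seconds (default 360, the standard 6-min
#'   recording).
#' @param dt Sampling interval in seconds (default 0.08 s, i.e. 12.5 Hz, a
#'   common tracking-export rate). `duration/dt` must be a whole number of
#'   samples.
#' @param seed Master seed; per-subject seeds are derived from it so cohorts
#'   are reproducible and independent of simulation order.
#' @param n_per_group Animals per phase.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(gregarious = default_phase_params("gregarious"),
                       solitary = default_phase_params("solitary"),
                       duration = 360, dt = 0.08, seed = 1,
                       n_per_group = 100) {
  if (abs(duration / dt - round(duration / dt)) > 1e-9)
    .lp_stop("`duration` must be a whole number of `dt` steps",
             "lp_contract_error")
  if (n_per_group < 0)
    .lp_stop("`n_per_group` must be >= 0", "lp_contract_error")
  structure(list(gregarious = gregarious, solitary = solitary,
                 duration = duration, dt = dt, seed = as.integer(seed),
                 n_per_group = as.integer(n_per_group)),
            class = "sim_config")
}

# unit vector toward (sign > 0) or away from the partition midpoint
.stim_dir <- function(x, y, px, py, sign) {
  dx <- px - x; dy <- py - y
  nrm <- sqrt(dx^2 + dy^2)
  if (nrm < 1e-9) return(c(0, 0))
  sign * c(dx, dy) / nrm
}

#' Simulate one arena trajectory
#'
#' @param pp [phase_params()] of the simulated phase.
#' @param g [arena_geometry()].
#' @param duration,dt Trial length and sampling interval, seconds.
#' @param seed Integer seed; the same seed always yields the same
#'   trajectory.
#' @param subject_id,phase Metadata attached to the result.
#' @return A [trajectory()] with `duration/dt` samples starting at t = 0.
#'   The start position is uniform in the central zone clear of the wall
#'   band; the animal starts paused.
#' @export
simulate_trajectory <- function(pp, g, duration = 360, dt = 0.08,
                                seed = NULL, subject_id = "sim",
                                phase = "unknown") {
  n <- round(duration / dt)
  if (abs(duration / dt - n) > 1e-9)
    .lp_stop("`duration` must be a whole number of `dt` steps",
             "lp_contract_error")
  if (n < 2L)
    .lp_stop("need at least 2 samples", "lp_contract_error")
  if (!is.null(seed)) set.seed(seed)
  L <- g$test_length; W <- g$width
  e <- .stim_edges(g)
  px <- e$partition_x; py <- W / 2
  f <- g$stimulus_zone_fraction
  x <- numeric(n); y <- numeric(n)
  x[1] <- stats::runif(1, f * L, (1 - f) * L)
  y[1] <- stats::runif(1, g$wall_band, W - g$wall_band)
  h <- stats::runif(1, -pi, pi)
  moving <- FALSE

  nstep <- n - 1L
  p_go <- 1 - (1 - pp$p_start_move)^dt
  p_halt <- 1 - (1 - pp$p_stop_move)^dt
  u_state <- stats::runif(nstep)
  # positive-truncated normal step lengths via inverse CDF
  mu_len <- pp$speed_mean * dt; sd_len <- pp$speed_sd * dt
  if (sd_len > 0) {
    plo <- stats::pnorm(0, mu_len, sd_len)
    len <- stats::qnorm(plo + stats::runif(nstep) * (1 - plo), mu_len, sd_len)
  } else len <- rep(mu_len, nstep)
  turn <- if (pp$turn_concentration > 0)
    stats::rnorm(nstep, 0, 1 / sqrt(pp$turn_concentration))
  else stats::runif(nstep, -pi, pi)

  wb <- abs(pp$stimulus_bias); wsgn <- sign(pp$stimulus_bias)
  wa <- pp$wall_affinity
  wp <- 1 - wb - wa  # persistence weight
  for (i in seq_len(nstep)) {
    if (moving) {
      if (u_state[i] < p_halt) moving <- FALSE
    } else if (u_state[i] < p_go) moving <- TRUE
    if (!moving) {
      x[i + 1] <- x[i]; y[i + 1] <- y[i]
      next
    }
    h <- h + turn[i]
    ux <- cos(h); uy <- sin(h)
    dx <- wp * ux; dy <- wp * uy
    if (wb > 0) {
      sv <- .stim_dir(x[i], y[i], px, py, wsgn)
      dx <- dx + wb * sv[1]; dy <- dy + wb * sv[2]
    }
    if (wa > 0) {
      # tangent of the nearest wall, signed to align with the heading
      dists <- c(x[i], L - x[i], y[i], W - y[i])
      wall <- which.min(dists)
      if (wall <= 2) { tx <- 0; ty <- if (uy >= 0) 1 else -1 }
      else { tx <- if (ux >= 0) 1 else -1; ty <- 0 }
      dx <- dx + wa * tx; dy <- dy + wa * ty
    }
    nrm <- sqrt(dx^2 + dy^2)
    if (nrm < 1e-9) { dx <- ux; dy <- uy } else { dx <- dx / nrm; dy <- dy / nrm }
    nx <- x[i] + len[i] * dx
    ny <- y[i] + len[i] * dy
    # specular reflection at the boundaries
    while (nx < 0 || nx > L) {
      if (nx < 0) { nx <- -nx; dx <- -dx } else { nx <- 2 * L - nx; dx <- -dx }
    }
    while (ny < 0 || ny > W) {
      if (ny < 0) { ny <- -ny; dy <- -dy } else { ny <- 2 * W - ny; dy <- -dy }
    }
    h <- atan2(dy, dx)
    x[i + 1] <- nx; y[i + 1] <- ny
  }
  trajectory(subject_id, (seq_len(n) - 1) * dt, x, y, g, phase = phase)
}

#' Simulate a two-phase cohort
#'
#' Simulates `n_per_group` gregarious and `n_per_group` solitary animals.
#' Per-subject seeds are drawn once from the master seed, so the cohort is
#' reproducible and each trajectory is independent of the order in which it
#' is generated.
#'
#' @param cfg A [sim_config()].
#' @param g An [arena_geometry()].
#' @return List of [trajectory()] objects with phase labels attached
#'   (gregarious first).
#' @export
simulate_cohort <- function(cfg, g) {
  n <- cfg$n_per_group
  if (n == 0L) return(list())
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  greg <- lapply(seq_len(n), function(i)
    simulate_trajectory(cfg$gregarious, g, cfg$duration, cfg$dt,
                        seed = seeds[i],
                        subject_id = sprintf("greg_%03d", i),
                        phase = "gregarious"))
  sol <- lapply(seq_len(n), function(i)
    simulate_trajectory(cfg$solitary, g, cfg$duration, cfg$dt,
                        seed = seeds[n + i],
                        subject_id = sprintf("sol_%03d", i),
                        phase = "solitary"))
  c(greg, sol)
}
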