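# Independent brute-force oracles, deliberately written as naive per-sample
# loops so they share no code path with the package internals.

# build a trajectory from coordinate vectors
make_traj <- function(x, y, dt = 0.08, g = arena_geometry(),
                      id = "t1", phase = "unknown") {
  trajectory(id, (seq_along(x) - 1) * dt, x, y, g, phase = phase)
}

# random walk confined to the arena interior
random_traj <- function(n, g = arena_geometry(), dt = 0.08, step_sd = 2,
                        phase = "unknown", id = "rw") {
  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1, 0, g$test_length); y[1] <- runif(1, 0, g$width)
  for (i in seq_len(n - 1)) {
    x[i + 1] <- min(max(x[i] + rnorm(1, 0, step_sd), 0), g$test_length)
    y[i + 1] <- min(max(y[i] + rnorm(1, 0, step_sd), 0), g$width)
  }
  make_traj(x, y, dt = dt, g = g, id = id, phase = phase)
}

# all eleven parameters by explicit per-sample loops (assumes stimulus at
# low x, the default)
brute_features <- function(traj, g, mp = movement_params()) {
  n <- length(traj$t); dt <- traj$dt; dur <- n * dt
  fL <- g$stimulus_zone_fraction * g$test_length
  inz <- function(i, zone) {
    x <- traj$x[i]; y <- traj$y[i]
    if (zone == "stimulus") return(x <= fL)
    if (zone == "opposite") return(x >= g$test_length - fL)
    min(x, g$test_length - x, y, g$width - y) <= g$wall_band
  }
  episode <- function(zone) {
    entries <- 0L; first <- NA_real_; inside_count <- 0L; prev <- FALSE
    for (i in seq_len(n)) {
      cur <- inz(i, zone)
      if (cur && !prev) entries <- entries + 1L
      if (cur && is.na(first)) first <- traj$t[i] - traj$t[1]
      if (cur) inside_count <- inside_count + 1L
      prev <- cur
    }
    if (entries == 0L) list(entries = 0L, lat = dur, dur = 0)
    else list(entries = entries, lat = first, dur = inside_count * dt)
  }
  tdm <- 0; dsum <- 0
  for (i in seq_len(n))
    dsum <- dsum + sqrt(traj$x[i]^2 + (traj$y[i] - g$width / 2)^2)
  for (i in seq_len(n - 1))
    tdm <- tdm + sqrt((traj$x[i + 1] - traj$x[i])^2 +
                      (traj$y[i + 1] - traj$y[i])^2)
  # explicit hysteresis state machine over intervals
  moving <- FALSE; bouts <- numeric(0); cur_len <- 0L
  for (i in seq_len(n - 1)) {
    sp <- sqrt((traj$x[i + 1] - traj$x[i])^2 +
               (traj$y[i + 1] - traj$y[i])^2) / dt
    was <- moving
    if (!moving && sp >= mp$start_speed) moving <- TRUE
    if (was && sp <= mp$stop_speed) moving <- FALSE
    if (moving) cur_len <- cur_len + 1L
    if (!moving && cur_len > 0L) { bouts <- c(bouts, cur_len * dt); cur_len <- 0L }
  }
  if (cur_len > 0L) bouts <- c(bouts, cur_len * dt)
  bouts <- bouts[bouts >= mp$min_bout - 1e-12]
  st <- episode("stimulus"); op <- episode("opposite"); wl <- episode("wall")
  c(EFISA = st$entries, LFOISA = st$lat, TDCW = wl$dur, EFCW = wl$entries,
    EFIOSA = op$entries, LFOIOSA = op$lat, MDTSG = dsum / n, TDM = tdm,
    TDMV = sum(bouts), FOM = length(bouts), AI = st$dur - op$dur)
}

# exact two-sided Mann-Whitney p by enumerating every assignment of ranks
enum_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  u_obs <- min(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2,
               n1 * n2 - (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2))
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, (sum(u_all <= u_obs) + sum(u_all >= n1 * n2 - u_obs)) / ncol(combos))
}

# 1-covariate logistic ML by direct optimization of the log-likelihood,
# independent of the IRLS path
oracle_logit1 <- function(x, y) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))))
  }
  fit <- optim(c(0, 0), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 20000))
  fit$par
}
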