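# The eleven behavioral parameters of the arena assay, computed from one
# trajectory:
#   EFISA / LFOISA   entries into, latency of first occurrence in, the
#                    stimulus strip (count, s)
#   TDCW / EFCW      duration in, entries into, the wall band (s, count)
#   EFIOSA / LFOIOSA entries / latency for the opposite strip (count, s)
#   MDTSG            mean distance to the stimulus group (cm)
#   TDM              total distance moved (cm)
#   TDMV / FOM       total duration (s) and count of movement bouts
#   AI               attraction index = stimulus minus opposite occupancy (s)

#' Fixed column order of the eleven behavioral parameters
#' @export
FEATURE_NAMES <- c("EFISA", "LFOISA", "TDCW", "EFCW", "EFIOSA", "LFOIOSA",
                   "MDTSG", "TDM", "TDMV", "FOM", "AI")

#' Movement-bout detector settings
#'
#' The bout detector is a hysteresis state machine on per-interval speeds: a
#' bout starts when speed rises to `start_speed` or above and ends when it
#' falls to `stop_speed` or below; speeds in between leave the state
#' unchanged, which suppresses jitter-driven flickering. Bouts shorter than
#' `min_bout` are discarded.
#'
#' @param start_speed Speed at or above which a bout starts, cm/s.
#' @param stop_speed Speed at or below which a bout ends, cm/s; must not
#'   exceed `start_speed`.
#' @param min_bout Minimum bout duration kept, in seconds.
#' @param min_step Per-step displacement floor (cm) applied to the total
#'   distance moved; 0 disables filtering (default).
#' @return An object of class `"movement_params"`.
#' @export
movement_params <- function(start_speed = 1.0, stop_speed = 0.5,
                            min_bout = 0.5, min_step = 0) {
  if (stop_speed > start_speed)
    .lp_stop("`stop_speed` must not exceed `start_speed`", "lp_contract_error")
  if (min_bout < 0 || min_step < 0)
    .lp_stop("`min_bout` and `min_step` must be non-negative", "lp_contract_error")
  structure(list(start_speed = start_speed, stop_speed = stop_speed,
                 min_bout = min_bout, min_step = min_step),
            class = "movement_params")
}

#' Per-interval speeds of a trajectory
#'
#' @param traj A [trajectory()].
#' @return Numeric vector of length `n_samples - 1`: Euclidean displacement
#'   of each sampling interval divided by dt, in cm/s.
#' @export
speeds <- function(traj) {
  sqrt(diff(traj$x)^2 + diff(traj$y)^2) / traj$dt
}

# Hysteresis state over intervals, vectorized: +1 where speed crosses the
# start threshold, 0 where it crosses the stop threshold, carry-forward in
# the dead band (initial state: paused).
.bout_state <- function(sp, mp) {
  sig <- rep(NA_integer_, length(sp))
  sig[sp >= mp$start_speed] <- 1L
  sig[sp <= mp$stop_speed] <- 0L
  filled <- c(0L, sig[!is.na(sig)])
  filled[cumsum(!is.na(sig)) + 1L]
}

#' Detect movement bouts
#'
#' @param traj A [trajectory()].
#' @param mp [movement_params()].
#' @return Data frame with columns `start_t`, `end_t`, `duration` (s), one
#'   row per retained bout in time order.
#' @export
detect_bouts <- function(traj, mp = movement_params()) {
  sp <- speeds(traj)
  state <- .bout_state(sp, mp)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  # interval i spans [t[i], t[i+1]]
  out <- data.frame(start_t = traj$t[starts[keep]],
                    end_t = traj$t[ends[keep] + 1L])
  out$duration <- out$end_t - out$start_t
  out[out$duration >= mp$min_bout | abs(out$duration - mp$min_bout) < 1e-12, ,
      drop = FALSE]
}

#' Zone occupancy episodes
#'
#' An entry is an outside-to-inside transition between consecutive samples;
#' a trajectory that starts inside the zone counts one entry with latency 0.
#' Occupancy is attributed per sample: each sample whose point lies in the
#' (closed) zone contributes dt. A never-entered zone is censored at the
#' trial duration: `(entries = 0, first_latency = duration, total_duration = 0)`.
#'
#' @param traj A [trajectory()].
#' @param g An [arena_geometry()].
#' @param zone One of `"stimulus"`, `"opposite"`, `"wall"`.
#' @return Named list `entries` (count), `first_latency` (s),
#'   `total_duration` (s).
#' @export
zone_episodes <- function(traj, g, zone) {
  if (!zone %in% c("stimulus", "opposite", "wall"))
    .lp_stop("`zone` must be one of 'stimulus', 'opposite', 'wall'",
             "lp_contract_error")
  inside <- .in_zone(traj$x, traj$y, g, zone)
  n <- length(inside)
  entries <- sum(inside & !c(FALSE, inside[-n]))
  if (!any(inside))
    return(list(entries = 0L, first_latency = traj$duration,
                total_duration = 0))
  list(entries = as.integer(entries),
       first_latency = traj$t[which(inside)[1]] - traj$t[1],
       total_duration = traj$dt * sum(inside))
}

#' Extract the eleven behavioral parameters from one trajectory
#'
#' @param traj A [trajectory()].
#' @param g An [arena_geometry()].
#' @param mp [movement_params()].
#' @return A one-row data frame of class `"behavioral_features"` with
#'   columns `subject_id`, `phase`, then the eleven parameters in the fixed
#'   order given by [FEATURE_NAMES].
#' @export
extract_features <- function(traj, g, mp = movement_params()) {
  disp <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  if (mp$min_step > 0) disp <- disp[disp >= mp$min_step]
  bouts <- detect_bouts(traj, mp)
  stim <- zone_episodes(traj, g, "stimulus")
  opp <- zone_episodes(traj, g, "opposite")
  wall <- zone_episodes(traj, g, "wall")
  out <- data.frame(
    subject_id = traj$subject_id, phase = traj$phase,
    EFISA = stim$entries, LFOISA = stim$first_latency,
    TDCW = wall$total_duration, EFCW = wall$entries,
    EFIOSA = opp$entries, LFOIOSA = opp$first_latency,
    MDTSG = mean(distance_to_stimulus(traj$x, traj$y, g)),
    TDM = sum(disp),
    TDMV = sum(bouts$duration), FOM = nrow(bouts),
    AI = stim$total_duration - opp$total_duration,
    stringsAsFactors = FALSE)
  class(out) <- c("behavioral_features", "data.frame")
  out
}

#' Extract features for a whole cohort
#'
#' @param trajs List of [trajectory()] objects.
#' @param g An [arena_geometry()].
#' @param mp [movement_params()].
#' @return Data frame with one row per trajectory, columns as in
#'   [extract_features()].
#' @export
extract_features_cohort <- function(trajs, g, mp = movement_params()) {
  if (!length(trajs))
    .lp_stop("empty cohort: no trajectories to extract features from",
             "lp_contract_error")
  out <- do.call(rbind, lapply(trajs, extract_features, g = g, mp = mp))
  rownames(out) <- NULL
  out
}

#' Write a feature table to CSV
#'
#' Columns are written in the fixed contract order (`subject_id`, `phase`,
#' then [FEATURE_NAMES]) so the file is a stable input for model fitting.
#'
#' @param features Data frame from [extract_features_cohort()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features[, c("subject_id", "phase", FEATURE_NAMES)],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#' @param path CSV path.
#' @return Data frame with the contract columns.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("subject_id", FEATURE_NAMES), names(df))
  if (length(missing_cols))
    .lp_stop(paste("feature file missing columns:",
                   paste(missing_cols, collapse = ", ")), "lp_format_error")
  df
}
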