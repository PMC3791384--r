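# Trajectories: uniformly sampled (t, x, y) paths of one nymph, plus the
# tracking-export CSV dialect used to exchange them.
#
# Duration convention: each sample owns one dt slab, so duration = n * dt.
# This keeps zone occupancy (dt per in-zone sample) bounded by the trial
# duration and makes a 4500-sample recording at 12.5 Hz a 360 s trial.

.DT_TOL <- 1e-6
.PHASES <- c("gregarious", "solitary", "treated", "unknown")

#' Construct a trajectory
#'
#' @param subject_id Subject identifier (single string).
#' @param t Strictly increasing, uniformly spaced sample times in seconds.
#' @param x,y Positions in cm, validated against the arena.
#' @param g An [arena_geometry()] the positions must lie inside.
#' @param phase Phase label, one of `"gregarious"`, `"solitary"`,
#'   `"treated"`, `"unknown"`.
#' @return An object of class `"trajectory"` with fields `subject_id`,
#'   `phase`, `t`, `x`, `y`, `dt` and `duration` (= n samples * dt).
#' @export
trajectory <- function(subject_id, t, x, y, g, phase = "unknown") {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  phase <- match.arg(phase, .PHASES)
  n <- length(t)
  if (n < 2L || length(x) != n || length(y) != n)
    .lp_stop(sprintf("subject '%s': need >= 2 samples with matching t/x/y lengths",
                     subject_id), "lp_format_error")
  dts <- diff(t)
  if (any(dts <= 0))
    .lp_stop(sprintf("subject '%s': timestamps not strictly increasing", subject_id),
             "lp_format_error")
  dt <- dts[1]
  if (any(abs(dts - dt) > .DT_TOL)) {
    i <- which(abs(dts - dt) > .DT_TOL)[1]
    .lp_stop(sprintf("subject '%s': non-uniform sampling interval at sample %d (dt %g vs %g s)",
                     subject_id, i + 1L, dts[i], dt), "lp_format_error")
  }
  .check_inside(x, y, g, what = sprintf("subject '%s': position", subject_id))
  structure(
    list(subject_id = subject_id, phase = phase, t = as.numeric(t),
         x = as.numeric(x), y = as.numeric(y), dt = dt, duration = n * dt),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory '%s' (%s): %d samples, dt = %g s, %.2f s\n",
              x$subject_id, x$phase, length(x$t), x$dt, x$duration))
  invisible(x)
}

#' Read trajectories from a tracking-export CSV file
#'
#' Expects a comma-separated UTF-8 file with header columns `subject_id`,
#' `time_s`, `x_cm`, `y_cm` and optionally `phase`. Rows are grouped by
#' subject and sorted by time; each subject must be uniformly sampled and
#' every position must lie inside the arena. Files with tracking dropouts
#' (non-uniform dt) are rejected rather than imputed.
#'
#' @param path CSV file path.
#' @param g An [arena_geometry()].
#' @return List of [trajectory()] objects, one per subject, in order of
#'   first appearance.
#' @export
read_trajectories <- function(path, g) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_s", "x_cm", "y_cm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    .lp_stop(paste("missing required columns:", paste(missing_cols, collapse = ", ")),
             "lp_format_error")
  if (!"phase" %in% names(df)) df$phase <- "unknown"
  ids <- unique(df$subject_id)
  lapply(ids, function(id) {
    rows <- df[df$subject_id == id, , drop = FALSE]
    rows <- rows[order(rows$time_s), , drop = FALSE]
    if (anyDuplicated(rows$time_s))
      .lp_stop(sprintf("subject '%s': duplicate timestamp %g s", id,
                       rows$time_s[duplicated(rows$time_s)][1]), "lp_format_error")
    phase <- rows$phase[1]
    if (!phase %in% .PHASES) phase <- "unknown"
    trajectory(as.character(id), rows$time_s, rows$x_cm, rows$y_cm, g,
               phase = phase)
  })
}

#' Write trajectories to the tracking-export CSV dialect
#'
#' Positions are written with enough digits that a read/write round trip
#' reproduces them to better than 1e-9 cm.
#'
#' @param trajs List of [trajectory()] objects (may be empty: a header-only
#'   file is written).
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_trajectories <- function(trajs, path) {
  header <- "subject_id,phase,time_s,x_cm,y_cm"
  # %.17g round-trips doubles exactly, so derived features are bit-identical
  fmt <- function(v) sprintf("%.17g", v)
  lines <- unlist(lapply(trajs, function(tr) {
    paste(tr$subject_id, tr$phase, fmt(tr$t), fmt(tr$x), fmt(tr$y), sep = ",")
  }))
  con <- tryCatch(file(path, "w"), error = function(e)
    .lp_stop(sprintf("cannot open '%s' for writing", path), "lp_io_error"))
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}
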