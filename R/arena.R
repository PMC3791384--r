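# Arena geometry: the open test area of the place-preference arena, with the
# stimulus chamber behind a partition at one end. Coordinates are continuous
# cm; x runs along the stimulus axis with 0 at the stimulus-side partition,
# y across the arena. Zones are closed sets.

.lp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "locustphase_error", "error")))
}

#' Arena and zone geometry for the behavioral assay
#'
#' Describes the open test area accessible to the focal nymph, together with
#' the zone layout used by feature extraction: a stimulus strip (the fraction
#' of the test area closest to the partition behind which the stimulus group
#' sits), an equally sized opposite strip at the far end, and a thigmotaxis
#' band along the walls.
#'
#' The defaults describe a 40 x 30 cm rectangular arena whose two 7.5 cm deep
#' end chambers are walled off, leaving a 25 x 30 cm test area; the stimulus
#' and opposite zones are each 25% of that test area.
#'
#' @param test_length Extent of the open test area along the stimulus axis,
#'   in cm. Must be positive.
#' @param width Arena width across the stimulus axis, in cm. Must be positive.
#' @param stimulus_zone_fraction Fraction of `test_length` making up each of
#'   the stimulus and opposite strips; in (0, 0.5].
#' @param wall_band Width of the wall-following band, in cm; must be less
#'   than half the smaller arena dimension. The tracker literature gives no
#'   standard value; the default of 2 cm is about one fourth-stadium nymph
#'   body length.
#' @param stimulus_side Which end of the x axis holds the stimulus chamber.
#'   `"low_x"` (default) puts the stimulus partition at x = 0.
#' @return An object of class `"arena_geometry"`.
#' @examples
#' g <- arena_geometry()
#' zones_of(c(0, 15), g)      # on the partition: stimulus strip + wall band
#' distance_to_stimulus(20, 15, g)
#' @export
arena_geometry <- function(test_length = 25, width = 30,
                           stimulus_zone_fraction = 0.25,
                           wall_band = 2,
                           stimulus_side = c("low_x", "high_x")) {
  stimulus_side <- match.arg(stimulus_side)
  if (!is.numeric(test_length) || length(test_length) != 1L || test_length <= 0)
    .lp_stop("`test_length` must be a positive number (cm)", "lp_domain_error")
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    .lp_stop("`width` must be a positive number (cm)", "lp_domain_error")
  if (!is.numeric(stimulus_zone_fraction) || length(stimulus_zone_fraction) != 1L ||
      stimulus_zone_fraction <= 0 || stimulus_zone_fraction > 0.5)
    .lp_stop("`stimulus_zone_fraction` must lie in (0, 0.5]", "lp_domain_error")
  if (!is.numeric(wall_band) || length(wall_band) != 1L || wall_band < 0 ||
      wall_band >= min(test_length, width) / 2)
    .lp_stop("`wall_band` must be non-negative and less than half the smaller arena dimension",
             "lp_domain_error")
  structure(
    list(test_length = test_length, width = width,
         stimulus_zone_fraction = stimulus_zone_fraction,
         wall_band = wall_band, stimulus_side = stimulus_side),
    class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat("Arena geometry (open test area)\n")
  cat(sprintf("  test area: %.4g x %.4g cm, stimulus side: %s\n",
              x$test_length, x$width, x$stimulus_side))
  cat(sprintf("  stimulus/opposite strips: %.4g%% of test length (%.4g cm each)\n",
              100 * x$stimulus_zone_fraction,
              x$stimulus_zone_fraction * x$test_length))
  cat(sprintf("  wall band: %.4g cm\n", x$wall_band))
  invisible(x)
}

# x coordinate of the stimulus partition and the inner edge of each strip
.stim_edges <- function(g) {
  d <- g$stimulus_zone_fraction * g$test_length
  if (g$stimulus_side == "low_x") {
    list(stim_lo = 0, stim_hi = d, opp_lo = g$test_length - d,
         opp_hi = g$test_length, partition_x = 0)
  } else {
    list(stim_lo = g$test_length - d, stim_hi = g$test_length,
         opp_lo = 0, opp_hi = d, partition_x = g$test_length)
  }
}

.check_inside <- function(x, y, g, what = "point") {
  bad <- !is.finite(x) | !is.finite(y) | x < 0 | x > g$test_length |
    y < 0 | y > g$width
  if (any(bad))
    .lp_stop(sprintf("%s outside arena: first offending (x, y) = (%g, %g)",
                     what, x[which(bad)[1]], y[which(bad)[1]]),
             "lp_domain_error")
  invisible(TRUE)
}

# Vectorized closed-zone membership; internal workhorse for features.
.in_zone <- function(x, y, g, zone) {
  e <- .stim_edges(g)
  switch(zone,
    stimulus = x >= e$stim_lo & x <= e$stim_hi,
    opposite = x >= e$opp_lo & x <= e$opp_hi,
    wall = pmin(x, g$test_length - x, y, g$width - y) <= g$wall_band,
    center = !(x >= e$stim_lo & x <= e$stim_hi) &
             !(x >= e$opp_lo & x <= e$opp_hi),
    .lp_stop(sprintf("unknown zone '%s'", zone), "lp_contract_error"))
}

#' Zone membership of a point
#'
#' Zones are closed: a point exactly on a zone boundary belongs to the zone.
#' The stimulus, opposite and center labels partition the arena; the wall
#' label can co-occur with any of them.
#'
#' @param p Numeric length-2 vector `c(x, y)` in cm.
#' @param g An [arena_geometry()].
#' @return Character vector of zone labels, a subset of
#'   `c("stimulus", "opposite", "center", "wall")`.
#' @export
zones_of <- function(p, g) {
  stopifnot(is.numeric(p), length(p) == 2L)
  .check_inside(p[1], p[2], g)
  labs <- c("stimulus", "opposite", "center", "wall")
  labs[vapply(labs, function(z) .in_zone(p[1], p[2], g, z), logical(1))]
}

#' Distance to the stimulus group
#'
#' Euclidean distance from a point to the midpoint of the partition wall
#' separating the test area from the stimulus chamber. The stimulus animals
#' move freely inside their chamber, so the partition midpoint is used as a
#' fixed, reproducible proxy for their location.
#'
#' @param x,y Point coordinates in cm (vectorized).
#' @param g An [arena_geometry()].
#' @return Distances in cm, same length as `x`.
#' @export
distance_to_stimulus <- function(x, y, g) {
  .check_inside(x, y, g)
  e <- .stim_edges(g)
  sqrt((x - e$partition_x)^2 + (y - g$width / 2)^2)
}
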