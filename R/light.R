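#' Light schedules
#'
#' A light schedule is a piecewise-constant description of the light source
#' over time: an ordered set of segments, each starting at a step index and
#' holding either a direction at infinity (an angle, in radians, measured from
#' the +x axis) or a finite point source (a position in the plane). Cells
#' aiming at an at-infinity source all head along the same angle; cells aiming
#' at a point source head along the bearing from their own position to it.
#'
#' `light_schedule()` builds a schedule from parallel vectors; the default is a
#' single constant source at infinity to the right of the colony (angle 0).
#' `light_switch_schedule()` is a convenience for the rotation protocol in
#' which the source is displaced 90 degrees clockwise at `t_switch`.
#'
#' @param angle Angles (radians) for at-infinity segments, or `NA` where the
#'   segment is a point source.
#' @param t_start Start step of each segment; strictly increasing, first 0.
#' @param point Optional 2-column matrix (or length-2 vector for a single
#'   segment) of point-source positions; rows with `NA` use `angle`.
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule(angle = 0)                          # constant light to the right
#' light_switch_schedule(t_switch = 2e5)              # 90 deg clockwise at 2e5
#' @export
light_schedule <- function(angle = 0, t_start = 0, point = NULL) {
  n <- max(length(angle), if (is.null(point)) 0L else nrow(rbind(point)))
  if (n == 0) abort("a light schedule needs at least one segment")
  n <- max(n, length(t_start))
  angle <- rep_len(as.numeric(angle), n)
  t_start <- rep_len(as.numeric(t_start), n)
  if (is.null(point)) {
    px <- rep(NA_real_, n); py <- rep(NA_real_, n)
  } else {
    point <- rbind(point)
    if (ncol(point) != 2) abort("`point` must have two columns (x, y)")
    if (nrow(point) != n) point <- point[rep_len(seq_len(nrow(point)), n), , drop = FALSE]
    px <- as.numeric(point[, 1]); py <- as.numeric(point[, 2])
  }
  mode <- ifelse(is.na(px) | is.na(py), 0L, 1L)
  if (any(mode == 0L & is.na(angle)))
    abort("each segment needs either an `angle` or a `point`")
  if (t_start[1] != 0)
    abort("the first light segment must start at t = 0")
  if (n > 1 && any(diff(t_start) <= 0))
    abort("light segment `t_start` values must be strictly increasing")
  structure(
    tibble(t_start = t_start, mode = mode,
           angle = ifelse(mode == 0L, angle %% (2 * pi), NA_real_),
           px = px, py = py),
    class = c("light_schedule", class(tibble())))
}

#' @rdname light_schedule
#' @param t_switch Step at which the source is rotated.
#' @param angle_before Initial at-infinity direction (default 0, light to the
#'   right).
#' @param angle_after Direction after the switch; default `angle_before - pi/2`
#'   (a 90 degree clockwise rotation of the source).
#' @export
light_switch_schedule <- function(t_switch, angle_before = 0,
                                  angle_after = angle_before - pi / 2) {
  if (t_switch <= 0) abort("`t_switch` must be positive")
  light_schedule(angle = c(angle_before, angle_after), t_start = c(0, t_switch))
}

# list-of-vectors form handed to the compiled code
as_light_list <- function(schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (nrow(schedule) == 0) abort("empty light schedule")
  list(t_start = schedule$t_start, mode = as.integer(schedule$mode),
       angle = ifelse(is.na(schedule$angle), 0, schedule$angle),
       px = ifelse(is.na(schedule$px), 0, schedule$px),
       py = ifelse(is.na(schedule$py), 0, schedule$py))
}

#' Direction toward the light
#'
#' The heading a cell at position `(x, y)` would take when aiming at the light
#' at step `t`: the segment angle for an at-infinity source (independent of
#' position), or the bearing from the cell to the source point. Angles are
#' wrapped into `[0, 2*pi)`.
#'
#' @param schedule A [light_schedule()].
#' @param t Step index (scalar).
#' @param x,y Cell coordinates (vectorized).
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @examples
#' light_direction(light_schedule(angle = 0), t = 10, x = 5, y = 3)
#' @export
light_direction <- function(schedule, t, x = 0, y = 0) {
  if (!inherits(schedule, "light_schedule") || nrow(schedule) == 0)
    abort("`schedule` must be a non-empty light_schedule")
  if (t < 0) abort("`t` must be non-negative")
  m <- cbind(as.numeric(x), as.numeric(y))
  cpp_light_direction(m, as_light_list(schedule), t)
}
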