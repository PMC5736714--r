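#' Colony geometry
#'
#' The initial colony occupies a circle or a rectangle whose area is fixed by
#' the mean density: `n_cells / rho`. A circle gets radius
#' `sqrt(n_cells / (pi * rho))`; a rectangle is tall in `y` and thin in `x`
#' (aspect = height/width, default 10), modelling a flat colony front out of
#' which cells move perpendicular to the surface when lit from the right.
#'
#' @param shape `"circle"` or `"rectangle"`.
#' @param n_cells Number of cells.
#' @param rho Mean density (cells per unit area); must be positive.
#' @param anchor Centre of the colony in the plane.
#' @param aspect Height:width ratio for rectangles.
#' @return An object of class `colony_geometry` with the derived extent.
#' @examples
#' colony_geometry("circle", 500, 0.05)$radius   # ~56.42
#' @export
colony_geometry <- function(shape = c("circle", "rectangle"), n_cells = 500,
                            rho = 0.05, anchor = c(0, 0), aspect = 10) {
  shape <- match.arg(shape)
  if (rho <= 0) abort("`rho` must be positive")
  if (n_cells < 1) abort("`n_cells` must be at least 1")
  area <- n_cells / rho
  g <- list(shape = shape, anchor = as.numeric(anchor), area = area)
  if (shape == "circle") {
    g$radius <- sqrt(area / pi)
  } else {
    g$height <- sqrt(area * aspect)
    g$width <- area / g$height
    g$aspect <- aspect
  }
  structure(g, class = "colony_geometry")
}

#' @export
print.colony_geometry <- function(x, ...) {
  if (x$shape == "circle")
    cat(sprintf("<colony_geometry> circle, radius %.2f at (%g, %g)\n",
                x$radius, x$anchor[1], x$anchor[2]))
  else
    cat(sprintf("<colony_geometry> rectangle %.2f x %.2f at (%g, %g)\n",
                x$width, x$height, x$anchor[1], x$anchor[2]))
  invisible(x)
}

# is each (x, y) inside the colony domain?
in_domain <- function(geometry, x, y) {
  dx <- x - geometry$anchor[1]
  dy <- y - geometry$anchor[2]
  if (geometry$shape == "circle") dx^2 + dy^2 <= geometry$radius^2
  else abs(dx) <= geometry$width / 2 & abs(dy) <= geometry$height / 2
}

# signed distance beyond the colony boundary (positive outside)
dist_outside <- function(geometry, x, y) {
  dx <- x - geometry$anchor[1]
  dy <- y - geometry$anchor[2]
  if (geometry$shape == "circle") sqrt(dx^2 + dy^2) - geometry$radius
  else pmax(abs(dx) - geometry$width / 2, abs(dy) - geometry$height / 2)
}

#' Construct the initial colony
#'
#' Draws `n_cells` positions uniformly over the domain (overlaps are allowed;
#' the soft-core repulsion resolves them dynamically), flags
#' `round(phi_ch * n_cells)` uniformly chosen cells as freeloaders, draws
#' initial headings exactly as a heading update at `t = 0`, and sets every
#' lattice site whose centre lies inside the domain to `S0` (sites outside
#' stay untouched and read as 0). RNG draw order: positions in cell order,
#' then the freeloader choice, then headings.
#'
#' @param config A [sim_config()].
#' @param geometry A [colony_geometry()].
#' @param schedule A [light_schedule()] (initial headings may aim at it).
#' @return List with elements `state` ([cell_state()]) and `slime`
#'   ([slime_field()]).
#' @export
make_colony <- function(config, geometry, schedule = light_schedule(angle = 0)) {
  n <- config$n_cells
  ax <- geometry$anchor[1]; ay <- geometry$anchor[2]
  if (geometry$shape == "circle") {
    rad <- geometry$radius * sqrt(runif(n))
    phi <- 2 * pi * runif(n)
    pos <- cbind(ax + rad * cos(phi), ay + rad * sin(phi))
  } else {
    pos <- cbind(ax + (runif(n) - 0.5) * geometry$width,
                 ay + (runif(n) - 0.5) * geometry$height)
  }
  n_free <- round(config$phi_ch * n)
  freeloader <- logical(n)
  if (n_free > 0) freeloader[sample.int(n, n_free)] <- TRUE

  state <- cell_state(pos, numeric(n), freeloader)
  state$headings <- update_headings(state, schedule, t = 0, config$p_photo)

  sp <- config$spacing
  if (geometry$shape == "circle") {
    rr <- c(ceiling((ay - geometry$radius) / sp), floor((ay + geometry$radius) / sp))
    cc <- c(ceiling((ax - geometry$radius) / sp), floor((ax + geometry$radius) / sp))
  } else {
    rr <- c(ceiling((ay - geometry$height / 2) / sp), floor((ay + geometry$height / 2) / sp))
    cc <- c(ceiling((ax - geometry$width / 2) / sp), floor((ax + geometry$width / 2) / sp))
  }
  rs <- rr[1]:rr[2]; cs <- cc[1]:cc[2]
  xg <- matrix(cs * sp, nrow = length(rs), ncol = length(cs), byrow = TRUE)
  yg <- matrix(rs * sp, nrow = length(rs), ncol = length(cs))
  vals <- matrix(0, length(rs), length(cs))
  vals[in_domain(geometry, xg, yg)] <- config$S0
  slime <- slime_field(vals, r_min = rr[1], c_min = cc[1], spacing = sp,
                       S_max = config$S_max)
  list(state = state, slime = slime)
}
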