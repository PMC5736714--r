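#' Scenario presets
#'
#' Ready-made experiment fixtures bundling a configuration, a colony
#' geometry, a light schedule, and (where relevant) a pre-laid slime band:
#'
#' * `"circle"` — a circular colony (500 cells, density 0.05) lit from the
#'   right; fingers nucleate at the bright edge and extrude toward the light.
#' * `"flat"` — a flat (tall, thin rectangular) colony lit from the right;
#'   cells leave the front perpendicular to the surface. The basis for the
#'   rose-plot/kymograph analyses and the `p_photo` sweep.
#' * `"slime_band"` — the flat scenario with a saturated slime band laid
#'   normal to the direction of finger growth, some distance ahead of the
#'   front, for the band-crossing speed-up experiment.
#' * `"freeloaders"` — the flat scenario with half the cells blind to the
#'   light (`phi_ch = 0.5`), for the entrainment experiment.
#' * `"light_switch"` — a denser circular colony (`rho = 0.2`) whose light
#'   source is rotated 90 degrees clockwise at `t_switch`, for the
#'   finger-reorientation experiment.
#'
#' Any [sim_config()] field can be overridden through `...`; `t_switch`,
#' `band`, `anchor` and `aspect` tune the scenario itself.
#'
#' @param name Preset name.
#' @param ... Overrides for [sim_config()] fields (e.g. `p_photo = 0.01`,
#'   `n_steps = 2e4`).
#' @param t_switch Switch step for `"light_switch"` (default 2e5).
#' @param band `c(xmin, xmax, level)` for `"slime_band"`.
#' @param anchor Colony centre.
#' @param aspect Rectangle aspect for flat scenarios.
#' @return An object of class `phototax_scenario`: a list with `name`,
#'   `config`, `geometry`, `schedule`, `band`.
#' @examples
#' sc <- phototax_preset("circle", n_steps = 1000)
#' sc$geometry$radius
#' @export
phototax_preset <- function(name = c("circle", "flat", "slime_band",
                                     "freeloaders", "light_switch"),
                            ..., t_switch = 2e5, band = NULL,
                            anchor = c(0, 0), aspect = 10) {
  name <- match.arg(name)
  over <- list(...)
  base <- switch(name,
    circle       = list(n_steps = 16000L),
    flat         = list(n_steps = 100000L),
    slime_band   = list(n_cells = 300L, n_steps = 30000L),
    freeloaders  = list(phi_ch = 0.5, n_steps = 100000L),
    light_switch = list(rho = 0.2, n_steps = 250000L))
  cfg_args <- modifyList(base, over)
  unknown <- setdiff(names(cfg_args), names(formals(sim_config)))
  if (length(unknown))
    abort(paste0("unknown configuration field(s): ",
                 paste(unknown, collapse = ", ")))
  config <- do.call(sim_config, cfg_args)

  shape <- if (name %in% c("circle", "light_switch")) "circle" else "rectangle"
  geometry <- colony_geometry(shape, n_cells = config$n_cells,
                              rho = config$rho, anchor = anchor,
                              aspect = aspect)
  schedule <- if (name == "light_switch")
    light_switch_schedule(t_switch) else light_schedule(angle = 0)

  if (name == "slime_band" && is.null(band)) {
    # strip ahead of the colony front: front sits at x = width/2, the band
    # starts ~3 pilus reaches further out so fingers form before reaching it
    x0 <- anchor[1] + geometry$width / 2 + 18
    band <- c(x0, x0 + 10, config$S_max)
  }
  structure(list(name = name, config = config, geometry = geometry,
                 schedule = schedule, band = band),
            class = "phototax_scenario")
}

#' @export
print.phototax_scenario <- function(x, ...) {
  cat(sprintf("<phototax_scenario> \"%s\"\n", x$name))
  print(x$config)
  print(x$geometry)
  if (!is.null(x$band))
    cat(sprintf("  slime band: x in [%g, %g] at level %g\n",
                x$band[1], x$band[2], x$band[3]))
  invisible(x)
}
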