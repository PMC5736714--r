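#' Simulation configuration
#'
#' Collects every model parameter into a validated configuration object.
#' Defaults are the standard parameter set used throughout: cells of radius
#' `R` carrying `a` pili that reach a distance `A` beyond the cell edge,
#' sigmoidal tug-force parameters `(k1, k2)`, an initial in-colony slime level
#' `S0` capped at `S_max`, per-cell slime deposition `S_rate` per step, a
#' per-step probability `p_photo` of heading straight at the light, a
#' freeloader fraction `phi_ch`, and a mean colony density `rho` (cells per
#' unit area). Lengths are in units of the cell radius; one time step is one
#' simulation unit.
#'
#' `dt` (time step) and `f_bias` (magnitude of the heading bias force) are
#' fixed model constants equal to 1 and are carried read-only in the object.
#'
#' @param R Cell radius (length unit of the model). Default 1.
#' @param A Pilus reach beyond the cell edge. Default `4 * R`.
#' @param a Number of pili per cell (tug budget per donor per step). Default 4.
#' @param gamma0 Friction at slime level `S0`; its inverse is the maximal cell
#'   speed, so the default `1/(0.1 * R)` gives a top step of `R/10`.
#' @param k1,k2 Amplitude and steepness of the sigmoidal pair-force law.
#'   Defaults 1 and 2.
#' @param S0 Initial slime on every lattice site inside the colony. Default 1000.
#' @param S_max Slime cap per lattice site. Default 1000.
#' @param S_rate Slime deposited by one cell in one step. Default 0.1.
#' @param p_photo Per-step probability that a sighted cell heads at the light.
#' @param phi_ch Fraction of cells that are freeloaders (motile, slime-laying,
#'   tugging, but blind to the light).
#' @param rho Mean colony density, cells per unit area. Default 0.05.
#' @param n_cells Number of cells. Default 500.
#' @param S_floor Minimum effective slime used in the friction law, clamping
#'   the divergence on virgin (slime-free) substrate. Default 1, i.e. at most
#'   a 1000-fold slow-down relative to `S0` ground.
#' @param seed RNG seed for the run.
#' @param n_steps Default run length in steps.
#' @param spacing Slime lattice constant. Default `R`.
#' @param step_cap Hard cap on the per-step displacement. Default `R/10`.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(p_photo = 0.5, n_cells = 100)
#' cfg$p_photo
#' @export
sim_config <- function(R = 1, A = 4 * R, a = 4L, gamma0 = 1 / (0.1 * R),
                       k1 = 1, k2 = 2, S0 = 1000, S_max = 1000, S_rate = 0.1,
                       p_photo = 0.1, phi_ch = 0, rho = 0.05, n_cells = 500L,
                       S_floor = 1, seed = 1L, n_steps = 10000L,
                       spacing = R, step_cap = R / 10) {
  cfg <- list(
    R = R, A = A, a = as.integer(a), gamma0 = gamma0, k1 = k1, k2 = k2,
    S0 = S0, S_max = S_max, S_rate = S_rate, p_photo = p_photo,
    phi_ch = phi_ch, rho = rho, n_cells = as.integer(n_cells),
    dt = 1, f_bias = 1, S_floor = S_floor, step_cap = step_cap,
    spacing = spacing, seed = as.integer(seed), n_steps = as.integer(n_steps)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  problems <- character()
  need_num <- function(field, min = NULL, max = NULL, strict_min = FALSE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      problems <<- c(problems, sprintf("`%s` must be a single finite number", field))
      return(invisible())
    }
    if (!is.null(min) && (if (strict_min) v <= min else v < min))
      problems <<- c(problems, sprintf(
        "`%s` must be %s %s (got %g)", field,
        if (strict_min) ">" else ">=", format(min), v))
    if (!is.null(max) && v > max)
      problems <<- c(problems, sprintf("`%s` must be <= %s (got %g)", field, format(max), v))
  }
  need_num("R", min = 0, strict_min = TRUE)
  need_num("A", min = 0)
  need_num("a", min = 0)
  need_num("gamma0", min = 0, strict_min = TRUE)
  need_num("S0", min = 0, strict_min = TRUE)
  need_num("S_max", min = 0)
  need_num("S_rate", min = 0)
  need_num("p_photo", min = 0, max = 1)
  need_num("phi_ch", min = 0, max = 1)
  need_num("rho", min = 0, strict_min = TRUE)
  need_num("n_cells", min = 1)
  need_num("S_floor", min = 0, strict_min = TRUE)
  need_num("step_cap", min = 0, strict_min = TRUE)
  need_num("spacing", min = 0, strict_min = TRUE)
  need_num("n_steps", min = 0)
  if (is.numeric(cfg$S0) && is.numeric(cfg$S_max) && length(cfg$S0) == 1 &&
      length(cfg$S_max) == 1 && isTRUE(cfg$S0 > cfg$S_max))
    problems <- c(problems, sprintf("`S0` (%g) must not exceed `S_max` (%g)",
                                    cfg$S0, cfg$S_max))
  if (is.numeric(cfg$a) && cfg$a != round(cfg$a))
    problems <- c(problems, "`a` must be an integer count of pili")
  if (!identical(cfg$dt, 1) || !identical(cfg$f_bias, 1))
    problems <- c(problems, "`dt` and `f_bias` are fixed model constants equal to 1")
  if (length(problems))
    abort(c("invalid simulation configuration:", setNames(problems, rep("x", length(problems)))))
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d cells, density rho = %g, p_photo = %g, phi_ch = %g\n",
              x$n_cells, x$rho, x$p_photo, x$phi_ch))
  cat(sprintf("  R = %g, A = %g, a = %d, (k1, k2) = (%g, %g), gamma0 = %g\n",
              x$R, x$A, x$a, x$k1, x$k2, x$gamma0))
  cat(sprintf("  slime: S0 = %g, S_max = %g, S_rate = %g, S_floor = %g, spacing = %g\n",
              x$S0, x$S_max, x$S_rate, x$S_floor, x$spacing))
  cat(sprintf("  seed = %d, n_steps = %d\n", x$seed, x$n_steps))
  invisible(x)
}

# parameter list handed to the compiled stepper
cpp_params <- function(cfg) {
  cfg[c("R", "A", "a", "gamma0", "k1", "k2", "S0", "S_max", "S_rate",
        "p_photo", "f_bias", "step_cap", "S_floor", "spacing")]
}
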