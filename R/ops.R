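#' Pair force magnitude
#'
#' Signed magnitude of the pilus-mediated tug force between two cells whose
#' centres are a distance `D` apart:
#' `K(D) = (1 + k1 * (tanh(k2 * (D - 2R)) - 1)) / a`.
#' The sigmoid is negative below contact (`D < 2R`, soft-core repulsion),
#' crosses zero at contact when `k1 = 1`, and saturates to `1/a` at large
#' separation; dividing by the pilus count `a` spreads a cell's tug budget
#' over its pili.
#'
#' @param D Centre-to-centre distance (vectorized), non-negative.
#' @param R Cell radius.
#' @param k1,k2 Force-law amplitude and steepness.
#' @param a Number of pili per cell; must be positive.
#' @return Numeric vector of signed force magnitudes.
#' @examples
#' pair_force(c(2, 10), R = 1)   # zero at contact, ~1/4 far away
#' @export
pair_force <- function(D, R = 1, k1 = 1, k2 = 2, a = 4) {
  if (a == 0) abort("`a` must be positive: the force law divides by the pilus count")
  if (any(D < 0)) abort("`D` must be non-negative")
  cpp_pair_force(as.numeric(D), R, k1, k2, a)
}

#' Update cell headings
#'
#' Each sighted cell independently heads straight at the light with
#' probability `p_photo` and otherwise draws a uniform heading on
#' `[0, 2*pi)`; freeloaders always draw uniformly. Consumes the R RNG stream
#' in cell order (this fixed draw order is what makes runs reproducible at a
#' given seed).
#'
#' @param state A [cell_state()].
#' @param schedule A [light_schedule()].
#' @param t Current step index.
#' @param p_photo Probability of a light-directed heading.
#' @return Numeric vector of new headings in `[0, 2*pi)`.
#' @export
update_headings <- function(state, schedule, t, p_photo) {
  if (p_photo < 0 || p_photo > 1) abort("`p_photo` must lie in [0, 1]")
  cpp_update_headings(state$positions, state$headings, state$freeloader,
                      as_light_list(schedule), t, p_photo)
}

#' Select the tugs active this step
#'
#' Every cell acts as a donor: it picks at most `a` recipients uniformly
#' without replacement among the cells within `2R + A` of its centre (pilus
#' reach measured edge-to-centreline). Tugs are transient and regenerated
#' afresh each step; the cap applies to a cell as donor, so a crowded cell may
#' receive more than `a` tugs. Donor choices are independent, so reciprocity
#' is not guaranteed.
#'
#' @param state A [cell_state()] (or an `n x 2` position matrix).
#' @param R Cell radius.
#' @param A Pilus reach beyond the cell edge.
#' @param a Tug budget per donor.
#' @return A tibble with integer columns `donor` and `recipient`.
#' @export
select_tugs <- function(state, R = 1, A = 4 * R, a = 4) {
  pos <- if (inherits(state, "cell_state")) state$positions else as.matrix(state)
  m <- cpp_select_tugs(pos, R, A, as.integer(a))
  tibble(donor = as.integer(m[, 1]), recipient = as.integer(m[, 2]))
}

#' Net forces on each cell
#'
#' Sums, over the active tugs, the force each donor applies to its recipient:
#' magnitude [pair_force()] of the pair distance, directed along the unit
#' vector from recipient toward donor (attraction when positive, separation
#' when negative). Exactly coincident pairs get a random separation direction.
#' Also returns the heading bias force `G_i`, a unit vector along each cell's
#' heading.
#'
#' @param state A [cell_state()].
#' @param tugs Tug table from [select_tugs()].
#' @param config A [sim_config()].
#' @return List with `n x 2` matrices `F` (tug sum) and `G` (heading bias).
#' @export
net_forces <- function(state, tugs, config) {
  tm <- cbind(as.integer(tugs$donor), as.integer(tugs$recipient))
  if (nrow(tm) > 0) {
    n <- nrow(state$positions)
    if (any(tm < 1) || any(tm > n)) abort("tug indices out of range")
    if (any(tm[, 1] == tm[, 2])) abort("self-tugs are not allowed")
  }
  cpp_net_forces(state$positions, tm, state$headings, cpp_params(config))
}

#' Slime-dependent friction
#'
#' `gamma = gamma0 * S0 / max(S, S_floor)` with `S` the slime at the lattice
#' site nearest each coordinate. Equal to `gamma0` exactly on `S0` ground; the
#' `S_floor` clamp keeps friction finite on virgin substrate.
#'
#' @param slime A [slime_field()].
#' @param x,y Coordinates (vectorized).
#' @param gamma0 Friction at slime level `S0`.
#' @param S0 Reference slime level.
#' @param S_floor Minimum effective slime.
#' @return Numeric vector of friction factors.
#' @export
friction <- function(slime, x, y, gamma0 = 10, S0 = 1000, S_floor = 1) {
  if (gamma0 <= 0 || S0 <= 0) abort("`gamma0` and `S0` must be positive")
  gamma0 * S0 / pmax(slime_at(slime, x, y), S_floor)
}

#' Move cells one step
#'
#' Overdamped update: each cell is displaced by `(G_i + F_i) / gamma_i`, with
#' the displacement magnitude clamped to `step_cap` (`R/10` by default — with
#' the standard parameters an unhindered cell on `S0` ground moves exactly
#' that far). Headings are not changed here.
#'
#' @param state A [cell_state()].
#' @param forces List with matrices `F` and `G` from [net_forces()].
#' @param slime A [slime_field()].
#' @param config A [sim_config()].
#' @return New `n x 2` position matrix.
#' @export
move_cells <- function(state, forces, slime, config) {
  tot <- forces$F + forces$G
  if (!all(is.finite(tot))) abort("non-finite forces passed to `move_cells()`")
  gam <- friction(slime, state$positions[, 1], state$positions[, 2],
                  config$gamma0, config$S0, config$S_floor)
  disp <- tot / gam
  d <- sqrt(rowSums(disp^2))
  over <- d > config$step_cap
  if (any(over)) disp[over, ] <- disp[over, , drop = FALSE] * (config$step_cap / d[over])
  state$positions + disp
}

#' Deposit slime
#'
#' Every cell adds `S_rate` to the lattice site nearest its centre; a site
#' shared by `m` cells gains `m * S_rate`. Sites are clamped at `S_max`.
#' There is no diffusion and no decay.
#'
#' @param slime A [slime_field()].
#' @param positions `n x 2` matrix of cell centres.
#' @param S_rate Amount per cell per step.
#' @param S_max Per-site cap.
#' @return The updated `slime_field`.
#' @export
deposit_slime <- function(slime, positions, S_rate = 0.1, S_max = slime$S_max) {
  if (S_rate < 0) abort("`S_rate` must be non-negative")
  positions <- as.matrix(positions)
  r <- as.integer(round(positions[, 2] / slime$spacing))
  c <- as.integer(round(positions[, 1] / slime$spacing))
  slime <- grow_slime_field(slime, range(r), range(c))
  key <- paste(r, c)
  counts <- table(key)
  uk <- names(counts)
  parts <- matrix(as.integer(unlist(strsplit(uk, " "))), ncol = 2, byrow = TRUE)
  i <- parts[, 1] - slime$r_min + 1L
  j <- parts[, 2] - slime$c_min + 1L
  idx <- cbind(i, j)
  slime$values[idx] <- pmin(slime$values[idx] + as.numeric(counts) * S_rate, S_max)
  slime
}

#' Advance the model one step
#'
#' Applies, in order: heading update, tug selection, force computation,
#' overdamped move, then slime deposition at the post-move positions. This is
#' the reference composition of the individual operations; [run_sim()] executes
#' the identical sequence in compiled code, and the two agree draw-for-draw at
#' a fixed RNG state.
#'
#' @param state A [cell_state()].
#' @param slime A [slime_field()].
#' @param schedule A [light_schedule()].
#' @param config A [sim_config()].
#' @param t Current step index.
#' @return List with elements `state`, `slime`, and `t` (advanced by 1).
#' @export
step_cells <- function(state, slime, schedule, config, t = 0) {
  state$headings <- update_headings(state, schedule, t, config$p_photo)
  tugs <- select_tugs(state, config$R, config$A, config$a)
  forces <- net_forces(state, tugs, config)
  state$positions <- move_cells(state, forces, slime, config)
  slime <- deposit_slime(slime, state$positions, config$S_rate, config$S_max)
  list(state = state, slime = slime, t = t + config$dt)
}
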