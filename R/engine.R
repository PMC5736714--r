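get_rng_state <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

set_rng_state <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
  invisible(state)
}

bind_steps <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  da <- dim(a); db <- dim(b)
  if (length(da) == 3) {
    out <- array(NA_real_, c(da[1] + db[1], da[2], da[3]))
    out[seq_len(da[1]), , ] <- a
    out[da[1] + seq_len(db[1]), , ] <- b
  } else {
    out <- array(NA_real_, c(da[1] + db[1], da[2]))
    out[seq_len(da[1]), ] <- a
    out[da[1] + seq_len(db[1]), ] <- b
  }
  out
}

#' Run a simulation
#'
#' Drives the per-step update over a full run: heading update, tug selection,
#' forces, overdamped move, slime deposition — all in compiled code — while
#' recording positions every `record_every` steps (plus the initial and final
#' state) and slime snapshots every `slime_every` steps. A run is fully
#' reproducible: the same configuration and seed give bit-identical records.
#'
#' `run_sim()` accepts either a scenario from [phototax_preset()] or a
#' [sim_config()] plus geometry and schedule.
#'
#' @param x A `phototax_scenario` or [sim_config()].
#' @param ... Passed through between methods.
#' @param geometry A [colony_geometry()] (config method).
#' @param schedule A [light_schedule()].
#' @param n_steps Run length; defaults to `config$n_steps`.
#' @param record_every Position-recording interval (steps).
#' @param slime_every Slime-snapshot interval; 0 disables snapshots (the final
#'   field is always kept).
#' @param record_headings Record per-step headings too (memory doubles).
#' @param init Optional list `(state, slime)` to start from, bypassing
#'   [make_colony()].
#' @param band Optional `c(xmin, xmax, level)` slime band laid before t = 0.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return An object of class `phototax_record`; see [tidy.phototax_record()].
#' @examples
#' rec <- run_sim(phototax_preset("circle", n_cells = 50, n_steps = 200))
#' dplyr::glimpse(tidy(rec))
#' @export
run_sim <- function(x, ...) UseMethod("run_sim")

#' @rdname run_sim
#' @export
run_sim.phototax_scenario <- function(x, n_steps = NULL, ...) {
  cfg <- x$config
  if (!is.null(n_steps)) cfg$n_steps <- as.integer(n_steps)
  run_sim(cfg, geometry = x$geometry, schedule = x$schedule, band = x$band,
          ...)
}

#' @rdname run_sim
#' @export
run_sim.sim_config <- function(x, geometry, schedule = light_schedule(angle = 0),
                               n_steps = x$n_steps, record_every = 100L,
                               slime_every = 1000L, record_headings = FALSE,
                               init = NULL, band = NULL, seed = x$seed, ...) {
  config <- x
  if (record_every < 1) abort("`record_every` must be >= 1")
  set.seed(seed)
  if (is.null(init)) init <- make_colony(config, geometry, schedule)
  if (!is.null(band))
    init$slime <- make_slime_band(init$slime, band[1:2], band[3])

  res <- cpp_run(init$state$positions, init$state$headings,
                 init$state$freeloader,
                 init$slime$values, init$slime$r_min, init$slime$c_min,
                 cpp_params(config), as_light_list(schedule), 0,
                 as.integer(n_steps), as.integer(record_every),
                 record_headings, as.integer(slime_every))
  rng_state <- get_rng_state()

  n <- config$n_cells
  pos0 <- array(NA_real_, c(1, n, 2))
  pos0[1, , 1] <- init$state$positions[, 1]
  pos0[1, , 2] <- init$state$positions[, 2]
  head0 <- if (record_headings) matrix(init$state$headings, nrow = 1) else NULL

  final_slime <- slime_field(res$final_slime, res$r_min, res$c_min,
                             spacing = config$spacing, S_max = config$S_max)
  snaps <- lapply(res$slime_snaps, function(s)
    slime_field(s$values, s$r_min, s$c_min, spacing = config$spacing,
                S_max = config$S_max))

  structure(list(
    times = c(0, res$times),
    positions = bind_steps(pos0, res$positions),
    headings = if (record_headings) bind_steps(head0, res$headings) else NULL,
    freeloader = init$state$freeloader,
    slime_times = c(0, res$slime_times),
    slime_snaps = c(list(init$slime), snaps),
    final = list(
      state = cell_state(res$final_positions, res$final_headings,
                         init$state$freeloader),
      slime = final_slime, t = res$t_end, rng_state = rng_state),
    config = config, geometry = geometry, schedule = schedule,
    seed = seed, record_every = as.integer(record_every),
    slime_every = as.integer(slime_every), max_disp = res$max_disp
  ), class = "phototax_record")
}

#' Resume a recorded run
#'
#' Continues a run from its stored final state (positions, headings, slime,
#' RNG state). `run_sim` for `n` steps followed by `resume` for `m` steps is
#' bit-identical to a single run of `n + m` steps at the same seed, including
#' across light-schedule switches.
#'
#' @param record A `phototax_record`.
#' @param extra_steps Steps to append (0 returns the record unchanged).
#' @param record_every,slime_every Recording intervals for the appended span;
#'   default those of the original run.
#' @return The extended `phototax_record`.
#' @export
resume <- function(record, extra_steps, record_every = record$record_every,
                   slime_every = record$slime_every) {
  stopifnot(inherits(record, "phototax_record"))
  if (is.null(record$final$rng_state) || is.null(record$final$slime))
    abort("record lacks the final slime/RNG state needed to resume")
  if (extra_steps == 0) return(record)
  record_headings <- !is.null(record$headings)
  config <- record$config
  set_rng_state(record$final$rng_state)
  st <- record$final$state
  sl <- record$final$slime
  res <- cpp_run(st$positions, st$headings, st$freeloader,
                 sl$values, sl$r_min, sl$c_min,
                 cpp_params(config), as_light_list(record$schedule),
                 record$final$t, as.integer(extra_steps),
                 as.integer(record_every), record_headings,
                 as.integer(slime_every))
  rng_state <- get_rng_state()

  record$times <- c(record$times, res$times)
  record$positions <- bind_steps(record$positions, res$positions)
  if (record_headings)
    record$headings <- bind_steps(record$headings, res$headings)
  record$slime_times <- c(record$slime_times, res$slime_times)
  record$slime_snaps <- c(record$slime_snaps,
    lapply(res$slime_snaps, function(s)
      slime_field(s$values, s$r_min, s$c_min, spacing = config$spacing,
                  S_max = config$S_max)))
  record$final <- list(
    state = cell_state(res$final_positions, res$final_headings, st$freeloader),
    slime = slime_field(res$final_slime, res$r_min, res$c_min,
                        spacing = config$spacing, S_max = config$S_max),
    t = res$t_end, rng_state = rng_state)
  record$max_disp <- max(record$max_disp, res$max_disp)
  record
}
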