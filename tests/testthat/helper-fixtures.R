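# shared fixtures and independent oracles

# a uniform slime mat at level S0 covering x in xlim, y in ylim
uniform_slime <- function(xlim = c(-50, 50), ylim = c(-50, 50), S0 = 1000,
                          S_max = 1000, spacing = 1) {
  rr <- ceiling(ylim[1] / spacing):floor(ylim[2] / spacing)
  cc <- ceiling(xlim[1] / spacing):floor(xlim[2] / spacing)
  slime_field(matrix(S0, length(rr), length(cc)),
              r_min = rr[1], c_min = cc[1], spacing = spacing, S_max = S_max)
}

# a single cell at the origin on a uniform S0 mat
single_cell_run <- function(p_photo, n_steps, seed = 1, record_every = 1,
                            xlim = NULL) {
  cfg <- sim_config(n_cells = 1, p_photo = p_photo, n_steps = n_steps,
                    seed = seed)
  if (is.null(xlim)) {
    reach <- 0.1 * n_steps + 5
    xlim <- c(-reach, reach)
  }
  init <- list(state = cell_state(matrix(0, 1, 2)),
               slime = uniform_slime(xlim, c(-0.25 * abs(xlim[2]) - 20,
                                             0.25 * abs(xlim[2]) + 20)))
  run_sim(cfg, geometry = colony_geometry("circle", 1, 0.05),
          schedule = light_schedule(angle = 0), n_steps = n_steps,
          record_every = record_every, slime_every = 0, init = init,
          seed = seed)
}

# O(n^2) oracle for the within-cutoff pair list, as a sorted two-column matrix
brute_pairs <- function(pos, cutoff) {
  n <- nrow(pos)
  d <- as.matrix(dist(pos))
  out <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  m <- cbind(pmin(out[, 1], out[, 2]), pmax(out[, 1], out[, 2]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# build a minimal record object from a [time x cell x 2] position array
synthetic_record <- function(positions, times = seq_len(dim(positions)[1]) - 1,
                             freeloader = rep(FALSE, dim(positions)[2]),
                             config = sim_config(n_cells = dim(positions)[2]),
                             geometry = colony_geometry("circle",
                                                        dim(positions)[2], 0.05),
                             schedule = light_schedule(angle = 0)) {
  structure(list(times = times, positions = positions, headings = NULL,
                 freeloader = freeloader, slime_times = numeric(),
                 slime_snaps = list(),
                 final = list(state = cell_state(
                   cbind(positions[dim(positions)[1], , 1],
                         positions[dim(positions)[1], , 2])),
                   slime = NULL, t = max(times), rng_state = NULL),
                 config = config, geometry = geometry, schedule = schedule,
                 seed = 0L, record_every = 1L, slime_every = 0L,
                 max_disp = NA_real_),
            class = "phototax_record")
}

# small colony scenario used across engine tests
small_circle <- function(n = 60, seed = 5, ...) {
  phototax_preset("circle", n_cells = as.integer(n), ...)
}
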