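#' @export
print.phototax_record <- function(x, ...) {
  cat(sprintf("<phototax_record> %d cells, %d recorded steps (t = %g .. %g), seed %d\n",
              dim(x$positions)[2], length(x$times), min(x$times),
              max(x$times), x$seed))
  cat(sprintf("  p_photo = %g, phi_ch = %g, max step displacement %.4g\n",
              x$config$p_photo, x$config$phi_ch, x$max_disp))
  invisible(x)
}

#' Tidy a simulation record
#'
#' One row per recorded step per cell, with columns `step`, `cell_id`, `x`,
#' `y`, `freeloader` (and `heading` when headings were recorded). This is the
#' canonical tabular export of a run.
#'
#' @param x A `phototax_record`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.phototax_record <- function(x, ...) {
  nt <- length(x$times)
  n <- dim(x$positions)[2]
  xv <- as.vector(x$positions[, , 1])
  yv <- as.vector(x$positions[, , 2])
  fv <- rep(x$freeloader, each = nt)
  out <- tibble(
    step = rep(x$times, times = n),
    cell_id = rep(seq_len(n), each = nt),
    x = xv,
    y = yv,
    freeloader = fv)
  if (!is.null(x$headings)) out$heading <- as.vector(x$headings)
  out
}

#' One-row summary of a run
#'
#' @param x A `phototax_record`.
#' @param ... Unused.
#' @return A one-row tibble: cell and step counts, key parameters, total
#'   slime, and the largest single-step displacement observed.
#' @export
glance.phototax_record <- function(x, ...) {
  tibble(
    n_cells = dim(x$positions)[2],
    n_steps = max(x$times),
    n_recorded = length(x$times),
    seed = x$seed,
    p_photo = x$config$p_photo,
    phi_ch = x$config$phi_ch,
    rho = x$config$rho,
    total_slime = slime_total(x$final$slime),
    max_step_disp = x$max_disp)
}

#' Positions at a recorded step
#'
#' @param record A `phototax_record`.
#' @param t A step index present in `record$times` (default: last).
#' @return An `n x 2` matrix of positions.
#' @export
positions_at <- function(record, t = max(record$times)) {
  i <- match(t, record$times)
  if (is.na(i))
    abort(sprintf("step %g was not recorded (nearest recorded: %g)",
                  t, record$times[which.min(abs(record$times - t))]))
  m <- cbind(record$positions[i, , 1], record$positions[i, , 2])
  colnames(m) <- c("x", "y")
  m
}

#' Slime snapshot nearest a step
#'
#' @param record A `phototax_record`.
#' @param t Step index; the stored snapshot closest in time is returned.
#' @return A [slime_field()].
#' @export
slime_at_step <- function(record, t = max(record$times)) {
  if (length(record$slime_snaps) == 0) return(record$final$slime)
  record$slime_snaps[[which.min(abs(record$slime_times - t))]]
}
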