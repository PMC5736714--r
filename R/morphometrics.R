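rec_index_span <- function(record, t_range, need_unit_stride = TRUE, what) {
  times <- record$times
  if (is.null(t_range)) t_range <- range(times)
  idx <- which(times >= t_range[1] & times <= t_range[2])
  if (length(idx) < 2)
    abort(sprintf("%s needs at least two recorded steps in the analysis span", what))
  if (need_unit_stride && any(diff(times[idx]) != 1))
    abort(paste0(what, " requires consecutive steps (record_every = 1) over ",
                 "the analysis span; re-run or resume() that span with ",
                 "record_every = 1"))
  idx
}

#' Rose-plot histogram of short-window movement directions
#'
#' Tracks every cell across a moving window and histograms the direction of
#' its net displacement over `window` steps — the standard rose-plot input.
#' Windows with exactly zero net displacement carry no direction and are
#' excluded (their count is reported in the `n_excluded` attribute). The raw
#' angles are kept in the `angles` attribute so circular statistics can be
#' computed from them rather than from bin centres.
#'
#' @param record A `phototax_record` recorded at unit stride over the span.
#' @param window Window length in steps (default 5).
#' @param n_bins Number of angular bins (default 36, i.e. 10 degrees).
#' @param t_range Optional `c(from, to)` restricting the analysis span.
#' @param stride Spacing between window starts; 1 (default) is the sliding
#'   window, `window` gives non-overlapping windows.
#' @param cells Optional integer vector restricting the analysis to a subset
#'   of cells (e.g. the members of detected fingers).
#' @return A tibble of class `direction_histogram` with columns `bin_left`,
#'   `bin_mid`, `bin_right`, `count`; attributes `angles`, `window`,
#'   `n_excluded`.
#' @export
direction_histogram <- function(record, window = 5, n_bins = 36,
                                t_range = NULL, stride = 1, cells = NULL) {
  idx <- rec_index_span(record, t_range, TRUE, "direction_histogram()")
  if (length(idx) < window + 1)
    abort("analysis span shorter than one window")
  xs <- record$positions[idx, , 1, drop = FALSE]
  ys <- record$positions[idx, , 2, drop = FALSE]
  dim(xs) <- dim(xs)[1:2]
  dim(ys) <- dim(ys)[1:2]
  if (!is.null(cells)) {
    xs <- xs[, cells, drop = FALSE]
    ys <- ys[, cells, drop = FALSE]
  }
  nt <- length(idx)
  starts <- seq(1, nt - window, by = stride)
  dx <- xs[starts + window, , drop = FALSE] - xs[starts, , drop = FALSE]
  dy <- ys[starts + window, , drop = FALSE] - ys[starts, , drop = FALSE]
  moved <- (dx != 0) | (dy != 0)
  angles <- atan2(dy[moved], dx[moved]) %% (2 * pi)
  breaks <- seq(0, 2 * pi, length.out = n_bins + 1)
  counts <- tabulate(pmin(floor(angles / (2 * pi) * n_bins) + 1, n_bins),
                     nbins = n_bins)
  out <- tibble(bin_left = breaks[-(n_bins + 1)],
                bin_mid = (breaks[-(n_bins + 1)] + breaks[-1]) / 2,
                bin_right = breaks[-1],
                count = counts)
  attr(out, "angles") <- angles
  attr(out, "window") <- window
  attr(out, "n_excluded") <- sum(!moved)
  class(out) <- c("direction_histogram", class(out))
  out
}

#' Circular anisotropy of a direction distribution
#'
#' Mean resultant length (0 for an isotropic distribution, 1 when all
#' directions coincide) and circular mean angle. For a `direction_histogram`
#' the retained raw angles are used, not the bin centres.
#'
#' @param x A `direction_histogram` or a numeric vector of angles (radians).
#' @param ... Unused.
#' @return A one-row tibble: `resultant_length`, `mean_angle` (in
#'   `[0, 2*pi)`), `n`.
#' @export
anisotropy <- function(x, ...) UseMethod("anisotropy")

#' @export
anisotropy.direction_histogram <- function(x, ...) {
  ang <- attr(x, "angles")
  if (length(ang) == 0) abort("empty direction histogram")
  anisotropy(ang)
}

#' @export
anisotropy.numeric <- function(x, ...) {
  if (length(x) == 0) abort("no angles supplied")
  C <- mean(cos(x)); S <- mean(sin(x))
  tibble(resultant_length = sqrt(C^2 + S^2),
         mean_angle = atan2(S, C) %% (2 * pi),
         n = length(x))
}

#' Kymograph traces
#'
#' One coordinate of every cell against time, plus the per-interval speed
#' (2-D displacement magnitude per step between consecutive recorded steps).
#' Suitable for coordinate-versus-time renderings of finger formation and
#' band crossing.
#'
#' @param record A `phototax_record`.
#' @param axis `"x"` or `"y"`.
#' @return A tibble: `step`, `cell_id`, `coord`, `speed` (`NA` at the first
#'   recorded step of each cell).
#' @export
kymograph <- function(record, axis = c("x", "y")) {
  axis <- match.arg(axis)
  nt <- length(record$times)
  n <- dim(record$positions)[2]
  xs <- record$positions[, , 1, drop = FALSE]
  ys <- record$positions[, , 2, drop = FALSE]
  dim(xs) <- dim(ys) <- c(nt, n)
  dt <- diff(record$times)
  dxs <- xs[-1, , drop = FALSE] - xs[-nt, , drop = FALSE]
  dys <- ys[-1, , drop = FALSE] - ys[-nt, , drop = FALSE]
  spd <- sqrt(dxs^2 + dys^2) / dt
  tibble(
    step = rep(record$times, times = n),
    cell_id = rep(seq_len(n), each = nt),
    coord = as.vector(if (axis == "x") xs else ys),
    speed = as.vector(rbind(NA_real_, spd)))
}

#' Finger segmentation
#'
#' Fingers are single-linkage clusters (linkage distance `link_dist`,
#' default `2R + A`) of the cells lying outside the reference colony boundary
#' by at least `margin` (default `2R`); clusters with at least `min_size`
#' members count as fingers.
#'
#' @param record A `phototax_record`.
#' @param t Recorded step to analyse (default: last).
#' @param reference A [colony_geometry()]; default the record's own.
#' @param link_dist Single-linkage merge distance.
#' @param min_size Minimum cells per finger.
#' @param margin Required distance beyond the boundary.
#' @return A tibble with one row per member cell: `finger_id` (1 = largest),
#'   `cell_id`, `x`, `y`, `dist_outside`.
#' @export
detect_fingers <- function(record, t = max(record$times),
                           reference = record$geometry,
                           link_dist = NULL, min_size = 10, margin = NULL) {
  cfg <- record$config
  if (is.null(link_dist)) link_dist <- 2 * cfg$R + cfg$A
  if (is.null(margin)) margin <- 2 * cfg$R
  pos <- positions_at(record, t)
  d_out <- dist_outside(reference, pos[, 1], pos[, 2])
  outside <- which(d_out >= margin)
  empty <- tibble(finger_id = integer(), cell_id = integer(),
                  x = numeric(), y = numeric(), dist_outside = numeric())
  if (length(outside) == 0) return(empty)
  if (length(outside) == 1) {
    grp <- 1L
  } else {
    hc <- hclust(dist(pos[outside, , drop = FALSE]), method = "single")
    grp <- cutree(hc, h = link_dist)
  }
  keep_grp <- as.integer(names(which(table(grp) >= min_size)))
  if (length(keep_grp) == 0) return(empty)
  # renumber fingers largest-first
  sizes <- sort(table(grp)[as.character(keep_grp)], decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  keep <- grp %in% keep_grp
  tibble(
    finger_id = as.integer(relabel[as.character(grp[keep])]),
    cell_id = outside[keep],
    x = pos[outside[keep], 1],
    y = pos[outside[keep], 2],
    dist_outside = d_out[outside[keep]]) %>%
    dplyr::arrange(.data$finger_id, .data$cell_id)
}

#' @rdname detect_fingers
#' @param fingers Output of `detect_fingers()`.
#' @return `summarise_fingers()`: one row per finger with member count,
#'   centroid and maximal extent beyond the boundary.
#' @export
summarise_fingers <- function(fingers) {
  fingers %>%
    dplyr::group_by(.data$finger_id) %>%
    dplyr::summarise(n_cells = dplyr::n(),
                     centroid_x = mean(.data$x),
                     centroid_y = mean(.data$y),
                     max_extent = max(.data$dist_outside),
                     .groups = "drop")
}

#' Finger onset time
#'
#' The earliest recorded step `t` at which [detect_fingers()] is non-empty at
#' every recorded step in `[t, t + persistence]`. The persistence requirement
#' rejects transient stragglers; `persistence = 0` reduces to the first
#' non-empty detection. Returns `NA` when fingers never (persistently) form
#' within the record.
#'
#' @inheritParams detect_fingers
#' @param persistence Steps over which detection must persist (default 500).
#' @return The onset step, or `NA`.
#' @export
finger_onset <- function(record, reference = record$geometry,
                         min_size = 10, persistence = 500,
                         link_dist = NULL, margin = NULL) {
  times <- record$times
  has <- vapply(times, function(t)
    nrow(detect_fingers(record, t, reference, link_dist, min_size, margin)) > 0,
    logical(1))
  for (i in which(has)) {
    t0 <- times[i]
    if (t0 + persistence > max(times)) break   # window not covered by record
    win <- which(times >= t0 & times <= t0 + persistence)
    if (all(has[win])) return(t0)
  }
  NA_real_
}

#' Band-crossing speed profile
#'
#' Mean per-step speed stratified by where the cell was relative to a slime
#' band laid across the path of advancing fingers: `before` (x below the band,
#' optionally restricted to `x >= before_from` to exclude the colony
#' interior), `inside`, and `after`. By default only cells that actually
#' reach the band interior contribute, each cell's strata means being
#' averaged with equal weight per cell.
#'
#' @param record A `phototax_record` (unit stride over the crossing gives
#'   per-step speeds; coarser records give per-interval means).
#' @param band `c(xmin, xmax)`.
#' @param before_from Lower x-limit of the `before` stratum (default `-Inf`).
#' @param after_to Upper x-limit of the `after` stratum (default `Inf`).
#' @param cells `"crossing"` (default) restricts to cells observed inside the
#'   band; `"all"` uses every cell.
#' @return A tibble: `stratum`, `n_cells`, `n_intervals`, `mean_speed`.
#' @export
band_speed_profile <- function(record, band, before_from = -Inf,
                               after_to = Inf, cells = c("crossing", "all")) {
  cells <- match.arg(cells)
  ky <- kymograph(record, "x")
  ky <- ky[!is.na(ky$speed), , drop = FALSE]
  ky$stratum <- dplyr::case_when(
    ky$coord >= band[1] & ky$coord <= band[2] ~ "inside",
    ky$coord < band[1] & ky$coord >= before_from ~ "before",
    ky$coord > band[2] & ky$coord <= after_to ~ "after",
    TRUE ~ NA_character_)
  ky <- ky[!is.na(ky$stratum), , drop = FALSE]
  if (cells == "crossing") {
    crossing <- unique(ky$cell_id[ky$stratum == "inside"])
    ky <- ky[ky$cell_id %in% crossing, , drop = FALSE]
  }
  ky %>%
    dplyr::group_by(.data$cell_id, .data$stratum) %>%
    dplyr::summarise(m = mean(.data$speed), k = dplyr::n(), .groups = "drop") %>%
    dplyr::group_by(.data$stratum) %>%
    dplyr::summarise(n_cells = dplyr::n(),
                     n_intervals = sum(.data$k),
                     mean_speed = mean(.data$m),
                     .groups = "drop") %>%
    dplyr::arrange(factor(.data$stratum, levels = c("before", "inside", "after")))
}

#' Net drift along the light axis, by freeloader status
#'
#' Mean signed displacement per step along the light axis (the first light
#' segment's direction; for a point source, the bearing from the initial
#' colony centroid), split into sighted cells and freeloaders. The standard
#' error is across cells.
#'
#' @param record A `phototax_record`.
#' @param t_range Optional `c(from, to)` span (default: whole record).
#' @return A tibble with one row per group present: `group`, `n`,
#'   `drift_per_step`, `se`.
#' @export
freeloader_drift <- function(record, t_range = NULL) {
  times <- record$times
  if (is.null(t_range)) t_range <- range(times)
  i0 <- which.min(abs(times - t_range[1]))
  i1 <- which.min(abs(times - t_range[2]))
  if (i1 <= i0) abort("`t_range` must span at least one recorded interval")
  seg <- record$schedule[1, ]
  if (seg$mode == 0) {
    axis <- seg$angle
  } else {
    cen <- colMeans(cbind(record$positions[1, , 1], record$positions[1, , 2]))
    axis <- atan2(seg$py - cen[2], seg$px - cen[1])
  }
  u <- c(cos(axis), sin(axis))
  dx <- record$positions[i1, , 1] - record$positions[i0, , 1]
  dy <- record$positions[i1, , 2] - record$positions[i0, , 2]
  drift <- (dx * u[1] + dy * u[2]) / (times[i1] - times[i0])
  tibble(freeloader = record$freeloader, drift = drift) %>%
    dplyr::group_by(group = ifelse(.data$freeloader, "freeloader", "sighted")) %>%
    dplyr::summarise(n = dplyr::n(),
                     drift_per_step = mean(.data$drift),
                     se = sd(.data$drift) / sqrt(dplyr::n()),
                     .groups = "drop")
}
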