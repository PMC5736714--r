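`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a run configuration from a YAML file
#'
#' A declarative run description: optionally a `preset` name, any
#' [sim_config()] field (unspecified fields take the standard defaults), and
#' optional `geometry` (shape/anchor/aspect), `schedule` (list of segments
#' with `t_start` and `angle` or `point: [x, y]`), `band`
#' (`xmin`/`xmax`/`level`), `t_switch`, `record_every`, `slime_every`, `seed`.
#' Unknown keys and out-of-range values are reported together.
#'
#' @param path Path to the YAML file.
#' @return A `phototax_scenario` (with `record_every`/`slime_every` attached
#'   when given), ready for [run_sim()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_cfg <- names(formals(sim_config))
  known_top <- c(known_cfg, "preset", "geometry", "schedule", "band",
                 "t_switch", "record_every", "slime_every")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    abort(c("unknown configuration key(s):",
            setNames(unknown, rep("x", length(unknown)))))
  cfg_over <- raw[intersect(names(raw), known_cfg)]
  geo <- raw$geometry %||% list()
  band <- if (!is.null(raw$band))
    c(raw$band$xmin, raw$band$xmax, raw$band$level %||% 1000)

  if (!is.null(raw$preset)) {
    args <- c(list(name = raw$preset), cfg_over)
    if (!is.null(raw$t_switch)) args$t_switch <- raw$t_switch
    if (!is.null(band)) args$band <- band
    if (!is.null(geo$anchor)) args$anchor <- unlist(geo$anchor)
    if (!is.null(geo$aspect)) args$aspect <- geo$aspect
    sc <- do.call(phototax_preset, args)
  } else {
    config <- do.call(sim_config, cfg_over)
    geometry <- colony_geometry(geo$shape %||% "circle",
                                n_cells = config$n_cells, rho = config$rho,
                                anchor = unlist(geo$anchor %||% c(0, 0)),
                                aspect = geo$aspect %||% 10)
    schedule <- parse_schedule(raw$schedule)
    sc <- structure(list(name = "custom", config = config,
                         geometry = geometry, schedule = schedule,
                         band = band),
                    class = "phototax_scenario")
  }
  sc$record_every <- raw$record_every
  sc$slime_every <- raw$slime_every
  sc
}

parse_schedule <- function(spec) {
  if (is.null(spec)) return(light_schedule(angle = 0))
  t_start <- vapply(spec, function(s) as.numeric(s$t_start %||% 0), numeric(1))
  angle <- vapply(spec, function(s) as.numeric(s$angle %||% NA_real_), numeric(1))
  pts <- t(vapply(spec, function(s) {
    if (is.null(s$point)) c(NA_real_, NA_real_) else as.numeric(unlist(s$point))
  }, numeric(2)))
  light_schedule(angle = angle, t_start = t_start,
                 point = if (all(is.na(pts))) NULL else pts)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Persist and reload a run
#'
#' `write_run()` writes a plain-text container: `trajectory.csv`
#' (`step, cell_id, x, y, freeloader`, bit-stable column order, full double
#' precision), `slime_final.csv` (`r, c, value`, non-zero sites), and
#' `manifest.json` holding the full configuration echo, seed, schedule,
#' recorded times, the final state (positions, headings, RNG state) and code
#' version — everything needed to reload the record losslessly or resume it.
#' `read_run()` reconstructs the `phototax_record` (slime snapshots other
#' than the final field are not persisted).
#'
#' @param record A `phototax_record`.
#' @param dir Output directory (created if needed).
#' @return `write_run()`: `dir`, invisibly. `read_run()`: a `phototax_record`.
#' @export
write_run <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- tidy(record)
  df <- data.frame(step = tr$step, cell_id = tr$cell_id,
                   x = fmt_num(tr$x), y = fmt_num(tr$y),
                   freeloader = as.integer(tr$freeloader))
  write.csv(df, file.path(dir, "trajectory.csv"), row.names = FALSE,
            quote = FALSE)
  sl <- record$final$slime
  st <- tidy(sl)
  write.csv(data.frame(r = st$r, c = st$c, value = fmt_num(st$value)),
            file.path(dir, "slime_final.csv"), row.names = FALSE, quote = FALSE)
  # NA-free numeric form: all-NA columns would otherwise drop from the JSON
  sched <- as_light_list(record$schedule)
  manifest <- list(
    package = "phototaxr",
    version = as.character(packageVersion("phototaxr")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = record$seed,
    record_every = record$record_every,
    slime_every = record$slime_every,
    max_disp = record$max_disp,
    times = record$times,
    config = unclass(record$config),
    geometry = unclass(record$geometry),
    schedule = sched,
    freeloader = record$freeloader,
    slime = list(r_min = sl$r_min, c_min = sl$c_min,
                 nr = nrow(sl$values), nc = ncol(sl$values),
                 spacing = sl$spacing, S_max = sl$S_max),
    final = list(t = record$final$t,
                 headings = record$final$state$headings,
                 rng_state = record$final$rng_state))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_run
#' @export
read_run <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  tr <- read.csv(file.path(dir, "trajectory.csv"),
                 colClasses = c("numeric", "integer", "numeric", "numeric",
                                "integer"))
  times <- man$times
  nt <- length(times)
  n <- length(man$freeloader)
  ord <- order(tr$cell_id, tr$step)
  tr <- tr[ord, ]
  positions <- array(NA_real_, c(nt, n, 2))
  positions[, , 1] <- matrix(tr$x, nrow = nt)
  positions[, , 2] <- matrix(tr$y, nrow = nt)

  cfg <- man$config
  config <- do.call(sim_config, cfg[setdiff(names(cfg), c("dt", "f_bias"))])
  geometry <- structure(man$geometry, class = "colony_geometry")
  geometry$anchor <- as.numeric(geometry$anchor)
  sched <- man$schedule
  smode <- as.integer(sched$mode)
  schedule <- structure(
    tibble(t_start = as.numeric(sched$t_start), mode = smode,
           angle = ifelse(smode == 0L, as.numeric(sched$angle), NA_real_),
           px = ifelse(smode == 1L, as.numeric(sched$px), NA_real_),
           py = ifelse(smode == 1L, as.numeric(sched$py), NA_real_)),
    class = c("light_schedule", class(tibble())))
  sl <- read.csv(file.path(dir, "slime_final.csv"),
                 colClasses = c("integer", "integer", "numeric"))
  ms <- man$slime
  vals <- matrix(0, ms$nr, ms$nc)
  vals[cbind(sl$r - ms$r_min + 1L, sl$c - ms$c_min + 1L)] <- sl$value
  slime <- slime_field(vals, ms$r_min, ms$c_min, ms$spacing, ms$S_max)

  final_pos <- cbind(positions[nt, , 1], positions[nt, , 2])
  structure(list(
    times = times,
    positions = positions,
    headings = NULL,
    freeloader = as.logical(man$freeloader),
    slime_times = man$final$t,
    slime_snaps = list(slime),
    final = list(state = cell_state(final_pos, man$final$headings,
                                    as.logical(man$freeloader)),
                 slime = slime, t = man$final$t,
                 rng_state = as.integer(man$final$rng_state)),
    config = config, geometry = geometry, schedule = schedule,
    seed = man$seed, record_every = man$record_every,
    slime_every = man$slime_every, max_disp = man$max_disp
  ), class = "phototax_record")
}

#' JSON metrics summary of a run
#'
#' Computes the standard morphometrics that the record's resolution supports
#' (finger detection and onset always; anisotropy only where the record has a
#' unit-stride span; drift always) and writes them as a JSON summary.
#'
#' @param record A `phototax_record`.
#' @param path Output JSON path (`NULL` returns the list invisibly).
#' @param min_size,persistence Finger-detection settings.
#' @return The metrics list, invisibly.
#' @export
write_metrics <- function(record, path = NULL, min_size = 10,
                          persistence = 500) {
  fingers <- detect_fingers(record, min_size = min_size)
  onset <- finger_onset(record, min_size = min_size,
                        persistence = persistence)
  aniso <- tryCatch(
    as.list(anisotropy(direction_histogram(record))),
    error = function(e) NULL)
  metrics <- list(
    schema_version = 1L,
    glance = as.list(glance(record)),
    finger_count = length(unique(fingers$finger_id)),
    finger_sizes = as.integer(table(fingers$finger_id)),
    finger_onset = if (is.na(onset)) NULL else onset,
    anisotropy = aniso,
    drift = as.list(freeloader_drift(record)))
  if (!is.null(path))
    jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  invisible(metrics)
}
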