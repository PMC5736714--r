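test_that("a straight mover puts all rose-plot mass in the forward bin", {
  rec <- single_cell_run(p_photo = 1, n_steps = 60)
  h <- direction_histogram(rec, window = 5, n_bins = 36)
  expect_equal(sum(h$count), 56)          # 56 sliding windows, none excluded
  expect_equal(h$count[1], 56)            # all in the bin containing angle 0
  a <- anisotropy(h)
  expect_equal(a$resultant_length, 1, tolerance = 1e-12)
  expect_equal(a$mean_angle, 0, tolerance = 1e-12)
})

test_that("zero-displacement windows are excluded, not binned", {
  pos <- array(0, c(20, 2, 2))            # cell 1 frozen, cell 2 moves in +y
  pos[, 2, 2] <- 0.1 * (0:19)
  rec <- synthetic_record(pos)
  h <- direction_histogram(rec, window = 5)
  expect_equal(attr(h, "n_excluded"), 15)
  expect_equal(sum(h$count), 15)
  expect_equal(anisotropy(h)$mean_angle, pi / 2, tolerance = 1e-12)
})

test_that("anisotropy matches closed-form circular statistics", {
  expect_equal(anisotropy(rep(1.3, 100))$resultant_length, 1, tolerance = 1e-14)
  # perfectly balanced angles cancel exactly
  expect_lt(anisotropy(2 * pi * (0:999) / 1000)$resultant_length, 1e-12)
  expect_lt(anisotropy(c(0.7, 0.7 + pi))$resultant_length, 1e-12)
  # global rotation rotates the mean and preserves the resultant length
  set.seed(1)
  ang <- rnorm(500, mean = 1, sd = 0.4) %% (2 * pi)
  a0 <- anisotropy(ang)
  a1 <- anisotropy((ang + 0.9) %% (2 * pi))
  expect_equal(a1$resultant_length, a0$resultant_length, tolerance = 1e-12)
  expect_equal(a1$mean_angle, (a0$mean_angle + 0.9) %% (2 * pi),
               tolerance = 1e-10)
  expect_error(anisotropy(numeric(0)), "no angles")
})

test_that("kymograph traces carry slope and per-step speed", {
  rec <- single_cell_run(p_photo = 1, n_steps = 40)
  ky <- kymograph(rec, "x")
  expect_equal(nrow(ky), 41)
  slopes <- diff(ky$coord) / diff(ky$step)
  expect_equal(slopes, rep(0.1, 40), tolerance = 1e-12)
  expect_equal(ky$speed[-1], rep(0.1, 40), tolerance = 1e-12)
  expect_true(is.na(ky$speed[1]))
  # a stationary synthetic trace is flat with zero speed
  rec2 <- synthetic_record(array(3, c(10, 1, 2)))
  ky2 <- kymograph(rec2, "y")
  expect_equal(unique(ky2$coord), 3)
  expect_equal(ky2$speed[-1], rep(0, 9))
})

test_that("finger detection applies margin, linkage, and size rules", {
  geo <- colony_geometry("circle", 100, 0.05)   # radius ~25.2
  R <- geo$radius
  # 12-cell chain outside the boundary with gaps below the linkage distance
  chain <- cbind(R + 3 + 5 * (0:11), rep(0, 12))
  inside <- cbind(runif(88, -5, 5), runif(88, -5, 5))
  pos <- array(NA_real_, c(2, 100, 2))
  pos[1, , ] <- pos[2, , ] <- rbind(chain, inside)
  rec <- synthetic_record(pos, times = c(0, 1), geometry = geo,
                          config = sim_config(n_cells = 100))
  f <- detect_fingers(rec, t = 1, min_size = 10)
  expect_equal(length(unique(f$finger_id)), 1)
  expect_equal(nrow(f), 12)
  expect_setequal(f$cell_id, 1:12)
  # all cells inside: nothing detected
  pos0 <- array(0, c(1, 20, 2))
  rec0 <- synthetic_record(pos0, times = 0, geometry = geo,
                           config = sim_config(n_cells = 20))
  expect_equal(nrow(detect_fingers(rec0, t = 0)), 0)
  # two chains separated by more than the linkage distance
  chain2 <- cbind(chain[, 1], rep(30, 12))
  pos2 <- array(NA_real_, c(1, 112, 2))
  pos2[1, , ] <- rbind(chain, chain2, inside)
  rec2 <- synthetic_record(pos2, times = 0, geometry = geo,
                           config = sim_config(n_cells = 112))
  f2 <- detect_fingers(rec2, t = 0, min_size = 10)
  expect_equal(length(unique(f2$finger_id)), 2)
  s2 <- summarise_fingers(f2)
  expect_equal(s2$n_cells, c(12, 12))
})

test_that("single-linkage fingers equal connected components of the pair graph", {
  skip_if_not_installed("igraph")
  geo <- colony_geometry("circle", 300, 0.05)
  set.seed(7)
  for (rep in 1:4) {
    pos <- matrix(rnorm(600, sd = geo$radius), ncol = 2)
    arr <- array(NA_real_, c(1, 300, 2)); arr[1, , ] <- pos
    rec <- synthetic_record(arr, times = 0, geometry = geo,
                            config = sim_config(n_cells = 300))
    f <- detect_fingers(rec, t = 0, min_size = 1)
    # oracle: components of the distance-threshold graph on outside cells
    d_out <- sqrt(rowSums(pos^2)) - geo$radius
    out <- which(d_out >= 2)
    dm <- 1 * (as.matrix(dist(pos[out, , drop = FALSE])) <= 6)
    g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    expect_equal(nrow(f), length(out))
    # same partition up to labels
    got <- split(f$cell_id, f$finger_id)
    want <- split(out, comp)
    key <- function(p) sort(unname(vapply(p, function(v)
      paste(sort(v), collapse = ","), "")))
    expect_equal(key(got), key(want))
  }
})

test_that("finger onset requires persistence and reduces correctly at 0", {
  geo <- colony_geometry("circle", 30, 0.05)
  nt <- 21
  pos <- array(0, c(nt, 30, 2))
  # from recorded index 11 (t = 10) onward, 12 cells sit far outside
  for (k in 11:nt) pos[k, 1:12, 1] <- geo$radius + 5 + (1:12)
  rec <- synthetic_record(pos, times = 0:(nt - 1), geometry = geo,
                          config = sim_config(n_cells = 30))
  expect_equal(finger_onset(rec, persistence = 5), 10)
  expect_equal(finger_onset(rec, persistence = 0), 10)
  # persistence window extending past the record: onset cannot be called
  expect_true(is.na(finger_onset(rec, persistence = 100)))
  # no fingers at all
  rec0 <- synthetic_record(array(0, c(5, 30, 2)), times = 0:4, geometry = geo,
                           config = sim_config(n_cells = 30))
  expect_true(is.na(finger_onset(rec0, persistence = 0)))
})

test_that("band speed profile is flat on homogeneous ground", {
  rec <- single_cell_run(p_photo = 1, n_steps = 80)
  prof <- band_speed_profile(rec, band = c(3, 5))
  expect_equal(nrow(prof), 3)
  expect_equal(prof$mean_speed, rep(0.1, 3), tolerance = 1e-12)
  # an empty band interval leaves only before/after strata
  prof2 <- band_speed_profile(rec, band = c(3, 2.99), cells = "all")
  expect_setequal(prof2$stratum, c("before", "after"))
})

test_that("drift splits by freeloader flag and projects on the light axis", {
  pos <- array(0, c(11, 2, 2))
  pos[, 1, 1] <- 0.1 * (0:10)              # sighted mover along +x
  rec <- synthetic_record(pos, freeloader = c(FALSE, TRUE),
                          config = sim_config(n_cells = 2, phi_ch = 0.5))
  d <- freeloader_drift(rec)
  expect_equal(d$drift_per_step[d$group == "sighted"], 0.1, tolerance = 1e-12)
  expect_equal(d$drift_per_step[d$group == "freeloader"], 0)
  # without freeloaders there is no freeloader row
  rec2 <- synthetic_record(pos, freeloader = c(FALSE, FALSE))
  expect_equal(freeloader_drift(rec2)$group, "sighted")
})

test_that("rose-plot analysis refuses coarse records", {
  sc <- small_circle(n = 20, n_steps = 100L)
  rec <- run_sim(sc, record_every = 10, seed = 3)
  expect_error(direction_histogram(rec), "record_every = 1")
})
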