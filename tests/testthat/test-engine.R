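test_that("identical seeds give bit-identical records", {
  sc <- small_circle(n = 60, n_steps = 400L)
  r1 <- run_sim(sc, seed = 21)
  r2 <- run_sim(sc, seed = 21)
  expect_identical(r1$positions, r2$positions)
  expect_identical(r1$final$state$headings, r2$final$state$headings)
  expect_identical(r1$final$slime$values, r2$final$slime$values)
  r3 <- run_sim(sc, seed = 22)
  expect_false(identical(r1$positions, r3$positions))
})

test_that("run(n) then resume(m) equals run(n + m) bit-exactly", {
  sc <- small_circle(n = 60, n_steps = 200L)
  whole <- run_sim(sc, n_steps = 200, record_every = 50, seed = 31)
  part <- run_sim(sc, n_steps = 100, record_every = 50, seed = 31)
  part <- resume(part, 100)
  expect_identical(whole$times, part$times)
  expect_identical(whole$positions, part$positions)
  expect_identical(whole$final$state$positions, part$final$state$positions)
  expect_identical(whole$final$slime$values, part$final$slime$values)
  expect_identical(whole$final$rng_state, part$final$rng_state)
})

test_that("checkpoint equivalence holds across a light-schedule switch", {
  cfg <- sim_config(n_cells = 50, n_steps = 300L, p_photo = 0.5)
  geo <- colony_geometry("circle", 50, 0.05)
  sch <- light_switch_schedule(t_switch = 150)
  whole <- run_sim(cfg, geo, sch, n_steps = 300, record_every = 50, seed = 41)
  part <- run_sim(cfg, geo, sch, n_steps = 120, record_every = 50, seed = 41)
  part <- resume(part, 180)
  expect_identical(whole$final$state$positions, part$final$state$positions)
  # the post-switch population must actually feel the rotated light
  drift <- freeloader_drift(whole)
  expect_equal(drift$group, "sighted")
})

test_that("resume with zero steps is a no-op and recording times are right", {
  sc <- small_circle(n = 40, n_steps = 100L)
  rec <- run_sim(sc, n_steps = 100, record_every = 30, seed = 51)
  expect_identical(resume(rec, 0), rec)
  expect_equal(rec$times, c(0, 30, 60, 90, 100))
  rec0 <- run_sim(sc, n_steps = 0, seed = 51)
  expect_equal(rec0$times, 0)
  expect_equal(dim(rec0$positions)[1], 1)
})

test_that("no recorded displacement ever exceeds a tenth of a radius", {
  # dense crowd so that tug forces are large and the clamp matters
  sc <- small_circle(n = 120, rho = 0.5, n_steps = 300L)
  rec <- run_sim(sc, record_every = 1, slime_every = 0, seed = 61)
  expect_lte(rec$max_disp, 0.1 + 1e-12)
  d <- sqrt(apply(rec$positions[, , 1], 2, diff)^2 +
            apply(rec$positions[, , 2], 2, diff)^2)
  expect_lte(max(d), 0.1 + 1e-12)
})

test_that("recorded headings are kept when requested", {
  sc <- small_circle(n = 30, n_steps = 50L)
  rec <- run_sim(sc, record_every = 10, record_headings = TRUE, seed = 71)
  expect_equal(dim(rec$headings), c(length(rec$times), 30))
  expect_true(all(rec$headings[-1, ] >= 0 & rec$headings[-1, ] < 2 * pi))
  td <- tidy(rec)
  expect_true("heading" %in% names(td))
})

test_that("tidy and glance expose the run as tables", {
  sc <- small_circle(n = 25, n_steps = 60L, phi_ch = 0.2)
  rec <- run_sim(sc, record_every = 20, seed = 81)
  td <- tidy(rec)
  expect_equal(nrow(td), length(rec$times) * 25)
  expect_equal(names(td), c("step", "cell_id", "x", "y", "freeloader"))
  expect_equal(sum(td$freeloader) / length(rec$times), round(0.2 * 25))
  g <- glance(rec)
  expect_equal(g$n_cells, 25)
  expect_equal(g$n_steps, 60)
  expect_lte(g$max_step_disp, 0.1 + 1e-12)
})
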