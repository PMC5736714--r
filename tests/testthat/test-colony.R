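test_that("colony extent follows from the density definition", {
  g <- colony_geometry("circle", 500, 0.05)
  expect_equal(g$radius, sqrt(500 / (0.05 * pi)), tolerance = 1e-12)
  expect_equal(g$radius, 56.419, tolerance = 1e-4)
  g2 <- colony_geometry("circle", 500, 0.2)
  expect_equal(g2$radius, 28.209, tolerance = 1e-4)
  r <- colony_geometry("rectangle", 500, 0.05, aspect = 10)
  expect_equal(r$width * r$height, 500 / 0.05, tolerance = 1e-12)
  expect_equal(r$height / r$width, 10, tolerance = 1e-12)
  expect_error(colony_geometry("circle", 500, 0), "positive")
})

test_that("the freeloader count is exact and chosen without bias", {
  cfg <- sim_config(n_cells = 500, phi_ch = 0.5)
  set.seed(1)
  col <- make_colony(cfg, colony_geometry("circle", 500, 0.05))
  expect_equal(sum(col$state$freeloader), 250)
  cfg2 <- sim_config(n_cells = 10, phi_ch = 0.25)
  set.seed(1)
  col2 <- make_colony(cfg2, colony_geometry("circle", 10, 0.05))
  expect_equal(sum(col2$state$freeloader), round(0.25 * 10))
})

test_that("initial slime is S0 exactly on in-domain sites and 0 outside", {
  cfg <- sim_config(n_cells = 20)
  geo <- colony_geometry("circle", 20, 0.05)   # radius ~11.28
  set.seed(2)
  col <- make_colony(cfg, geo)
  # brute-force oracle over a generous grid of site centres
  for (r in -15:15) for (c in -15:15) {
    inside <- (c^2 + r^2) <= geo$radius^2
    expect_equal(slime_at(col$slime, c, r), if (inside) 1000 else 0)
  }
  # rectangle case
  geor <- colony_geometry("rectangle", 20, 0.05, aspect = 4)
  set.seed(2)
  colr <- make_colony(cfg, geor)
  for (r in -18:18) for (c in -8:8) {
    inside <- abs(c) <= geor$width / 2 && abs(r) <= geor$height / 2
    expect_equal(slime_at(colr$slime, c, r), if (inside) 1000 else 0)
  }
})

test_that("initial positions are uniform over the domain", {
  cfg <- sim_config(n_cells = 10000)
  geo <- colony_geometry("rectangle", 10000, 0.05, aspect = 1)
  set.seed(3)
  col <- make_colony(cfg, geo)
  pos <- col$state$positions
  expect_true(all(in_domain <- abs(pos[, 1]) <= geo$width / 2 &
                    abs(pos[, 2]) <= geo$height / 2))
  # 5 x 5 equal-area bins
  bx <- cut(pos[, 1], breaks = seq(-geo$width / 2, geo$width / 2, length.out = 6))
  by <- cut(pos[, 2], breaks = seq(-geo$height / 2, geo$height / 2, length.out = 6))
  p <- suppressWarnings(stats::chisq.test(table(bx, by)))$p.value
  expect_gt(p, 1e-3)
  # circle: squared radius is uniform on [0, radius^2]
  geoc <- colony_geometry("circle", 10000, 0.05)
  set.seed(4)
  colc <- make_colony(cfg, geoc)
  r2 <- rowSums(colc$state$positions^2) / geoc$radius^2
  expect_true(all(r2 <= 1))
  pc <- suppressWarnings(stats::chisq.test(table(cut(r2, seq(0, 1, 0.1)))))$p.value
  expect_gt(pc, 1e-3)
})

test_that("initial headings come from a fresh heading update", {
  cfg <- sim_config(n_cells = 2000, p_photo = 1)
  set.seed(5)
  col <- make_colony(cfg, colony_geometry("circle", 2000, 0.05),
                     light_schedule(angle = 0))
  expect_true(all(col$state$headings == 0))   # p = 1: everyone aims at light
})
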