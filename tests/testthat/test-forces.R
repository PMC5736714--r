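# reference evaluation of the sigmoidal force law, written out independently
K_oracle <- function(D, R = 1, k1 = 1, k2 = 2, a = 4)
  (1 + k1 * (tanh(k2 * (D - 2 * R)) - 1)) / a

test_that("pair force anchor points match the closed form", {
  expect_identical(pair_force(2, R = 1), 0)          # zero at contact, k1 = 1
  expect_equal(pair_force(100, R = 1), 1 / 4, tolerance = 1e-12)
  expect_equal(pair_force(1, R = 1), K_oracle(1), tolerance = 1e-14)
  expect_equal(pair_force(1, R = 1), -0.2410068950189542, tolerance = 1e-12)
  # vectorized agreement on a grid, including the repulsive branch
  D <- seq(0, 10, by = 0.05)
  expect_equal(pair_force(D), K_oracle(D), tolerance = 1e-14)
})

test_that("pair force is repulsive below contact, monotone, saturating", {
  D <- seq(0, 12, by = 0.01)
  K <- pair_force(D)
  expect_true(all(K[D < 2] < 0))
  expect_true(all(diff(K) >= 0))            # non-decreasing everywhere
  expect_true(all(diff(K[D <= 5]) > 0))     # strictly so before saturation
  expect_lt(abs(K[length(K)] - 0.25), 1e-8)
  expect_error(pair_force(1, a = 0), "positive")
  expect_error(pair_force(-1), "non-negative")
})

test_that("an isolated cell has zero tug force and a unit bias force", {
  st <- cell_state(matrix(c(0, 0), 1, 2), headings = pi / 4)
  f <- net_forces(st, select_tugs(st), sim_config(n_cells = 1))
  expect_equal(f$F, matrix(0, 1, 2))
  expect_equal(sqrt(sum(f$G^2)), 1)
  expect_equal(f$G[1, ], c(cos(pi / 4), sin(pi / 4)))
})

test_that("overlapping cells with mutual tugs are pushed apart", {
  st <- cell_state(rbind(c(0, 0), c(1, 0)))   # D = 1 < 2R
  cfg <- sim_config(n_cells = 2)
  tugs <- tibble::tibble(donor = c(1L, 2L), recipient = c(2L, 1L))
  f <- net_forces(st, tugs, cfg)
  K <- pair_force(1)
  expect_lt(K, 0)
  # force on cell 1 points along -x (away from cell 2), and vice versa
  expect_equal(f$F[1, ], c(K, 0))     # K * unit(1 -> 2) with K < 0
  expect_equal(f$F[2, ], c(-K, 0))
  expect_equal(abs(f$F[1, 1]), 0.2410068950189542, tolerance = 1e-12)
})

test_that("symmetric donors cancel the transverse force component", {
  st <- cell_state(rbind(c(0, 0), c(3, 3), c(3, -3)))
  cfg <- sim_config(n_cells = 3)
  tugs <- tibble::tibble(donor = c(2L, 3L), recipient = c(1L, 1L))
  f <- net_forces(st, tugs, cfg)
  expect_equal(f$F[1, 2], 0, tolerance = 1e-14)
  expect_gt(f$F[1, 1], 0)   # both attractions pull toward +x
})

test_that("coincident centres get a finite random separation force", {
  st <- cell_state(rbind(c(1, 1), c(1, 1)))
  cfg <- sim_config(n_cells = 2)
  tugs <- tibble::tibble(donor = 1L, recipient = 2L)
  set.seed(1)
  f <- net_forces(st, tugs, cfg)
  expect_true(all(is.finite(f$F)))
  expect_equal(sqrt(sum(f$F[2, ]^2)), abs(pair_force(0)), tolerance = 1e-12)
})

test_that("tug eligibility is a hard distance threshold at 2R + A", {
  cfg <- sim_config(n_cells = 2)
  st5 <- cell_state(rbind(c(0, 0), c(5, 0)))
  st7 <- cell_state(rbind(c(0, 0), c(7, 0)))
  set.seed(2)
  expect_equal(nrow(select_tugs(st5, 1, 4, 4)), 2)  # both directions eligible
  expect_equal(nrow(select_tugs(st7, 1, 4, 4)), 0)
})

test_that("a donor with many eligible neighbours picks exactly a of them", {
  # 10 neighbours on a circle of radius 3 around a central donor
  ang <- 2 * pi * (0:9) / 10
  st <- cell_state(rbind(c(0, 0), cbind(3 * cos(ang), 3 * sin(ang))))
  set.seed(3)
  tugs <- select_tugs(st, R = 1, A = 4, a = 4)
  from_center <- tugs[tugs$donor == 1, ]
  expect_equal(nrow(from_center), 4)
  expect_equal(length(unique(from_center$recipient)), 4)
  # every donor respects the cap and never tugs itself
  counts <- table(tugs$donor)
  expect_true(all(counts <= 4))
  expect_true(all(tugs$donor != tugs$recipient))
})

test_that("tug sets are regenerated afresh each step", {
  set.seed(4)
  pos <- matrix(runif(100, 0, 15), ncol = 2)
  st <- cell_state(pos)
  t1 <- select_tugs(st)
  t2 <- select_tugs(st)
  expect_false(identical(t1, t2))
})

test_that("all selected tugs satisfy the reach constraint", {
  set.seed(5)
  for (n in c(30, 120)) {
    pos <- matrix(runif(2 * n, 0, 30), ncol = 2)
    tugs <- select_tugs(cell_state(pos))
    D <- sqrt(rowSums((pos[tugs$donor, , drop = FALSE] -
                       pos[tugs$recipient, , drop = FALSE])^2))
    expect_true(all(D <= 6))
  }
})

test_that("accelerated neighbour search equals the brute-force pair list", {
  set.seed(6)
  for (n in c(20, 80, 200)) {
    for (spread in c(8, 40, 200)) {
      pos <- matrix(runif(2 * n, 0, spread), ncol = 2)
      got <- phototaxr:::cpp_neighbor_pairs(pos, 6)
      got <- cbind(pmin(got[, 1], got[, 2]), pmax(got[, 1], got[, 2]))
      got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
      expect_equal(unname(got), unname(brute_pairs(pos, 6)))
    }
  }
})
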