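test_that("pressure on the 1-D chain matches the hand-solved system", {
  lat <- build_square_lattice(5, 1)
  g <- population_grid(lat, occupied = c(2, 3, 3, 4))
  p <- solve_pressure(g)
  expect_equal(p[2:4], c(1 / 2, 1, 1 / 2), tolerance = 1e-10)
  expect_equal(p[c(1, 5)], c(0, 0))
})

test_that("pressure vanishes at equilibrium and is non-negative", {
  lat <- build_hex_lattice(8, 8)
  g <- population_grid(lat, occupied = c(20, 21, 28, 29))
  expect_equal(as.numeric(solve_pressure(g)), rep(0, 64))
  set.seed(5)
  for (k in 1:20) {
    gr <- random_population(lat, 10, p_double = 0.5)
    expect_true(all(solve_pressure(gr) >= -1e-12))
  }
})

test_that("discrete divergence identity holds on randomized configurations", {
  lat <- build_hex_lattice(10, 10)
  set.seed(7)
  for (k in 1:100) {
    gr <- random_population(lat, sample(3:25, 1), p_double = 0.4)
    p <- solve_pressure(gr)
    s_total <- sum(gr$u == 2)
    expect_lt(abs(boundary_current_sum(gr, p) - s_total), 1e-10)
  }
})

test_that("pressure inherits the lattice point symmetry", {
  # single double-occupied voxel at the center of a symmetric hex patch
  lat <- build_hex_lattice(7, 7)
  ctr <- 25
  occ <- c(ctr, lat$adj[[ctr]])
  ids <- as.list(seq_along(occ))
  names(ids) <- occ
  ids[[as.character(ctr)]] <- c(100L, 101L)
  g <- population_grid(lat, ids)
  p <- solve_pressure(g)
  # opposite neighbors of the center see identical pressure
  nb <- lat$adj[[ctr]]
  for (j in nb) {
    opp <- nb[which.min(rowSums((lat$coords[nb, , drop = FALSE] -
      matrix(2 * lat$coords[ctr, ] - lat$coords[j, ], length(nb), 2,
             byrow = TRUE))^2))]
    expect_equal(p[j], p[opp], tolerance = 1e-10)
  }
})

test_that("movement rates convert only downhill currents between unequal voxels", {
  lat <- build_square_lattice(5, 1)
  g <- population_grid(lat, occupied = c(2, 3, 3, 4))
  p <- solve_pressure(g)
  # pure pressure conversion: all four downhill candidates at rate 1/2
  mv <- movement_rates(g, p, growth_params(keep_connected = FALSE))
  key <- paste(mv$source, mv$dest)
  expect_setequal(key, c("2 1", "3 2", "3 4", "4 5"))
  expect_equal(mv$rate, rep(1 / 2, 4))
  # equal occupancy across an edge gives no candidate even under pressure
  expect_false(any(key %in% c("2 3", "4 3")))
  # default fragmentation guard: the end-voxel moves (which would detach
  # the mover on a 1-D chain) are excluded, double-voxel moves are kept
  mvk <- movement_rates(g, p, growth_params())
  expect_setequal(paste(mvk$source, mvk$dest), c("3 2", "3 4"))
  expect_equal(mvk$rate, rep(1 / 2, 2))
  # equilibrium: no candidates at all
  g0 <- population_grid(lat, occupied = c(2, 3))
  expect_equal(nrow(movement_rates(g0, solve_pressure(g0),
                                   growth_params())), 0)
})

test_that("nutrient field solves the boundary-fed consumption problem", {
  lat <- build_hex_lattice(8, 8)
  g <- population_grid(lat, occupied = c(19, 20, 27, 28))
  # no consumption: harmonic with constant boundary value
  c0 <- nutrient_field(g, growth_params(kappa = 0, c_b = 1))
  expect_equal(c0[c(19, 20, 27, 28)], rep(1, 4))
  # single occupied voxel: one-unknown solve, c = c_b - kappa/deg
  g1 <- population_grid(lat, occupied = 28)
  deg <- length(lat$adj[[28]])
  c1 <- nutrient_field(g1, growth_params(kappa = 0.3))
  expect_equal(c1[28], 1 - 0.3 / deg, tolerance = 1e-12)
  # maximum principle: interior never exceeds the boundary value
  set.seed(9)
  for (k in 1:10) {
    gr <- random_population(lat, 15, p_double = 0.3)
    cc <- nutrient_field(gr, growth_params(kappa = 0.05))
    expect_true(all(cc <= 1 + 1e-12))
  }
})

test_that("nutrient decreases toward the interior of a compact population", {
  lat <- build_hex_lattice(13, 13)
  ctr <- 85
  d2 <- rowSums((lat$coords -
                   matrix(lat$coords[ctr, ], 169, 2, byrow = TRUE))^2)
  occ <- which(d2 <= 36.1)
  g <- population_grid(lat, occupied = occ)
  cc <- nutrient_field(g, growth_params(kappa = 0.05))
  dist <- distance_to_boundary(g)
  agg <- tapply(cc[occ], dist[occ], mean)
  expect_true(all(diff(agg[order(as.integer(names(agg)))]) <= 1e-12))
})

test_that("proliferation is gated by occupancy and nutrient threshold", {
  lat <- build_hex_lattice(8, 8)
  g <- population_grid(lat, occupied = c(19, 20, 27))
  cc <- nutrient_field(g, growth_params(kappa = 0.02))
  pr <- proliferation_rates(g, cc, growth_params(c_thr = 0, mu = 2))
  expect_equal(sort(pr$voxel), c(19, 20, 27))
  expect_equal(pr$rate, rep(2, 3))
  # threshold above the boundary concentration: nobody divides
  pr0 <- proliferation_rates(g, cc, growth_params(c_thr = 1.5))
  expect_equal(nrow(pr0), 0)
  # doubly occupied voxels never divide
  ids <- list(`19` = 1:2, `20` = 3L)
  g2 <- population_grid(lat, ids)
  cc2 <- nutrient_field(g2, growth_params())
  pr2 <- proliferation_rates(g2, cc2, growth_params(c_thr = 0))
  expect_equal(pr2$voxel, 20)
})

test_that("a compressed chain relaxes to an absorbing equilibrium", {
  lat <- build_square_lattice(7, 1)
  g <- population_grid(lat, list(`3` = 1L, `4` = c(2L, 3L), `5` = 4L))
  log <- simulate_population(g, growth_params(mu = 0), seed = 3)
  expect_true(attr(log, "equilibrium"))
  expect_true(all(log$kind == "move"))
  fin <- attr(log, "final_grid")
  expect_true(all(fin$u <= 1))
  expect_equal(sum(fin$u), 4)
  expect_equal(as.numeric(solve_pressure(fin)), rep(0, 7))
})

test_that("growth events are reproducible, conservative and logged replayably", {
  lat <- build_hex_lattice(15, 15)
  g <- population_grid(lat, occupied = 113)
  log1 <- simulate_population(g, growth_params(target_size = 40), seed = 12)
  log2 <- simulate_population(g, growth_params(target_size = 40), seed = 12)
  expect_identical(as.data.frame(log1), as.data.frame(log2))
  # population count changes only at divide events
  n_div <- sum(log1$kind == "divide")
  fin <- attr(log1, "final_grid")
  expect_equal(sum(fin$u), 1 + n_div)
  expect_equal(sum(fin$u), 40)
  # replaying the log reproduces the final grid exactly
  rep_fin <- replay_events(g, log1)
  expect_identical(rep_fin$u, fin$u)
  expect_identical(rep_fin$cells, fin$cells)
  # event-log round trip through JSON lines is exact
  path <- tempfile(fileext = ".jsonl")
  write_event_log(log1, path)
  back <- read_event_log(path)
  expect_equal(as.data.frame(back), as.data.frame(log1),
               ignore_attr = TRUE)
})
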