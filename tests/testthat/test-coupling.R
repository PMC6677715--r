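test_that("division splits molecules binomially and conserves totals exactly", {
  m <- cell_mesh_fixture()
  set.seed(31)
  parent <- distribute_counts(m, c(100, 57, 13))
  for (k in 1:50) {
    halves <- divide_counts(parent, m)
    expect_identical(cell_totals(halves$d1) + cell_totals(halves$d2),
                     cell_totals(parent))
    expect_true(all(halves$d1 >= 0) && all(halves$d2 >= 0))
  }
  # daughter share of N is Binomial(100, 1/2): mean within 3 SE of 50
  reps <- 1000
  share <- replicate(reps, cell_totals(divide_counts(parent, m)$d1)[["N"]])
  expect_lt(abs(mean(share) - 50), 3 * sqrt(25 / reps))
  # zero parent gives zero daughters
  z <- divide_counts(rdme_zero_state(m), m)
  expect_equal(sum(z$d1) + sum(z$d2), 0)
  # reporter can be withheld from the split
  nd <- divide_counts(parent, m, species = "nd")
  expect_equal(unname(cell_totals(nd$d1)[3] + cell_totals(nd$d2)[3]), 0)
})

test_that("applying events keeps grid, states and contact graph consistent", {
  p <- pathway_params()
  lat <- build_hex_lattice(7, 7)
  g <- population_grid(lat, occupied = c(24, 25, 32))
  m <- cell_mesh_fixture(10, p$omega)
  set.seed(41)
  states <- list(`1` = distribute_counts(m, c(50, 60, 0)),
                 `2` = distribute_counts(m, c(70, 10, 5)),
                 `3` = distribute_counts(m, c(20, 90, 1)))
  ts <- tissue_state(g, m, p, protrusion_spec(3.5), states)
  tot0 <- cell_totals(states[["1"]]) + cell_totals(states[["2"]]) +
    cell_totals(states[["3"]])
  # move a cell away and back: grid and molecular totals unchanged
  ev1 <- list(kind = "move", source = 24, dest = 23, cell_id = 1, time = 1)
  ev2 <- list(kind = "move", source = 23, dest = 24, cell_id = 1, time = 2)
  ts2 <- apply_event(apply_event(ts, ev1), ev2)
  expect_identical(ts2$grid$u, ts$grid$u)
  expect_identical(ts2$states, ts$states)
  # divide: population +1, tissue-wide totals conserved at the instant
  ev3 <- list(kind = "divide", source = 25, cell_id = 2, new_id = 4,
              time = 3)
  ts3 <- apply_event(ts, ev3)
  expect_equal(length(ts3$cell_ids), 4)
  tot3 <- Reduce(`+`, lapply(ts3$states, cell_totals))
  expect_identical(tot3, tot0)
  # the rebuilt contact graph matches a fresh full rebuild
  fresh <- build_population_contacts(ts3$grid, ts3$spec, p)
  expect_identical(ts3$graph$J, fresh$J)
  expect_identical(ts3$graph$P, fresh$P)
  # illegal events are rejected
  expect_error(apply_event(ts, list(kind = "move", source = 24, dest = 25,
                                    cell_id = 1, time = 1)), "illegal")
  expect_error(apply_event(ts, list(kind = "jump", source = 24, dest = 23,
                                    cell_id = 1, time = 1)), "unknown")
})

test_that("co-resident and adjacent cells are junctional contacts", {
  p <- pathway_params()
  lat <- build_hex_lattice(7, 7)
  g <- population_grid(lat, list(`24` = c(1L, 2L), `25` = 3L, `33` = 4L))
  cg <- build_population_contacts(g, protrusion_spec(3.5), p)
  ids <- attr(cg, "cell_ids")
  expect_equal(ids, 1:4)
  expect_setequal(cg$J[[1]], c(2, 3))  # voxel mate and neighbor-voxel cell
  expect_setequal(cg$J[[3]], c(1, 2))
  # cell 4 sits one ring further out: protrusional contact of cell 3, not
  # junctional of anyone
  expect_length(cg$J[[4]], 0)
  expect_equal(sqrt(sum((lat$coords[33, ] - lat$coords[25, ])^2)),
               2 * sqrt(3))
  expect_true(4 %in% cg$P[[3]])
  expect_true(3 %in% cg$P[[4]])
})

test_that("one-way replay of a growth log is bit-reproducible", {
  p <- pathway_params(omega = 100)
  lat <- build_hex_lattice(9, 9)
  g0 <- population_grid(lat, occupied = 41)
  log <- simulate_population(g0, growth_params(target_size = 6), seed = 2)
  m <- cell_mesh_fixture(7, p$omega)
  run_once <- function() {
    set.seed(77)
    init <- list(`1` = distribute_counts(m, c(40, 40, 0)))
    ts <- tissue_state(population_grid(lat, occupied = 41), m, p,
                       protrusion_spec(3.5), init)
    run_coupled(ts, log, t_end = max(log$time) + 0.5,
                times = c(0.2, max(log$time) + 0.5), seed = 123)
  }
  t1 <- run_once()
  t2 <- run_once()
  expect_identical(t1, t2)
  fin <- attr(t1, "tissue")
  expect_equal(length(fin$cell_ids), 6)
  expect_true(all(t1$N >= 0 & t1$D >= 0 & t1$R >= 0))
  # the final contact graph matches the final positions
  fresh <- build_population_contacts(fin$grid, fin$spec, p)
  expect_identical(fin$graph$J, fresh$J)
})

test_that("the coupled driver on one single-voxel cell matches the well-stirred law", {
  # reduction case: a frozen single cell with a single-voxel mesh is the
  # same process as the population Gillespie driver; compare mean N and D
  # at t = 1 over replicates
  p <- pathway_params()
  m1 <- cell_mesh_fixture(1, p$omega)
  lat1 <- build_hex_lattice(1, 1)
  reps <- 80
  nd_cpl <- matrix(0, reps, 2)
  nd_ssa <- matrix(0, reps, 2)
  for (r in seq_len(reps)) {
    ts <- tissue_state(population_grid(lat1, occupied = 1), m1, p,
                       protrusion_spec(3.5),
                       list(`1` = matrix(0L, 1, 3)))
    tr <- run_coupled(ts, NULL, t_end = 1, times = 1, seed = 5000 + r)
    nd_cpl[r, ] <- c(tr$N[1], tr$D[1])
    g1 <- contact_graph(lat1, NULL, p)
    tw <- ssa_population(rbind(c(0L, 0L, 0L)), g1, p, t_end = 1,
                         seed = 9000 + r)
    nd_ssa[r, ] <- c(tw$N[1], tw$D[1])
  }
  for (s in 1:2) {
    se <- sqrt(var(nd_cpl[, s]) / reps + var(nd_ssa[, s]) / reps)
    expect_lt(abs(mean(nd_cpl[, s]) - mean(nd_ssa[, s])), 3 * se)
  }
})

test_that("moves and graph rebuilds never change tissue-wide molecule totals", {
  p <- pathway_params(omega = 50)
  lat <- build_hex_lattice(9, 9)
  g0 <- population_grid(lat, occupied = 41)
  log <- simulate_population(g0, growth_params(target_size = 5), seed = 6)
  moves_only <- log[log$kind == "move", , drop = FALSE]
  m <- cell_mesh_fixture(7, p$omega)
  set.seed(13)
  init <- list(`1` = distribute_counts(m, c(30, 20, 10)))
  ts <- tissue_state(population_grid(lat, occupied = 41), m, p,
                     protrusion_spec(3.5), init)
  # apply the division events too, tracking totals across each event
  tot <- cell_totals(init[[1]])
  for (k in seq_len(nrow(log))) {
    before <- Reduce(`+`, lapply(ts$states, cell_totals))
    ts <- apply_event(ts, log[k, ])
    after <- Reduce(`+`, lapply(ts$states, cell_totals))
    expect_identical(after, before)
  }
})
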