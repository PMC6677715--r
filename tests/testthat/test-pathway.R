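test_that("ndr_rhs reproduces the written-out model equations", {
  p <- pathway_params()
  # zero state: only the production terms survive
  expect_equal(as.numeric(ndr_rhs(rbind(c(0, 0, 0)), rbind(c(0, 0, 0)), p)),
               c(100, 500, 0))
  # decay/cis terms only (production off, all constants 1)
  p0 <- pathway_params(beta_n = 0, beta_d = 0, beta_r = 0,
                       k_t = 1, k_c = 1, k_rs = 1)
  expect_equal(as.numeric(ndr_rhs(rbind(c(1, 1, 1)), rbind(c(0, 0, 0)), p0)),
               c(-2, -2, -1))
  # signal terms enter with the right constants
  d1 <- ndr_rhs(rbind(c(1, 1, 0)), rbind(c(4, 0, 6)), p)
  expect_equal(unname(d1[1, 1]), 100 - 4 * 1 / 2 - 1 * 1 / 0.5 - 1)
  expect_equal(unname(d1[1, 2]), 500 - 1 * 6 / 2 - 1 * 1 / 0.5 - 1)
  expect_error(ndr_rhs(rbind(c(-1, 0, 0)), rbind(c(0, 0, 0)), p),
               "non-negative")
})

test_that("isolated-cell fixed point from the root-finding oracle is a zero of the rhs", {
  p <- pathway_params()
  fp <- ndr_isolated_fixed_point(p)
  expect_equal(as.numeric(ndr_rhs(rbind(fp), rbind(c(0, 0, 0)), p)),
               c(0, 0, 0), tolerance = 1e-9)
  # frozen regression values for the baseline parameters
  expect_equal(unname(fp["n"]), 0.12480505, tolerance = 1e-6)
  expect_equal(unname(fp["d"]), 400.124805, tolerance = 1e-6)
  # the ODE relaxes onto it from the origin
  sol <- ndr_ode(rbind(c(0, 0, 0)), NULL, p, times = c(0, 50))
  expect_equal(unname(sol[2, 2]), unname(fp["n"]), tolerance = 1e-4)
  expect_equal(unname(sol[2, 3]), unname(fp["d"]), tolerance = 1e-4)
})

test_that("collier_rhs implements the two-species feedback form", {
  p <- pathway_params()
  zero <- function(x) 0 * x
  expect_equal(as.numeric(collier_rhs(rbind(c(2, 3)), 0, zero, zero, p)),
               c(-2, -3))
  # fixed-point identity: n = f(<d>), d = g(n) gives zero derivative
  f <- function(x) x^2 / (0.01 + x^2)
  g <- function(x) 1 / (1 + 100 * x^2)
  dbar <- 0.3
  n0 <- f(dbar); d0 <- g(n0)
  expect_equal(as.numeric(collier_rhs(rbind(c(n0, d0)), dbar, f, g, p)),
               c(0, 0))
  # the constant scales only the Delta equation
  p2 <- pathway_params(collier_const = 3)
  out <- collier_rhs(rbind(c(0.1, 0.2)), 0.5, f, g, p2)
  expect_equal(unname(out[1, 2]), 3 * (g(0.1) - 0.2))
})

test_that("ndr_propensities matches the transition rates channel by channel", {
  p <- pathway_params()
  a <- ndr_propensities(c(0, 0, 0), c(0, 0, 0), p)
  expect_equal(unname(a), c(100 * 400, 500 * 400, 0, 0, 0, 0, 0, 0, 0))
  # cis annihilation arithmetic
  a2 <- ndr_propensities(c(2, 3, 0), c(0, 0, 0), p)
  expect_equal(unname(a2[["cis_ND"]]), 2 * 3 / (0.5 * 400))
  # reporter repression at R = Omega halves Delta production
  a3 <- ndr_propensities(c(0, 0, 400), c(0, 0, 0), p)
  expect_equal(unname(a3[["prod_D"]]), 500 * 400 / 2)
  # signal-mediated degradations
  a4 <- ndr_propensities(c(10, 20, 0), c(8, 0, 6), p)
  expect_equal(unname(a4[["deg_N_trans"]]), 10 * 8 / (2 * 400))
  expect_equal(unname(a4[["deg_D_trans"]]), 20 * 6 / (2 * 400))
  expect_error(ndr_propensities(c(-1, 0, 0), c(0, 0, 0), p), "non-negative")
})

test_that("propensities are non-negative over randomized states", {
  p <- pathway_params()
  set.seed(11)
  for (k in 1:200) {
    cnt <- rpois(3, c(200, 800, 5e4))
    sig <- runif(3, 0, 1e5)
    expect_true(all(ndr_propensities(cnt, sig, p) >= 0))
  }
})

test_that("adaptive_chunk follows the norm-ratio rule with bounds", {
  p <- pathway_params()
  expect_equal(adaptive_chunk(c(1, 0), c(2, 0), p), 0.025)
  # equilibrium: capped at dtau_max
  expect_equal(adaptive_chunk(c(1, 1), c(0, 0), p), p$dtau_max)
  # zero state with non-zero drift: floored at dtau_min
  expect_equal(adaptive_chunk(c(0, 0), c(5, 0), p), p$dtau_min)
  # both zero: treated as equilibrium
  expect_equal(adaptive_chunk(c(0, 0), c(0, 0), p), p$dtau_max)
  # invariance under joint rescaling (f linear in x)
  x <- c(0.3, 0.7, 0.1)
  fx <- 2 * x
  expect_equal(adaptive_chunk(10 * x, 10 * fx, p), adaptive_chunk(x, fx, p))
})

test_that("ssa_population is seed-reproducible and respects disabled channels", {
  p <- pathway_params()
  lat <- build_hex_lattice(3, 3)
  g <- contact_graph(lat, protrusion_spec(3.5), p)
  init <- random_initial_counts(9, p, seed = 5)
  t1 <- ssa_population(init, g, p, t_end = 0.5, seed = 99)
  t2 <- ssa_population(init, g, p, t_end = 0.5, seed = 99)
  expect_identical(t1, t2)
  # all channels off: flat trajectory
  t3 <- ssa_population(init, g, p, t_end = 0.5, seed = 1,
                       channels = rep(FALSE, 9))
  expect_identical(matrix(c(t3$N, t3$D, t3$R), ncol = 3),
                   matrix(c(init[, 1], init[, 2], init[, 3]), ncol = 3))
  expect_error(ssa_population(init, g, p, t_end = -1), "non-negative")
})

test_that("stochastic means approach the deterministic solution as volume grows", {
  # isolated cell, short transient from the origin; one moderate volume:
  # the mean over replicates tracks the ODE within Monte-Carlo error
  # (the full three-volume trend is exercised in the acceptance suite)
  p <- pathway_params(omega = 4000)
  lat1 <- build_hex_lattice(1, 1)
  g1 <- contact_graph(lat1, NULL, p)
  times <- c(0.1, 0.2)
  reps <- 60
  acc <- matrix(0, length(times), 3)
  for (r in seq_len(reps)) {
    tr <- ssa_population(rbind(c(0L, 0L, 0L)), g1, p, t_end = 0.2,
                         seed = 1000 + r, times = times)
    acc <- acc + as.matrix(tr[, c("N", "D", "R")]) / p$omega
  }
  acc <- acc / reps
  sol <- ndr_ode(rbind(c(0, 0, 0)), NULL, p, times = c(0, times))
  ode_nd <- sol[-1, 2:3]
  rel <- abs(acc[, 1:2] - ode_nd) / max(abs(ode_nd))
  expect_lt(max(rel), 0.02)
})
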