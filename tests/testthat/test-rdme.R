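test_that("the mesh fixture is a connected dual mesh with the right volume", {
  m <- cell_mesh_fixture()
  expect_gte(m$n_voxels, 30)
  expect_lte(m$n_voxels, 50)
  expect_equal(sum(m$volumes), 400)
  expect_true(all(m$volumes > 0))
  expect_true(tissuessa:::mesh_connected(m))
  # single-voxel degenerate case: the well-stirred model
  m1 <- cell_mesh_fixture(1, 400)
  expect_equal(m1$n_voxels, 1)
  expect_equal(m1$volumes, 400)
  # deterministic construction
  m2 <- cell_mesh_fixture()
  expect_identical(m$volumes, m2$volumes)
  expect_identical(m$edges, m2$edges)
  expect_error(cell_mesh_fixture(0), ">= 1")
})

test_that("diffusion jump rates follow the finite-volume e/d over V scaling", {
  two <- cell_mesh(volumes = c(2, 1),
                   edges = data.frame(i = 1, j = 2, e_over_d = 1))
  Q <- diffusion_jump_rates(two, 1)
  expect_equal(Q[1, 2], 1 / 2)
  expect_equal(Q[2, 1], 1)
  expect_equal(as.numeric(Matrix::rowSums(Q)), c(0, 0))
  expect_equal(as.matrix(diffusion_jump_rates(two, 0)),
               matrix(0, 2, 2), ignore_attr = TRUE)
  # rows scale as 1/V: scaling all volumes by c scales all rates by 1/c
  m <- cell_mesh_fixture()
  m3 <- cell_mesh(3 * m$volumes, m$edges)
  Q1 <- diffusion_jump_rates(m, 0.7)
  Q3 <- diffusion_jump_rates(m3, 0.7)
  expect_equal(as.matrix(Q3), as.matrix(Q1) / 3, tolerance = 1e-12)
  expect_error(diffusion_jump_rates(m, -1), "non-negative")
})

test_that("bimolecular propensity scales inversely with the compartment volume", {
  # the per-voxel rule substitutes V_i for Omega: halving the volume at
  # fixed counts doubles the N+D annihilation propensity
  a_full <- ndr_propensities(c(10, 20, 0), c(0, 0, 0),
                             pathway_params(omega = 400))
  a_half <- ndr_propensities(c(10, 20, 0), c(0, 0, 0),
                             pathway_params(omega = 200))
  expect_equal(unname(a_half[["cis_ND"]]), 2 * unname(a_full[["cis_ND"]]))
})

test_that("diffusion-only dynamics conserve every species exactly", {
  m <- cell_mesh_fixture()
  set.seed(21)
  st <- distribute_counts(m, c(1000, 400, 50))
  out <- nsm(m, st, pathway_params(), c(0, 0, 0), t_end = 10, seed = 4,
             channels = rep(FALSE, 9))
  expect_identical(cell_totals(out), cell_totals(st))
  expect_true(all(out >= 0))
})

test_that("stationary voxel occupancy is proportional to voxel volume", {
  # two-voxel chain with volume ratio 2: detailed balance gives mean
  # occupancy ratio V1/V2 = 2
  two <- cell_mesh(volumes = c(2, 1),
                   edges = data.frame(i = 1, j = 2, e_over_d = 1))
  ntot <- 300L
  set.seed(8)
  st <- matrix(c(200L, 100L, 0L, 0L, 0L, 0L), 2, 3)
  K <- 1500
  occ1 <- numeric(K)
  for (k in seq_len(K)) {
    st <- nsm(two, st, pathway_params(), c(0, 0, 0), t_end = 2,
              channels = rep(FALSE, 9), gamma = 1)
    occ1[k] <- st[1, 1]
  }
  frac <- mean(occ1) / ntot
  # stationary: each molecule independently in voxel 1 w.p. V1/(V1+V2)=2/3;
  # samples 2 time units apart are nearly independent (relaxation rate 1.5)
  se <- sqrt((2 / 3) * (1 / 3) / ntot / K)
  expect_lt(abs(frac - 2 / 3), 3 * se)
  expect_equal(mean(occ1) / (ntot - mean(occ1)), 2, tolerance = 0.05)
})

test_that("the NSM agrees with a plain direct-method oracle on a 3-voxel toy", {
  # production + decay of N with diffusion; compare per-voxel mean N at a
  # fixed time over replicates against an independent R implementation
  vols <- c(3, 2, 1)
  edges <- data.frame(i = c(1, 2), j = c(2, 3), e_over_d = c(1, 1))
  toy <- cell_mesh(vols, edges)
  p <- pathway_params(beta_n = 2, beta_d = 0, beta_r = 0, omega = sum(vols))
  ch <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  qr <- as.matrix(diffusion_jump_rates(toy, 0.5))
  diag(qr) <- 0
  reps <- 300
  m_nsm <- matrix(0, reps, 3)
  m_ora <- matrix(0, reps, 3)
  set.seed(17)
  for (r in seq_len(reps)) {
    out <- nsm(toy, matrix(0L, 3, 3), p, c(0, 0, 0), t_end = 3,
               channels = ch, gamma = 0.5)
    m_nsm[r, ] <- out[, 1]
    m_ora[r, ] <- oracle_rdme_direct(vols, qr, beta_n = 2, t_end = 3,
                                     init = c(0L, 0L, 0L))
  }
  for (v in 1:3) {
    se <- sqrt(var(m_nsm[, v]) / reps + var(m_ora[, v]) / reps)
    expect_lt(abs(mean(m_nsm[, v]) - mean(m_ora[, v])), 3 * se)
  }
})

test_that("cell totals sum voxels and are invariant under diffusion", {
  expect_equal(unname(cell_totals(rbind(c(0, 0, 0)))), c(0, 0, 0))
  m <- cell_mesh_fixture()
  one_each <- matrix(0L, m$n_voxels, 3)
  one_each[, 2] <- 1L
  expect_equal(unname(cell_totals(one_each)[2]), m$n_voxels)
  set.seed(2)
  st <- distribute_counts(m, c(120, 80, 40))
  moved <- nsm(m, st, pathway_params(), c(0, 0, 0), t_end = 1, seed = 9,
               channels = rep(FALSE, 9))
  expect_identical(cell_totals(moved), cell_totals(st))
})

test_that("the NSM is reproducible for a fixed seed and validates input", {
  m <- cell_mesh_fixture()
  set.seed(1)
  st <- distribute_counts(m, c(100, 100, 0))
  a <- nsm(m, st, pathway_params(), c(0, 0, 0), t_end = 0.5, seed = 42)
  b <- nsm(m, st, pathway_params(), c(0, 0, 0), t_end = 0.5, seed = 42)
  expect_identical(a, b)
  expect_error(nsm(m, st, pathway_params(), c(0, 0, 0), t_end = -1),
               "non-negative")
  expect_error(nsm(m, st - 200L, pathway_params(), c(0, 0, 0), t_end = 1),
               "negative")
})

test_that("mesh export tables round-trip the geometry", {
  m <- cell_mesh_fixture()
  tabs <- mesh_tables(m)
  expect_equal(nrow(tabs$voxels), m$n_voxels)
  expect_equal(sum(tabs$voxels$volume), 400)
  expect_identical(tabs$edges, m$edges)
})
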