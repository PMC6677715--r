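# Independent oracles used by the tests. These deliberately avoid the code
# paths they are checking: plain-R Gillespie loops, root finders on the
# written-out equations, and brute-force graph enumeration.

# Isolated-cell fixed point of the three-species pathway ODEs (signals = 0):
# r' = -r forces r* = 0, leaving two algebraic equations solved by uniroot
# on n after eliminating d.
ndr_isolated_fixed_point <- function(params) {
  f <- function(n) {
    # d from the d-equation at r = 0: d (1 + n/k_c) = beta_d
    d <- params$beta_d / (1 + n / params$k_c)
    params$beta_n - d * n / params$k_c - n
  }
  n_star <- uniroot(f, c(1e-12, params$beta_n), tol = 1e-14)$root
  d_star <- params$beta_d / (1 + n_star / params$k_c)
  c(n = n_star, d = d_star, r = 0)
}

# Plain-R direct-method SSA over a small voxelized system: production and
# linear decay of one species (N) plus diffusion, the reference process for
# the Next Subvolume Method equivalence check.
oracle_rdme_direct <- function(volumes, qrates, beta_n, t_end, init) {
  nv <- length(volumes)
  x <- init
  t <- 0
  repeat {
    a_prod <- beta_n * volumes
    a_dec <- x
    a_diff <- qrates * x            # matrix: per-capita rate * counts
    a0 <- sum(a_prod) + sum(a_dec) + sum(a_diff)
    t <- t + rexp(1, a0)
    if (t > t_end) return(x)
    r <- runif(1) * a0
    if (r < sum(a_prod)) {
      i <- findInterval(r, cumsum(a_prod), left.open = TRUE) + 1L
      x[i] <- x[i] + 1L
    } else if (r < sum(a_prod) + sum(a_dec)) {
      r2 <- r - sum(a_prod)
      i <- findInterval(r2, cumsum(a_dec), left.open = TRUE) + 1L
      x[i] <- x[i] - 1L
    } else {
      r3 <- r - sum(a_prod) - sum(a_dec)
      flat <- as.numeric(t(a_diff))
      k <- findInterval(r3, cumsum(flat), left.open = TRUE) + 1L
      i <- (k - 1L) %/% nv + 1L
      j <- (k - 1L) %% nv + 1L
      x[i] <- x[i] - 1L
      x[j] <- x[j] + 1L
    }
  }
}

# Brute-force protrusional contact enumeration straight from the geometric
# definition, independent of the package's vectorized implementation.
oracle_protrusions <- function(coords, l, directions, width) {
  n <- nrow(coords)
  iso <- abs(width - 2 * pi) < 1e-12
  reach <- function(i, j) {
    v <- coords[j, ] - coords[i, ]
    d <- sqrt(sum(v^2))
    if (d <= 2 + 1e-9 || d > l + 1e-9) return(FALSE)
    if (iso) return(TRUE)
    phi <- atan2(v[2], v[1])
    any(vapply(directions, function(th) {
      dd <- abs((phi - th + pi) %% (2 * pi) - pi)
      dd <= width / 2 + 1e-9
    }, logical(1)))
  }
  P <- replicate(n, integer(0), simplify = FALSE)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && reach(i, j) && reach(j, i)) P[[i]] <- c(P[[i]], j)
  }
  P
}

# discrete divergence: sum of boundary currents of a solved pressure field
boundary_current_sum <- function(grid, p) {
  sets <- attr(p, "sets")
  tot <- 0
  for (i in sets$interior) {
    for (j in grid$lattice$adj[[i]]) {
      if (j %in% sets$boundary) tot <- tot + (p[i] - 0)
    }
  }
  tot
}

# random population on a lattice with guaranteed occupied set
random_population <- function(lattice, n_occ, p_double = 0.3) {
  n <- nrow(lattice$coords)
  occ <- sample.int(n, n_occ)
  ids <- list()
  nid <- 1L
  for (v in occ) {
    k <- 1L + rbinom(1, 1, p_double)
    ids[[as.character(v)]] <- nid:(nid + k - 1L)
    nid <- nid + k
  }
  population_grid(lattice, ids)
}

ensemble_sd_of_mean <- function(x) sd(x) / sqrt(length(x))
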