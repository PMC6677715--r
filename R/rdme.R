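#' Single-cell computational mesh
#'
#' Constructor for the dual-mesh discretization of one cell: voxel volumes,
#' voxel centroids, and an undirected edge list with the geometric ratios
#' e_ij/d_ij (shared edge length over centroid distance) that define the
#' finite-volume discrete Laplacian. The mesh graph must be connected and
#' all volumes positive.
#'
#' @param volumes positive numeric vector of voxel volumes.
#' @param edges data frame with columns \code{i}, \code{j},
#'   \code{e_over_d} (one row per undirected edge, \code{i < j}).
#' @param centroids optional n x 2 matrix of voxel centroids.
#' @return An object of class \code{"cell_mesh"}.
#' @export
cell_mesh <- function(volumes, edges, centroids = NULL) {
  nv <- length(volumes)
  if (nv < 1 || any(!is.finite(volumes)) || any(volumes <= 0))
    stop("cell_mesh: volumes must be positive", call. = FALSE)
  if (nv > 1) {
    if (!all(c("i", "j", "e_over_d") %in% names(edges)))
      stop("cell_mesh: edges need columns i, j, e_over_d", call. = FALSE)
    if (any(edges$i == edges$j) || any(edges$e_over_d <= 0))
      stop("cell_mesh: invalid edges", call. = FALSE)
  } else {
    edges <- data.frame(i = integer(0), j = integer(0),
                        e_over_d = numeric(0))
  }
  if (is.null(centroids)) centroids <- matrix(0, nv, 2)
  m <- structure(list(n_voxels = nv, volumes = volumes, edges = edges,
                      centroids = centroids),
                 class = "cell_mesh")
  if (!mesh_connected(m))
    stop("cell_mesh: mesh graph is not connected", call. = FALSE)
  m
}

mesh_connected <- function(mesh) {
  nv <- mesh$n_voxels
  if (nv == 1L) return(TRUE)
  adj <- mesh_adjacency(mesh)
  seen <- logical(nv)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

mesh_adjacency <- function(mesh) {
  nv <- mesh$n_voxels
  adj <- replicate(nv, integer(0), simplify = FALSE)
  for (k in seq_len(nrow(mesh$edges))) {
    i <- mesh$edges$i[k]; j <- mesh$edges$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("cell mesh: %d voxels, %d edges, total volume %g\n",
              x$n_voxels, nrow(x$edges), sum(x$volumes)))
  invisible(x)
}

#' Deterministic single-cell mesh fixture
#'
#' Builds the standard dual mesh of a disc-shaped cell: a central voxel
#' surrounded by concentric rings of annular-sector voxels (ring k holds 6k
#' voxels), giving voxel counts 1, 7, 19, 37, 61, ... The innermost region
#' (about 40\% of the cell radius) corresponds to the nucleus; the
#' distinction is geometric only, all reactions run in all voxels. Voxel
#' volumes are scaled so they sum exactly to \code{omega}; the e/d ratios
#' come from the actual sector geometry and are scale-invariant. The
#' construction is fully deterministic, so tests and trajectories are
#' reproducible.
#'
#' @param n_voxels_target requested voxel count (>= 1); the nearest
#'   achievable ring total is used (the default 40 gives 37 voxels).
#' @param omega total cell volume.
#' @return A \code{"cell_mesh"}.
#' @examples
#' m <- cell_mesh_fixture()
#' m$n_voxels       # 37
#' sum(m$volumes)   # 400
#' @export
cell_mesh_fixture <- function(n_voxels_target = 40, omega = 400) {
  if (n_voxels_target < 1) stop("n_voxels_target must be >= 1",
                                call. = FALSE)
  if (n_voxels_target == 1)
    return(cell_mesh(omega, NULL, matrix(0, 1, 2)))
  # layers: center + rings of 6k voxels; total 1 + 3 M (M - 1) for M layers
  totals <- 1 + 3 * (1:12) * (0:11)
  M <- which.min(abs(totals - n_voxels_target))
  nk <- c(1L, 6L * seq_len(M - 1L))
  bounds <- seq(0, 1, length.out = M + 1L)
  nv <- sum(nk)
  vol <- numeric(nv)
  cx <- numeric(nv); cy <- numeric(nv)
  layer <- integer(nv); sector <- integer(nv)
  id <- 0L
  for (j in seq_len(M)) {
    b0 <- bounds[j]; b1 <- bounds[j + 1L]
    rbar <- if (j == 1L) 0 else (2 / 3) * (b1^3 - b0^3) / (b1^2 - b0^2)
    for (l in seq_len(nk[j])) {
      id <- id + 1L
      phi <- 2 * pi * (l - 0.5) / nk[j]
      vol[id] <- pi * (b1^2 - b0^2) / nk[j]
      cx[id] <- rbar * cos(phi); cy[id] <- rbar * sin(phi)
      layer[id] <- j; sector[id] <- l
    }
  }
  vox_id <- function(j, l) {
    base <- if (j == 1L) 0L else sum(nk[seq_len(j - 1L)])
    base + ((l - 1L) %% nk[j]) + 1L
  }
  ei <- integer(0); ej <- integer(0); eod <- numeric(0)
  add_edge <- function(i, j, e, d) {
    ei <<- c(ei, min(i, j)); ej <<- c(ej, max(i, j)); eod <<- c(eod, e / d)
  }
  for (j in seq_len(M)) {
    b0 <- bounds[j]; b1 <- bounds[j + 1L]
    # edges between consecutive sectors of the same ring
    if (nk[j] > 1L) {
      for (l in seq_len(nk[j])) {
        i1 <- vox_id(j, l); i2 <- vox_id(j, l + 1L)
        d <- sqrt((cx[i1] - cx[i2])^2 + (cy[i1] - cy[i2])^2)
        add_edge(i1, i2, b1 - b0, d)
      }
    }
    # edges to the next ring: angular-interval overlaps across radius b1
    if (j < M) {
      for (l in seq_len(nk[j])) {
        a0 <- 2 * pi * (l - 1) / nk[j]; a1 <- 2 * pi * l / nk[j]
        for (l2 in seq_len(nk[j + 1L])) {
          c0 <- 2 * pi * (l2 - 1) / nk[j + 1L]
          c1 <- 2 * pi * l2 / nk[j + 1L]
          ov <- min(a1, c1) - max(a0, c0)
          if (ov > 1e-12) {
            i1 <- vox_id(j, l); i2 <- vox_id(j + 1L, l2)
            d <- sqrt((cx[i1] - cx[i2])^2 + (cy[i1] - cy[i2])^2)
            add_edge(i1, i2, b1 * ov, d)
          }
        }
      }
    }
  }
  edges <- unique(data.frame(i = ei, j = ej, e_over_d = eod))
  vol <- vol * (omega / sum(vol))
  m <- cell_mesh(vol, edges, cbind(cx, cy))
  m$layer <- layer
  m$nucleus <- layer <= max(1L, floor(0.4 * M))
  m
}

#' Diffusion jump-rate matrix
#'
#' The mesoscopic diffusion rate of one molecule jumping from voxel i to a
#' mesh neighbor j is \code{q_ij = gamma * (e_ij/d_ij) / V_i}, the
#' finite-volume-consistent discretization of the Laplacian; the default
#' diffusion constant in the pathway model is \code{1/Omega} for all three
#' species.
#'
#' @param mesh a \code{"cell_mesh"}.
#' @param gamma scalar diffusion constant (>= 0).
#' @return Sparse matrix (dgCMatrix) with off-diagonal jump rates and
#'   diagonal entries minus the row sums (zero row sums overall).
#' @examples
#' m <- cell_mesh_fixture()
#' Q <- diffusion_jump_rates(m, 1 / 400)
#' max(abs(Matrix::rowSums(Q)))  # 0
#' @export
diffusion_jump_rates <- function(mesh, gamma) {
  stopifnot(inherits(mesh, "cell_mesh"))
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma < 0)
    stop("gamma must be a single non-negative number", call. = FALSE)
  nv <- mesh$n_voxels
  e <- mesh$edges
  i <- c(e$i, e$j); j <- c(e$j, e$i)
  x <- gamma * c(e$e_over_d, e$e_over_d) / mesh$volumes[i]
  Q <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nv, nv))
  Matrix::diag(Q) <- -Matrix::rowSums(Q)
  Q
}

# CSR arrays (0-based) of per-molecule jump rates for the NSM kernel
mesh_csr <- function(mesh, gamma) {
  nv <- mesh$n_voxels
  e <- mesh$edges
  i <- c(e$i, e$j); j <- c(e$j, e$i)
  r <- gamma * c(e$e_over_d, e$e_over_d) / mesh$volumes[i]
  o <- order(i, j)
  i <- i[o]; j <- j[o]; r <- r[o]
  ptr <- c(0L, cumsum(tabulate(i, nbins = nv)))
  list(eptr = as.integer(ptr), enbr = as.integer(j - 1L), erate = r)
}

#' Zero molecular state on a mesh
#'
#' @param mesh a \code{"cell_mesh"}.
#' @return nv x 3 integer matrix of zeros with columns N, D, R.
#' @export
rdme_zero_state <- function(mesh) {
  matrix(0L, mesh$n_voxels, 3, dimnames = list(NULL, c("N", "D", "R")))
}

#' Distribute whole-cell totals onto mesh voxels
#'
#' Places per-species totals onto the voxels of a mesh, each molecule
#' independently in a voxel chosen with probability proportional to voxel
#' volume (the diffusive stationary distribution).
#'
#' @param mesh a \code{"cell_mesh"}.
#' @param totals length-3 vector of per-species totals (N, D, R).
#' @return nv x 3 integer state matrix.
#' @export
distribute_counts <- function(mesh, totals) {
  nv <- mesh$n_voxels
  prob <- mesh$volumes / sum(mesh$volumes)
  st <- vapply(seq_len(3), function(s) {
    tt <- as.integer(totals[s])
    if (tt == 0L) integer(nv)
    else as.integer(stats::rmultinom(1, tt, prob))
  }, integer(nv))
  if (!is.matrix(st)) st <- matrix(st, nv, 3)
  colnames(st) <- c("N", "D", "R")
  st
}

#' Next Subvolume Method on one cell
#'
#' Exact stochastic simulation of the reaction-diffusion process on a
#' single cell's mesh over \code{[0, t_end)} with frozen per-cell signals:
#' all nine pathway reactions run in every voxel (with the voxel volume
#' replacing the system volume in the production and bimolecular scalings)
#' and diffusion is a first-order jump between mesh neighbors. The sampler
#' keeps per-voxel next-event times in an indexed binary heap (ties broken
#' by voxel index) and updates only the affected voxel(s) per event.
#'
#' @param mesh a \code{"cell_mesh"}.
#' @param initial nv x 3 integer state matrix.
#' @param params a \code{"pathway_params"}.
#' @param signals length-3 vector (d_in, d_out, n_in), count units, frozen
#'   for the whole call.
#' @param t_end horizon (>= 0).
#' @param seed integer seed; \code{NULL} draws one from the R stream.
#' @param channels logical vector of length 9 enabling reaction channels.
#' @param gamma diffusion constant; default \code{1/omega}.
#' @return nv x 3 integer state matrix at \code{t_end}.
#' @examples
#' m <- cell_mesh_fixture()
#' st <- nsm(m, rdme_zero_state(m), pathway_params(), c(0, 0, 0),
#'           t_end = 0.1, seed = 1)
#' @export
nsm <- function(mesh, initial, params = pathway_params(), signals,
                t_end, seed = NULL, channels = rep(TRUE, 9),
                gamma = 1 / params$omega) {
  stopifnot(inherits(mesh, "cell_mesh"))
  if (t_end < 0) stop("t_end must be non-negative", call. = FALSE)
  initial <- matrix(as.integer(initial), mesh$n_voxels, 3)
  if (any(initial < 0)) stop("negative counts", call. = FALSE)
  if (is.null(seed)) seed <- draw_seed()
  csr <- mesh_csr(mesh, gamma)
  st <- nsm_cpp(initial, mesh$volumes, csr$eptr, csr$enbr, csr$erate,
                params_vec(params), as.integer(channels),
                as.numeric(signals), t_end, seed)
  colnames(st) <- c("N", "D", "R")
  st
}

#' Whole-cell molecule totals
#'
#' @param state nv x 3 per-voxel state matrix.
#' @return Named length-3 vector (N, D, R) of per-species totals.
#' @examples
#' cell_totals(rbind(c(1, 0, 2), c(3, 1, 0)))
#' @export
cell_totals <- function(state) {
  state <- rbind(state)
  out <- colSums(state)
  names(out) <- c("N", "D", "R")
  out
}

#' Export a mesh as plain tables
#'
#' @param mesh a \code{"cell_mesh"}.
#' @return A list with \code{voxels} (id, x, y, volume) and \code{edges}
#'   (i, j, e_over_d) data frames.
#' @export
mesh_tables <- function(mesh) {
  list(voxels = data.frame(id = seq_len(mesh$n_voxels),
                           x = mesh$centroids[, 1],
                           y = mesh$centroids[, 2],
                           volume = mesh$volumes),
       edges = mesh$edges)
}
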