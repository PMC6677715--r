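#' Cell-population occupancy grid
#'
#' The population layer state: a lattice whose voxels hold 0, 1 or 2 cells
#' (2 being the carrying capacity that sources pressure), together with the
#' identities of the cells in each voxel. The populated set
#' \code{Omega_h = \{i : u_i > 0\}} and its discrete boundary (unpopulated
#' voxels sharing an edge with it) are derived on demand.
#'
#' @param lattice a \code{"lattice"}.
#' @param occupied integer vector of voxel indices that start with one cell
#'   each, or a named list \code{voxel -> cell ids}.
#' @return An object of class \code{"population_grid"}: lattice, occupancy
#'   vector \code{u}, per-voxel cell-id lists \code{cells}, and
#'   \code{next_id}.
#' @examples
#' lat <- build_hex_lattice(9, 9)
#' g <- population_grid(lat, occupied = 41)  # one founder cell
#' @export
population_grid <- function(lattice, occupied) {
  stopifnot(inherits(lattice, "lattice"))
  n <- nrow(lattice$coords)
  cells <- replicate(n, integer(0), simplify = FALSE)
  if (is.list(occupied)) {
    vox <- as.integer(names(occupied))
    for (k in seq_along(vox)) cells[[vox[k]]] <- as.integer(occupied[[k]])
  } else {
    occupied <- as.integer(occupied)
    for (k in seq_along(occupied))
      cells[[occupied[k]]] <- c(cells[[occupied[k]]], k)
  }
  u <- lengths(cells)
  if (any(u > 2))
    stop("population_grid: occupancy above the carrying capacity of 2",
         call. = FALSE)
  ids <- unlist(cells, use.names = FALSE)
  if (anyDuplicated(ids))
    stop("population_grid: duplicated cell ids", call. = FALSE)
  structure(list(lattice = lattice, u = as.integer(u), cells = cells,
                 next_id = if (length(ids)) max(ids) + 1L else 1L),
            class = "population_grid")
}

#' @export
print.population_grid <- function(x, ...) {
  cat(sprintf("population grid: %d cells in %d of %d voxels (max occupancy %d)\n",
              sum(x$u), sum(x$u > 0), length(x$u), max(x$u)))
  invisible(x)
}

#' Populated set and discrete boundary
#'
#' @param grid a \code{"population_grid"}.
#' @return A list with \code{interior} (indices with \code{u > 0}) and
#'   \code{boundary} (empty voxels sharing a lattice edge with the
#'   interior).
#' @export
population_sets <- function(grid) {
  occ <- which(grid$u > 0L)
  nb <- unique(unlist(grid$lattice$adj[occ], use.names = FALSE))
  list(interior = occ, boundary = setdiff(nb, occ))
}

# Laplacian system over the populated set with Dirichlet rows eliminated.
# Returns the SPD matrix A = D - Adj restricted to interior unknowns plus
# the count of boundary (Dirichlet) neighbors of each unknown.
population_system <- function(grid) {
  sets <- population_sets(grid)
  occ <- sets$interior
  if (!length(occ)) stop("empty population", call. = FALSE)
  if (!length(sets$boundary))
    stop("population has no free boundary: pressure system is singular",
         call. = FALSE)
  pos <- integer(length(grid$u))
  pos[occ] <- seq_along(occ)
  adj <- grid$lattice$adj
  ii <- integer(0); jj <- integer(0)
  nb_bnd <- integer(length(occ))
  deg <- integer(length(occ))
  for (k in seq_along(occ)) {
    nbs <- adj[[occ[k]]]
    deg[k] <- length(nbs)
    inocc <- pos[nbs]
    inside <- inocc > 0L
    nb_bnd[k] <- sum(!inside)
    if (any(inside)) {
      ii <- c(ii, rep.int(k, sum(inside)))
      jj <- c(jj, inocc[inside])
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = -1,
                            dims = c(length(occ), length(occ)))
  Matrix::diag(A) <- deg
  list(A = A, occ = occ, boundary = sets$boundary, nb_bnd = nb_bnd,
       pos = pos)
}

#' Cellular pressure field
#'
#' Solves the discrete Laplace problem for the cellular pressure: with L
#' the lattice Laplacian restricted to the populated set, \code{-L p = s(u)}
#' where \code{s(u) = 1} in voxels at the carrying capacity (u = 2) and 0
#' otherwise, with \code{p = 0} on the discrete boundary. When no voxel is
#' over unit occupancy the pressure is identically zero (equilibrium).
#'
#' @param grid a \code{"population_grid"} with at least one cell.
#' @return Numeric vector of pressures over all lattice voxels (zero
#'   outside the populated set), with attribute \code{"sets"} carrying the
#'   interior/boundary partition.
#' @examples
#' lat <- build_square_lattice(5, 1)
#' g <- population_grid(lat, occupied = c(2, 3, 3, 4))
#' solve_pressure(g)[2:4]  # (1/2, 1, 1/2)
#' @export
solve_pressure <- function(grid) {
  sys <- population_system(grid)
  s <- as.numeric(grid$u[sys$occ] == 2L)
  p <- numeric(length(grid$u))
  if (any(s > 0))
    p[sys$occ] <- as.numeric(Matrix::solve(sys$A, s))
  structure(p, sets = list(interior = sys$occ, boundary = sys$boundary))
}

#' Candidate movement events and their rates
#'
#' Converts pressure differences into movement rates: for every ordered
#' pair of edge-sharing voxels (i, j) with \code{u_i > u_j}, the current
#' \code{I_ij = (e_ij/d_ij)(p_i - p_j)} (e/d = 1 on the uniform lattices
#' used here) gives the rate \code{R_ij = D * max(0, I_ij)}. Movements into
#' voxels with equal or higher occupancy have rate zero, as do negative
#' (uphill) currents. The conversion factor is also taken to be zero for
#' moves that would fragment the populated set (a lone rim cell stepping
#' off the tissue): the factor may depend on position and movement type,
#' and this choice keeps the population edge-connected at every event.
#'
#' @param grid a \code{"population_grid"}.
#' @param p pressure field from \code{\link{solve_pressure}}.
#' @param params a \code{"growth_params"}.
#' @return Data frame of candidates with positive rate: columns
#'   \code{source}, \code{dest}, \code{rate}.
#' @export
movement_rates <- function(grid, p, params = growth_params()) {
  occ <- which(grid$u > 0L)
  n_occ <- length(occ)
  # source-side fragmentation checks depend only on i: memoize per call
  src_ok <- rep(NA, length(grid$u))
  src <- integer(0); dst <- integer(0); rate <- numeric(0)
  for (i in occ) {
    for (j in grid$lattice$adj[[i]]) {
      if (grid$u[i] > grid$u[j]) {
        r <- params$d_move * max(0, p[i] - p[j])
        if (r <= 0) next
        if (params$keep_connected && grid$u[i] == 1L) {
          if (is.na(src_ok[i]))
            src_ok[i] <- vacating_source_ok(grid, i, n_occ)
          if (!src_ok[i] || !vacating_dest_ok(grid, i, j, n_occ)) next
        }
        src <- c(src, i); dst <- c(dst, j); rate <- c(rate, r)
      }
    }
  }
  data.frame(source = src, dest = dst, rate = rate)
}

# Source side of the fragmentation check for a vacating move: removing
# voxel i must not split the populated set. Cheap sufficient screen first
# (i's populated neighbors mutually adjacent through the ring around i),
# full BFS fallback otherwise.
vacating_source_ok <- function(grid, i, n_occ) {
  if (n_occ <= 1L) return(TRUE)
  adj <- grid$lattice$adj
  nb_i <- adj[[i]]
  occ_nb <- nb_i[grid$u[nb_i] > 0L]
  if (length(occ_nb) <= 1L) return(TRUE)
  comp <- seq_along(occ_nb)
  for (a in seq_along(occ_nb)) {
    for (b in seq_along(occ_nb)) {
      if (a < b && occ_nb[b] %in% adj[[occ_nb[a]]]) {
        ca <- comp[a]; cb <- comp[b]
        comp[comp == cb] <- ca
      }
    }
  }
  if (length(unique(comp)) == 1L) return(TRUE)
  # full check: BFS over the populated set without i
  inocc <- logical(length(grid$u))
  inocc[grid$u > 0L] <- TRUE
  inocc[i] <- FALSE
  start <- occ_nb[1L]
  seen <- logical(length(grid$u))
  seen[start] <- TRUE
  queue <- start
  count <- 1L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    nb <- nb[inocc[nb] & !seen[nb]]
    seen[nb] <- TRUE
    count <- count + length(nb)
    queue <- c(queue, nb)
  }
  count == n_occ - 1L
}

# Destination side: the target voxel must touch a populated voxel other
# than the vacated source (so the mover stays attached).
vacating_dest_ok <- function(grid, i, j, n_occ) {
  if (n_occ <= 1L) return(TRUE)
  nb_j <- grid$lattice$adj[[j]]
  any(grid$u[nb_j] > 0L & nb_j != i)
}

#' Quasi-static nutrient field
#'
#' Nutrient enters at the population boundary at concentration \code{c_b},
#' diffuses by the lattice Laplacian and is consumed at rate \code{kappa}
#' per cell: \code{-L c = -kappa * u} on the populated set with
#' \code{c = c_b} on the boundary, clamped below at zero.
#'
#' @param grid a \code{"population_grid"}.
#' @param params a \code{"growth_params"}.
#' @return Numeric concentration vector over all lattice voxels
#'   (\code{c_b} on the discrete boundary, 0 elsewhere outside).
#' @export
nutrient_field <- function(grid, params = growth_params()) {
  sys <- population_system(grid)
  rhs <- sys$nb_bnd * params$c_b - params$kappa * grid$u[sys$occ]
  cc <- numeric(length(grid$u))
  cc[sys$occ] <- pmax(0, as.numeric(Matrix::solve(sys$A, rhs)))
  cc[sys$boundary] <- params$c_b
  cc
}

#' Nutrient-gated proliferation rates
#'
#' A cell divides at rate \code{mu} when it is alone in its voxel
#' (occupancy 1; voxels already at the carrying capacity do not divide) and
#' the local nutrient concentration is at least \code{c_thr}.
#'
#' @param grid a \code{"population_grid"}.
#' @param c nutrient field from \code{\link{nutrient_field}}.
#' @param params a \code{"growth_params"}.
#' @return Data frame with columns \code{voxel}, \code{cell_id},
#'   \code{rate} for cells with positive birth rate.
#' @export
proliferation_rates <- function(grid, c, params = growth_params()) {
  eligible <- which(grid$u == 1L & c >= params$c_thr)
  if (!length(eligible) || params$mu <= 0)
    return(data.frame(voxel = integer(0), cell_id = integer(0),
                      rate = numeric(0)))
  data.frame(voxel = eligible,
             cell_id = vapply(grid$cells[eligible], `[`, integer(1), 1L),
             rate = params$mu)
}

# execute a move or divide on the grid; returns the updated grid
apply_grid_event <- function(grid, kind, source, dest, cell_id,
                             new_id = NA_integer_) {
  if (kind == "move") {
    k <- match(cell_id, grid$cells[[source]])
    if (is.na(k)) stop("unknown cell id in source voxel", call. = FALSE)
    if (grid$u[dest] >= grid$u[source])
      stop("illegal move: destination not less crowded", call. = FALSE)
    grid$cells[[source]] <- grid$cells[[source]][-k]
    grid$cells[[dest]] <- c(grid$cells[[dest]], cell_id)
    grid$u[source] <- grid$u[source] - 1L
    grid$u[dest] <- grid$u[dest] + 1L
  } else if (kind == "divide") {
    if (grid$u[source] != 1L)
      stop("illegal divide: voxel not singly occupied", call. = FALSE)
    if (!cell_id %in% grid$cells[[source]])
      stop("unknown cell id", call. = FALSE)
    if (is.na(new_id)) new_id <- grid$next_id
    grid$cells[[source]] <- c(grid$cells[[source]], new_id)
    grid$u[source] <- 2L
    grid$next_id <- max(grid$next_id, new_id + 1L)
  } else stop("unknown event kind", call. = FALSE)
  grid
}

#' Event-driven simulation of a growing cell population
#'
#' Gillespie-style sampler of the population layer: after every event the
#' pressure and nutrient fields and all movement and proliferation rates
#' are recomputed, the waiting time to the next event is exponential with
#' the total rate, and the event (a uniformly chosen candidate) is
#' executed. When a move fires from a doubly occupied voxel the moving
#' cell is chosen uniformly. The simulation stops at the configured target
#' population size, at \code{t_end}, or at equilibrium (zero total rate).
#'
#' @param grid initial \code{"population_grid"} (e.g. a single founder
#'   cell).
#' @param params a \code{"growth_params"}.
#' @param t_end time horizon (default \code{Inf}: run to target size or
#'   equilibrium).
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return An object of class \code{"event_log"}: a data frame with
#'   columns \code{time}, \code{kind}, \code{source}, \code{dest},
#'   \code{cell_id}, \code{new_id}, with attributes \code{final_grid} and
#'   \code{equilibrium}.
#' @examples
#' lat <- build_hex_lattice(15, 15)
#' g <- population_grid(lat, occupied = 113)
#' log <- simulate_population(g, growth_params(target_size = 20), seed = 1)
#' @export
simulate_population <- function(grid, params = growth_params(),
                                t_end = Inf, seed = NULL) {
  stopifnot(inherits(grid, "population_grid"))
  if (!is.null(seed)) set.seed(seed)
  t <- 0
  rows <- list()
  equilibrium <- FALSE
  repeat {
    if (sum(grid$u) >= params$target_size) break
    p <- solve_pressure(grid)
    mv <- movement_rates(grid, p, params)
    cc <- nutrient_field(grid, params)
    pr <- proliferation_rates(grid, cc, params)
    total <- sum(mv$rate) + sum(pr$rate)
    if (total <= 0) { equilibrium <- TRUE; break }
    t <- t + stats::rexp(1, total)
    if (t > t_end) break
    r <- stats::runif(1) * total
    if (r < sum(mv$rate)) {
      k <- findInterval(r, cumsum(mv$rate), left.open = TRUE) + 1L
      src <- mv$source[k]; dst <- mv$dest[k]
      cid <- grid$cells[[src]][sample.int(grid$u[src], 1L)]
      grid <- apply_grid_event(grid, "move", src, dst, cid)
      rows[[length(rows) + 1L]] <-
        data.frame(time = t, kind = "move", source = src, dest = dst,
                   cell_id = cid, new_id = NA_integer_)
    } else {
      r2 <- r - sum(mv$rate)
      k <- findInterval(r2, cumsum(pr$rate), left.open = TRUE) + 1L
      vox <- pr$voxel[k]; cid <- pr$cell_id[k]
      nid <- grid$next_id
      grid <- apply_grid_event(grid, "divide", vox, NA_integer_, cid, nid)
      rows[[length(rows) + 1L]] <-
        data.frame(time = t, kind = "divide", source = vox,
                   dest = NA_integer_, cell_id = cid, new_id = nid)
    }
  }
  log <- if (length(rows)) do.call(rbind, rows)
         else data.frame(time = numeric(0), kind = character(0),
                         source = integer(0), dest = integer(0),
                         cell_id = integer(0), new_id = integer(0))
  structure(log, class = c("event_log", "data.frame"),
            final_grid = grid, equilibrium = equilibrium)
}

#' Is the populated voxel set edge-connected?
#'
#' @param grid a \code{"population_grid"}.
#' @return \code{TRUE} if every populated voxel is reachable from every
#'   other along lattice edges through populated voxels.
#' @export
population_connected <- function(grid) {
  occ <- which(grid$u > 0L)
  if (length(occ) <= 1L) return(TRUE)
  inocc <- logical(length(grid$u))
  inocc[occ] <- TRUE
  seen <- logical(length(grid$u))
  queue <- occ[1L]
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- grid$lattice$adj[[v]]
    nb <- nb[inocc[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen[occ])
}

#' Lattice distance to the population boundary
#'
#' Breadth-first distance (in lattice edges) from every populated voxel to
#' the nearest discrete-boundary voxel.
#'
#' @param grid a \code{"population_grid"}.
#' @return Integer vector over all lattice voxels (\code{NA} outside the
#'   populated set; 1 for voxels adjacent to the boundary).
#' @export
distance_to_boundary <- function(grid) {
  sets <- population_sets(grid)
  dist <- rep(NA_integer_, length(grid$u))
  inocc <- logical(length(grid$u))
  inocc[sets$interior] <- TRUE
  frontier <- sets$boundary
  level <- 0L
  seen <- logical(length(grid$u))
  seen[frontier] <- TRUE
  while (length(frontier)) {
    level <- level + 1L
    nxt <- unique(unlist(grid$lattice$adj[frontier], use.names = FALSE))
    nxt <- nxt[inocc[nxt] & !seen[nxt]]
    dist[nxt] <- level
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  dist
}

#' Replay an event log onto a grid
#'
#' Applies the recorded events in order, optionally running a callback on
#' every intermediate grid (used to verify invariants along a trajectory).
#'
#' @param grid the initial \code{"population_grid"} the log was recorded
#'   from.
#' @param log an \code{"event_log"}.
#' @param callback optional \code{function(grid, event_row)} called after
#'   each event.
#' @return The final \code{"population_grid"}.
#' @export
replay_events <- function(grid, log, callback = NULL) {
  for (k in seq_len(nrow(log))) {
    grid <- apply_grid_event(grid, log$kind[k], log$source[k],
                             log$dest[k], log$cell_id[k], log$new_id[k])
    if (!is.null(callback)) callback(grid, log[k, ])
  }
  grid
}

#' Write / read an event log as JSON lines
#'
#' One JSON object per line with fields time, kind, source, dest, cell_id,
#' new_id; replayable bit-exactly.
#'
#' @param log an \code{"event_log"}.
#' @param path file path.
#' @return \code{path} (write) or the \code{"event_log"} (read).
#' @export
write_event_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(k) {
    as.character(jsonlite::toJSON(as.list(log[k, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA,
                                  na = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    data.frame(time = as.numeric(x$time), kind = as.character(x$kind),
               source = as.integer(x$source),
               dest = if (is.null(x$dest)) NA_integer_ else as.integer(x$dest),
               cell_id = as.integer(x$cell_id),
               new_id = if (is.null(x$new_id)) NA_integer_
                        else as.integer(x$new_id))
  })
  log <- do.call(rbind, rows)
  structure(log, class = c("event_log", "data.frame"))
}

#' Tabular snapshot of a population grid
#'
#' @param grid a \code{"population_grid"}.
#' @return Data frame with one row per populated voxel: \code{voxel},
#'   \code{x}, \code{y}, \code{u}, \code{cell_ids} (comma separated).
#' @export
grid_snapshot <- function(grid) {
  occ <- which(grid$u > 0L)
  data.frame(voxel = occ,
             x = grid$lattice$coords[occ, 1],
             y = grid$lattice$coords[occ, 2],
             u = grid$u[occ],
             cell_ids = vapply(grid$cells[occ], paste, character(1),
                               collapse = ","))
}
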