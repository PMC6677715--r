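#' Hexagonal cell lattice
#'
#' Builds an \code{nx} by \code{ny} patch of hexagonally packed cells with
#' unit cell radius, i.e. neighbor center distance 2. Rows run along the x
#' axis (one lattice axis is horizontal), with basis vectors (2, 0) and
#' (1, sqrt(3)). Junctional adjacency (the up-to-6 nearest neighbors) is
#' precomputed. With \code{periodic = TRUE} the patch is closed into a torus
#' and every cell has exactly 6 junctional neighbors.
#'
#' @param nx,ny number of cells along each lattice direction.
#' @param periodic wrap the patch into a torus?
#' @return An object of class \code{"lattice"}: a list with \code{coords}
#'   (n x 2 matrix of cell centers), \code{adj} (list of junctional neighbor
#'   indices), \code{nx}, \code{ny}, \code{periodic}, \code{type}.
#' @examples
#' lat <- build_hex_lattice(10, 10)
#' lengths(lat$adj)[1:5]
#' @export
build_hex_lattice <- function(nx, ny, periodic = FALSE) {
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 1 || ny < 1)
    stop("lattice dimensions must be >= 1", call. = FALSE)
  nx <- as.integer(nx); ny <- as.integer(ny)
  a <- rep(seq_len(nx) - 1L, times = ny)
  b <- rep(seq_len(ny) - 1L, each = nx)
  coords <- cbind(x = 2 * a + b, y = sqrt(3) * b)
  idx <- function(a, b) a + nx * b + 1L
  # axial-coordinate neighbor offsets of the triangular (hex-packed) lattice
  offs <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                c(1L, -1L), c(-1L, 1L))
  n <- nx * ny
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    ai <- a[i]; bi <- b[i]
    nb <- integer(0)
    for (k in seq_len(nrow(offs))) {
      aj <- ai + offs[k, 1L]; bj <- bi + offs[k, 2L]
      if (periodic) {
        aj <- aj %% nx; bj <- bj %% ny
      } else if (aj < 0L || aj >= nx || bj < 0L || bj >= ny) next
      nb <- c(nb, idx(aj, bj))
    }
    adj[[i]] <- sort(unique(nb[nb != i]))
  }
  structure(list(coords = coords, adj = adj, nx = nx, ny = ny,
                 periodic = periodic, type = "hex",
                 basis = rbind(c(2, 0), c(1, sqrt(3)))),
            class = "lattice")
}

#' Square cell lattice
#'
#' Square packing with neighbor center distance 2 and 4-neighbor (von
#' Neumann) junctional adjacency; \code{ny = 1} gives a 1-D chain. Used by
#' the population layer where a square grid is preferred.
#'
#' @inheritParams build_hex_lattice
#' @return An object of class \code{"lattice"}.
#' @examples
#' chain <- build_square_lattice(5, 1)
#' @export
build_square_lattice <- function(nx, ny, periodic = FALSE) {
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 1 || ny < 1)
    stop("lattice dimensions must be >= 1", call. = FALSE)
  nx <- as.integer(nx); ny <- as.integer(ny)
  a <- rep(seq_len(nx) - 1L, times = ny)
  b <- rep(seq_len(ny) - 1L, each = nx)
  coords <- cbind(x = 2 * a, y = 2 * b)
  idx <- function(a, b) a + nx * b + 1L
  offs <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  n <- nx * ny
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (k in seq_len(nrow(offs))) {
      aj <- a[i] + offs[k, 1L]; bj <- b[i] + offs[k, 2L]
      if (periodic) {
        aj <- aj %% nx; bj <- bj %% ny
      } else if (aj < 0L || aj >= nx || bj < 0L || bj >= ny) next
      nb <- c(nb, idx(aj, bj))
    }
    adj[[i]] <- sort(unique(nb[nb != i]))
  }
  structure(list(coords = coords, adj = adj, nx = nx, ny = ny,
                 periodic = periodic, type = "square",
                 basis = rbind(c(2, 0), c(0, 2))),
            class = "lattice")
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf("%s lattice: %d x %d (%d cells), %s\n", x$type, x$nx, x$ny,
              nrow(x$coords), if (x$periodic) "periodic" else "open"))
  invisible(x)
}

#' Protrusion geometry
#'
#' Describes the reach of cellular protrusions: a length \code{l} (in cell
#' radii), one or more directions \code{theta} (radians, measured from the
#' positive x axis), and an angular width \code{width}. A width of
#' \code{2*pi} means isotropic protrusions and the directions are ignored.
#'
#' @param length protrusion length l in cell radii (neighbor centers are 2
#'   radii apart).
#' @param directions numeric vector of protrusion directions theta in
#'   radians; ignored when \code{width == 2*pi}. Angles are taken modulo
#'   \code{2*pi}, so \code{c(0, pi)} describes opposite horizontal
#'   protrusions.
#' @param width angular width d-theta of each protrusion sector, in
#'   \code{[0, 2*pi]}.
#' @return An object of class \code{"protrusion_spec"}.
#' @examples
#' protrusion_spec(3.5)                      # isotropic, reaches ring 2
#' protrusion_spec(5, c(0, pi), pi / 20)     # polarized horizontal
#' @export
protrusion_spec <- function(length = 3.5, directions = NULL,
                            width = 2 * pi) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 0)
    stop("protrusion length must be a single non-negative number",
         call. = FALSE)
  if (!is.numeric(width) || length(width) != 1L || is.na(width) ||
      width < 0 || width > 2 * pi)
    stop("protrusion width must lie in [0, 2*pi]", call. = FALSE)
  iso <- abs(width - 2 * pi) < 1e-12
  if (!iso && (is.null(directions) || length(directions) == 0L))
    stop("directions required when width < 2*pi", call. = FALSE)
  structure(list(length = length,
                 directions = if (iso) numeric(0) else as.numeric(directions),
                 width = width, isotropic = iso),
            class = "protrusion_spec")
}

# smallest absolute angular difference
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# Core sector/distance rule on arbitrary cell coordinates. shifts: matrix
# of periodic image translations (single zero row for open domains).
protrusion_sets <- function(coords, spec, shifts = matrix(0, 1, 2)) {
  n <- nrow(coords)
  P <- replicate(n, integer(0), simplify = FALSE)
  if (spec$length <= 2) return(P)
  tol <- 1e-9
  in_sector <- function(phi) {
    if (spec$isotropic) return(rep(TRUE, length(phi)))
    ok <- rep(FALSE, length(phi))
    for (th in spec$directions)
      ok <- ok | (ang_diff(phi, th) <= spec$width / 2 + tol)
    ok
  }
  for (i in seq_len(n)) {
    for (s in seq_len(nrow(shifts))) {
      dx <- coords[, 1] + shifts[s, 1] - coords[i, 1]
      dy <- coords[, 2] + shifts[s, 2] - coords[i, 2]
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist > 2 + tol & dist <= spec$length + tol)
      cand <- cand[cand != i]
      if (!length(cand)) next
      phi_ij <- atan2(dy[cand], dx[cand])
      keep <- in_sector(phi_ij) & in_sector(phi_ij + pi)
      P[[i]] <- c(P[[i]], cand[keep])
    }
    P[[i]] <- sort(unique(P[[i]]))
  }
  P
}

adjacency_matrix <- function(L, n) {
  ii <- rep.int(seq_len(n), lengths(L))
  jj <- unlist(L, use.names = FALSE)
  if (!length(ii))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(n, n)))
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
}

#' Protrusion-mediated contact sets
#'
#' Computes, for every cell of a lattice, the set P(i) of protrusional
#' contacts: cells at center distance in (2, l] whose direction from i lies
#' inside one of i's protrusion sectors, and which reciprocally reach i with
#' one of their own sectors (mutual-reach rule; all cells share the same
#' global protrusion directions). Junctional neighbors (distance 2) are
#' never protrusional contacts. Sector edges are closed, with a small
#' numeric tolerance. On periodic lattices distances and directions use the
#' minimum-image convention.
#'
#' @param lattice a \code{"lattice"} object.
#' @param spec a \code{"protrusion_spec"}.
#' @return A list of integer vectors, \code{P[[i]]} the sorted protrusional
#'   contacts of cell i.
#' @examples
#' lat <- build_hex_lattice(9, 9)
#' P <- protrusional_contacts(lat, protrusion_spec(3.5))
#' length(P[[41]])  # interior cell: the 6 second-ring cells
#' @export
protrusional_contacts <- function(lattice, spec) {
  stopifnot(inherits(lattice, "lattice"), inherits(spec, "protrusion_spec"))
  shifts <- matrix(0, 1, 2)
  if (lattice$periodic) {
    span <- rbind(lattice$nx * lattice$basis[1, ],
                  lattice$ny * lattice$basis[2, ])
    g <- expand.grid(a = -1:1, b = -1:1)
    shifts <- as.matrix(g) %*% span
  }
  protrusion_sets(lattice$coords, spec, shifts)
}

#' Cell-to-cell signaling graph
#'
#' Bundles the junctional sets J(i) (lattice neighbors, superscript (a))
#' and the protrusional sets P(i) (superscript (b)) with the signal weights
#' \code{c(w_a, q_a, w_b, q_b)} into the graph used to aggregate incoming
#' and outgoing Delta/Notch signals.
#'
#' @param lattice a \code{"lattice"}.
#' @param spec a \code{"protrusion_spec"}, or \code{NULL} for no
#'   protrusional contacts.
#' @param params a \code{"pathway_params"} supplying the weights.
#' @param junctional optional junctional adjacency list overriding the
#'   lattice adjacency (used by the population layer, where co-resident
#'   cells are also junctional contacts).
#' @return An object of class \code{"contact_graph"} with fields \code{J},
#'   \code{P} (adjacency lists), \code{weights}, and sparse adjacency
#'   matrices \code{AJ}, \code{AP} used for fast aggregation.
#' @examples
#' lat <- build_hex_lattice(5, 5)
#' g <- contact_graph(lat, protrusion_spec(3.5), pathway_params())
#' @export
contact_graph <- function(lattice, spec = protrusion_spec(),
                          params = pathway_params(), junctional = NULL) {
  stopifnot(inherits(lattice, "lattice"))
  J <- if (is.null(junctional)) lattice$adj else junctional
  P <- if (is.null(spec)) replicate(length(J), integer(0), simplify = FALSE)
       else protrusional_contacts(lattice, spec)
  # protrusional contacts never duplicate junctional ones
  P <- mapply(function(p, j) setdiff(p, j), P, J, SIMPLIFY = FALSE)
  n <- length(J)
  structure(list(J = J, P = P,
                 weights = c(w_a = params$w_a, q_a = params$q_a,
                             w_b = params$w_b, q_b = params$q_b),
                 AJ = adjacency_matrix(J, n), AP = adjacency_matrix(P, n),
                 n = n),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("contact graph: %d cells, %d junctional / %d protrusional edges (directed)\n",
              x$n, sum(lengths(x$J)), sum(lengths(x$P))))
  cat(sprintf("  weights [w_a, q_a, w_b, q_b] = [%g, %g, %g, %g]\n",
              x$weights[1], x$weights[2], x$weights[3], x$weights[4]))
  invisible(x)
}

#' Aggregate incoming and outgoing signals
#'
#' Forms, for every cell, the weighted signal sums driving the pathway:
#' \code{d_in = w_a * sum(D over J(i)) + w_b * sum(D over P(i))},
#' \code{d_out = q_a * sum(D over J(i)) + q_b * sum(D over P(i))}, and
#' \code{n_in} analogous to \code{d_in} with Notch. Values are summed in
#' whatever units the caller supplies (counts in the stochastic drivers,
#' concentrations in the ODE form); the operation is linear.
#'
#' @param values n x 2 (or n x 3) numeric matrix whose first two columns are
#'   per-cell N and D.
#' @param graph a \code{"contact_graph"} for the same n cells.
#' @return An n x 3 matrix with columns \code{d_in}, \code{d_out},
#'   \code{n_in}.
#' @examples
#' lat <- build_hex_lattice(3, 3)
#' g <- contact_graph(lat, NULL, pathway_params())
#' aggregate_signals(cbind(N = rep(1, 9), D = rep(2, 9)), g)
#' @export
aggregate_signals <- function(values, graph) {
  stopifnot(inherits(graph, "contact_graph"))
  values <- as.matrix(values)
  if (nrow(values) != graph$n)
    stop("aggregate_signals: values have ", nrow(values),
         " rows but the graph has ", graph$n, " cells", call. = FALSE)
  N <- values[, 1]; D <- values[, 2]
  da <- as.numeric(graph$AJ %*% D); db <- as.numeric(graph$AP %*% D)
  na <- as.numeric(graph$AJ %*% N); nb <- as.numeric(graph$AP %*% N)
  w <- graph$weights
  cbind(d_in = w[["w_a"]] * da + w[["w_b"]] * db,
        d_out = w[["q_a"]] * da + w[["q_b"]] * db,
        n_in = w[["w_a"]] * na + w[["w_b"]] * nb)
}

#' Export the contact graph as an edge list
#'
#' @param graph a \code{"contact_graph"}.
#' @return A data frame with columns \code{i}, \code{j}, \code{type}
#'   (\code{"junctional"} or \code{"protrusional"}), one row per directed
#'   contact.
#' @export
contact_edges <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  ej <- data.frame(i = rep.int(seq_len(graph$n), lengths(graph$J)),
                   j = unlist(graph$J, use.names = FALSE))
  ep <- data.frame(i = rep.int(seq_len(graph$n), lengths(graph$P)),
                   j = unlist(graph$P, use.names = FALSE))
  out <- rbind(cbind(ej, type = rep("junctional", nrow(ej))),
               cbind(ep, type = rep("protrusional", nrow(ep))))
  rownames(out) <- NULL
  out
}
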