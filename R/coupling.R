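#' Full tissue state
#'
#' Bundles the population grid, one molecular (per-voxel) state per cell,
#' the shared single-cell mesh, the pathway parameters and protrusion
#' geometry, and the current time. The cell-to-cell contact graph is
#' derived from the occupied voxel positions and is rebuilt after every
#' population event.
#'
#' @param grid a \code{"population_grid"}.
#' @param mesh the shared \code{"cell_mesh"} of the single-cell layer.
#' @param params a \code{"pathway_params"}.
#' @param spec a \code{"protrusion_spec"} (or \code{NULL} for junctional
#'   signaling only).
#' @param states optional named list (names = cell ids) of nv x 3 state
#'   matrices; zero states by default.
#' @param time current simulation time.
#' @return An object of class \code{"tissue_state"}.
#' @export
tissue_state <- function(grid, mesh, params = pathway_params(),
                         spec = protrusion_spec(), states = NULL,
                         time = 0) {
  stopifnot(inherits(grid, "population_grid"), inherits(mesh, "cell_mesh"))
  ids <- sort(unlist(grid$cells, use.names = FALSE))
  if (is.null(states)) {
    states <- replicate(length(ids), rdme_zero_state(mesh),
                        simplify = FALSE)
    names(states) <- as.character(ids)
  }
  if (!setequal(names(states), as.character(ids)))
    stop("tissue_state: cell ids in grid and states differ", call. = FALSE)
  ts <- structure(list(grid = grid, mesh = mesh, params = params,
                       spec = spec, states = states, time = time,
                       cell_ids = ids, graph = NULL),
                  class = "tissue_state")
  ts$graph <- build_population_contacts(grid, spec, params)
  ts
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf("tissue state at t = %g: %d cells, %d-voxel mesh per cell\n",
              x$time, length(x$cell_ids), x$mesh$n_voxels))
  invisible(x)
}

#' Contact graph of a cell population
#'
#' Builds the signaling graph over the cells of a population grid, indexed
#' in increasing cell-id order. Junctional contacts are cells sharing a
#' voxel or occupying edge-adjacent voxels; protrusional contacts follow
#' the distance/sector rule of \code{\link{protrusional_contacts}} applied
#' to the occupied voxel centers.
#'
#' @param grid a \code{"population_grid"}.
#' @param spec a \code{"protrusion_spec"} or \code{NULL}.
#' @param params a \code{"pathway_params"} (weights).
#' @return A \code{"contact_graph"} over the cells (not the voxels), with
#'   an attribute \code{"cell_ids"} giving the id of each graph index.
#' @export
build_population_contacts <- function(grid, spec = protrusion_spec(),
                                      params = pathway_params()) {
  ids <- sort(unlist(grid$cells, use.names = FALSE))
  m <- length(ids)
  voxel_of <- integer(m)
  occ <- which(grid$u > 0L)
  for (v in occ)
    voxel_of[match(grid$cells[[v]], ids)] <- v
  pos <- grid$lattice$coords[voxel_of, , drop = FALSE]
  cells_in <- function(v) match(grid$cells[[v]], ids)
  J <- replicate(m, integer(0), simplify = FALSE)
  for (v in occ) {
    here <- cells_in(v)
    nb_occ <- grid$lattice$adj[[v]]
    nb_occ <- nb_occ[grid$u[nb_occ] > 0L]
    there <- if (length(nb_occ))
      unlist(lapply(nb_occ, cells_in), use.names = FALSE) else integer(0)
    for (c1 in here)
      J[[c1]] <- sort(unique(c(setdiff(here, c1), there)))
  }
  P <- if (is.null(spec)) replicate(m, integer(0), simplify = FALSE)
       else protrusion_sets(pos, spec)
  g <- structure(list(J = J, P = P,
                      weights = c(w_a = params$w_a, q_a = params$q_a,
                                  w_b = params$w_b, q_b = params$q_b),
                      AJ = adjacency_matrix(J, m),
                      AP = adjacency_matrix(P, m), n = m),
                 class = "contact_graph")
  attr(g, "cell_ids") <- ids
  attr(g, "voxel_of") <- voxel_of
  g
}

#' Random partition of a dividing cell's molecules
#'
#' At division every molecule of every species is assigned independently
#' to one of the two daughters with probability 1/2 (a binomial split of
#' the per-species totals), and each daughter's share is redistributed
#' over its mesh voxels proportionally to voxel volume. Totals are
#' conserved exactly.
#'
#' @param parent nv x 3 per-voxel state matrix of the parent.
#' @param mesh the daughters' \code{"cell_mesh"} (same as the parent's).
#' @param seed optional integer seed.
#' @param species which species are shared binomially: \code{"all"}
#'   (default) or \code{"nd"} (Notch and Delta shared, reporter zeroed in
#'   both daughters).
#' @return List with elements \code{d1} and \code{d2}, nv x 3 state
#'   matrices.
#' @examples
#' m <- cell_mesh_fixture()
#' st <- distribute_counts(m, c(100, 50, 10))
#' halves <- divide_counts(st, m, seed = 1)
#' cell_totals(halves$d1) + cell_totals(halves$d2)  # == parent totals
#' @export
divide_counts <- function(parent, mesh, seed = NULL,
                          species = c("all", "nd")) {
  species <- match.arg(species)
  if (!is.null(seed)) set.seed(seed)
  tot <- cell_totals(parent)
  share <- c(stats::rbinom(1, tot[1], 0.5), stats::rbinom(1, tot[2], 0.5),
             if (species == "all") stats::rbinom(1, tot[3], 0.5) else 0L)
  rest <- c(tot[1] - share[1], tot[2] - share[2],
            if (species == "all") tot[3] - share[3] else 0L)
  list(d1 = distribute_counts(mesh, share),
       d2 = distribute_counts(mesh, rest))
}

#' Apply a population event to the tissue
#'
#' A move transports the cell's entire molecular state with it (the
#' internal configuration is unchanged); a divide replaces the parent by
#' two daughters whose molecules come from \code{\link{divide_counts}},
#' both placed in the parent voxel (occupancy 2). The populated set, its
#' boundary, and the contact graph are recomputed.
#'
#' @param tissue a \code{"tissue_state"}.
#' @param event one-row data frame (or list) with fields \code{kind},
#'   \code{source}, \code{dest}, \code{cell_id}, \code{new_id},
#'   \code{time}.
#' @return The updated \code{"tissue_state"}.
#' @export
apply_event <- function(tissue, event) {
  kind <- as.character(event$kind)
  cid <- as.integer(event$cell_id)
  if (kind == "move") {
    tissue$grid <- apply_grid_event(tissue$grid, "move",
                                    as.integer(event$source),
                                    as.integer(event$dest), cid)
  } else if (kind == "divide") {
    nid <- as.integer(event$new_id)
    tissue$grid <- apply_grid_event(tissue$grid, "divide",
                                    as.integer(event$source), NA_integer_,
                                    cid, nid)
    halves <- divide_counts(tissue$states[[as.character(cid)]], tissue$mesh)
    tissue$states[[as.character(cid)]] <- halves$d1
    tissue$states[[as.character(nid)]] <- halves$d2
  } else stop("unknown event kind: ", kind, call. = FALSE)
  tissue$cell_ids <- sort(unlist(tissue$grid$cells, use.names = FALSE))
  tissue$time <- as.numeric(event$time)
  tissue$graph <- build_population_contacts(tissue$grid, tissue$spec,
                                            tissue$params)
  tissue
}

#' Coupled inner-outer tissue simulation
#'
#' Advances the molecular (RDME) state of every cell between the events of
#' a recorded population trajectory (one-way replay) with the split-step
#' signal-freezing scheme: per iteration, per-cell totals give the
#' signals, the chunk length comes from \code{\link{adaptive_chunk}} on
#' the population concentration vector, every cell's mesh is advanced
#' independently by the Next Subvolume Method to the next chunk boundary,
#' output time, or population event, and due events are applied
#' (event-first at exact ties). Signals and the chunk length are
#' recomputed at every chunk boundary and after every event.
#'
#' @param tissue initial \code{"tissue_state"}.
#' @param events an \code{"event_log"} recorded by
#'   \code{\link{simulate_population}} (times sorted increasing), or
#'   \code{NULL} for a frozen population.
#' @param t_end horizon (must be >= the tissue's current time).
#' @param times output times for per-cell totals.
#' @param seed integer seed fixing the whole run; \code{NULL} uses the
#'   current RNG state.
#' @param gamma diffusion constant; default \code{1/omega}.
#' @return A data frame with columns \code{time}, \code{cell} (cell id),
#'   \code{N}, \code{D}, \code{R} (whole-cell totals at the output times),
#'   with the final \code{"tissue_state"} as attribute \code{"tissue"}.
#' @export
run_coupled <- function(tissue, events = NULL, t_end, times = NULL,
                        seed = NULL, gamma = 1 / tissue$params$omega) {
  stopifnot(inherits(tissue, "tissue_state"))
  if (t_end < tissue$time) stop("t_end before current time", call. = FALSE)
  if (!is.null(events) && nrow(events) &&
      is.unsorted(events$time, strictly = FALSE))
    stop("event log times must be sorted", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  params <- tissue$params
  om <- params$omega
  csr <- mesh_csr(tissue$mesh, gamma)
  pv <- params_vec(params)
  en <- rep(1L, 9L)
  times <- sort(unique(if (is.null(times)) t_end else times))
  ev_idx <- 1L
  n_ev <- if (is.null(events)) 0L else nrow(events)
  rec <- list()
  record <- function(tt) {
    tot <- t(vapply(as.character(tissue$cell_ids),
                    function(id) cell_totals(tissue$states[[id]]),
                    numeric(3)))
    rec[[length(rec) + 1L]] <<-
      data.frame(time = tt, cell = tissue$cell_ids,
                 N = tot[, 1], D = tot[, 2], R = tot[, 3])
  }
  advance_cells <- function(dt, signals) {
    if (dt <= 0) return(invisible())
    ids <- as.character(tissue$cell_ids)
    for (k in seq_along(ids)) {
      tissue$states[[ids[k]]] <<-
        nsm_cpp(tissue$states[[ids[k]]], tissue$mesh$volumes,
                csr$eptr, csr$enbr, csr$erate, pv, en,
                as.numeric(signals[k, ]), dt, draw_seed())
    }
  }
  t <- tissue$time
  ti <- which(times >= t)[1]
  if (is.na(ti)) ti <- length(times) + 1L
  while (ev_idx <= n_ev && events$time[ev_idx] < t) ev_idx <- ev_idx + 1L
  repeat {
    while (ti <= length(times) && times[ti] <= t) { record(times[ti]); ti <- ti + 1L }
    if (t >= t_end) break
    tot <- t(vapply(as.character(tissue$cell_ids),
                    function(id) cell_totals(tissue$states[[id]]),
                    numeric(3)))
    sig <- aggregate_signals(tot, tissue$graph)
    fx <- as.numeric(ndr_rhs(tot / om, sig / om, params))
    dtau <- adaptive_chunk(as.numeric(tot) / om, fx, params)
    t_ev <- if (ev_idx <= n_ev) events$time[ev_idx] else Inf
    t_out <- if (ti <= length(times)) times[ti] else Inf
    t_next <- min(t + dtau, t_ev, t_out, t_end)
    advance_cells(t_next - t, sig)
    t <- t_next
    tissue$time <- t
    # events are processed before anything else at exact ties
    while (ev_idx <= n_ev && events$time[ev_idx] <= t) {
      tissue <- apply_event(tissue, events[ev_idx, ])
      tissue$time <- t
      ev_idx <- ev_idx + 1L
    }
  }
  out <- do.call(rbind, rec)
  attr(out, "tissue") <- tissue
  out
}
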