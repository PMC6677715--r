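#' Deterministic right-hand side of the Notch-Delta-Reporter model
#'
#' Evaluates the ODE form of the three-species lateral-inhibition pathway
#' for every cell. With per-cell concentrations (n, d, r) and precomputed
#' weighted signals (d_in, d_out, n_in):
#' \deqn{n' = \beta_n - d_{in} n / k_t - d n / k_c - n}
#' \deqn{d' = \beta_d / (1 + r^m) - d\, n_{in} / k_t - d n / k_c - d}
#' \deqn{r' = \beta_r (d_{out} n)^s / (k_{rs} + (d_{out} n)^s) - r}
#'
#' @param state n x 3 matrix of per-cell concentrations (columns n, d, r),
#'   non-negative.
#' @param signals n x 3 matrix of per-cell signals (columns d_in, d_out,
#'   n_in) in the same concentration units, non-negative.
#' @param params a \code{"pathway_params"}.
#' @return n x 3 matrix of time derivatives.
#' @examples
#' ndr_rhs(rbind(c(0, 0, 0)), rbind(c(0, 0, 0)), pathway_params())
#' @export
ndr_rhs <- function(state, signals, params = pathway_params()) {
  state <- rbind(state); signals <- rbind(signals)
  if (any(state < 0) || any(signals < 0))
    stop("ndr_rhs: state and signals must be non-negative", call. = FALSE)
  if (nrow(state) != nrow(signals))
    stop("ndr_rhs: state/signals shape mismatch", call. = FALSE)
  n <- state[, 1]; d <- state[, 2]; r <- state[, 3]
  d_in <- signals[, 1]; d_out <- signals[, 2]; n_in <- signals[, 3]
  act <- (d_out * n)^params$s
  cbind(n = params$beta_n - d_in * n / params$k_t - d * n / params$k_c - n,
        d = params$beta_d / (1 + r^params$m) -
          d * n_in / params$k_t - d * n / params$k_c - d,
        r = params$beta_r * act / (params$k_rs + act) - r)
}

#' Classical two-species lateral-inhibition right-hand side
#'
#' The original Notch-Delta feedback model without reporter or protrusions:
#' \code{n' = f(<d>) - n}, \code{d' = const * (g(n) - d)}, where \code{<d>}
#' is the mean Delta over the junctional neighbors, \code{f} is monotone
#' increasing and \code{g} monotone decreasing. The defaults are Hill-type:
#' \code{f(x) = x^2/(0.01 + x^2)}, \code{g(x) = 1/(1 + 100 x^2)}, with the
#' constant equal to 1.
#'
#' @param state n x 2 matrix of per-cell (n, d).
#' @param neighbor_mean_d numeric vector: mean Delta over each cell's
#'   junctional neighbors (zero for an isolated cell).
#' @param f,g activation and repression maps, vectorized.
#' @param params a \code{"pathway_params"} (only \code{collier_const} is
#'   used).
#' @return n x 2 matrix of derivatives.
#' @examples
#' collier_rhs(rbind(c(2, 3)), 0, f = function(x) 0 * x,
#'             g = function(x) 0 * x)
#' @export
collier_rhs <- function(state, neighbor_mean_d,
                        f = function(x) x^2 / (0.01 + x^2),
                        g = function(x) 1 / (1 + 100 * x^2),
                        params = pathway_params()) {
  state <- rbind(state)
  if (length(neighbor_mean_d) == 1L)
    neighbor_mean_d <- rep(neighbor_mean_d, nrow(state))
  if (length(neighbor_mean_d) != nrow(state))
    stop("collier_rhs: shape mismatch", call. = FALSE)
  n <- state[, 1]; d <- state[, 2]
  cbind(n = f(neighbor_mean_d) - n,
        d = params$collier_const * (g(n) - d))
}

#' Mean Delta over junctional neighbors
#'
#' Helper for the classical two-species model: averages a per-cell value
#' over each cell's junctional neighbor set (zero where a cell has none).
#'
#' @param d per-cell numeric vector.
#' @param lattice a \code{"lattice"}.
#' @return numeric vector of neighbor means.
#' @export
neighbor_mean <- function(d, lattice) {
  vapply(lattice$adj, function(nb) if (length(nb)) mean(d[nb]) else 0,
         numeric(1))
}

#' Stochastic reaction propensities of one cell
#'
#' Returns the nine reaction propensities of the well-stirred stochastic
#' interpretation at molecule counts (N, D, R) and count-unit signals, in
#' the fixed channel order: Notch production \code{beta_n * Omega}; Delta
#' production \code{beta_d * Omega * r1} with
#' \code{r1 = 1/(1 + (R/Omega)^m)}; reporter production
#' \code{beta_r * Omega * r2} with
#' \code{r2 = u^s/(k_rs + u^s)}, \code{u = d_out * N / Omega^2};
#' signal-mediated degradations \code{N * d_in/(k_t Omega)} and
#' \code{D * n_in/(k_t Omega)}; cis annihilation \code{N * D/(k_c Omega)};
#' and the linear decays \code{N}, \code{D}, \code{R}.
#'
#' @param counts length-3 non-negative integer vector (N, D, R), or an
#'   n x 3 matrix for several cells.
#' @param signals length-3 vector (d_in, d_out, n_in) in count units, or an
#'   n x 3 matrix.
#' @param params a \code{"pathway_params"}.
#' @return numeric vector of 9 propensities (or n x 9 matrix).
#' @examples
#' ndr_propensities(c(0, 0, 0), c(0, 0, 0), pathway_params())
#' @export
ndr_propensities <- function(counts, signals, params = pathway_params()) {
  cm <- rbind(counts); sm <- rbind(signals)
  if (any(cm < 0) || any(sm < 0))
    stop("ndr_propensities: counts and signals must be non-negative",
         call. = FALSE)
  om <- params$omega
  N <- cm[, 1]; D <- cm[, 2]; R <- cm[, 3]
  d_in <- sm[, 1]; d_out <- sm[, 2]; n_in <- sm[, 3]
  r1 <- 1 / (1 + (R / om)^params$m)
  u <- (d_out * N / om^2)^params$s
  r2 <- ifelse(u > 0, u / (params$k_rs + u), 0)
  a <- cbind(params$beta_n * om,
             params$beta_d * om * r1,
             params$beta_r * om * r2,
             N * d_in / (params$k_t * om),
             D * n_in / (params$k_t * om),
             N * D / (params$k_c * om),
             N, D, R)
  colnames(a) <- c("prod_N", "prod_D", "prod_R", "deg_N_trans",
                   "deg_D_trans", "cis_ND", "deg_N", "deg_D", "deg_R")
  if (is.matrix(counts)) a else drop(a)
}

#' Adaptive signal-freezing chunk length
#'
#' The cell-to-cell signals are frozen over chunks \code{[t, t + dtau)};
#' the chunk is chosen conservatively so that a forward-Euler step of the
#' deterministic model would change the state by about the safety fraction
#' (default 5\%) in a norm-wise sense:
#' \code{dtau = chunk_safety * ||x|| / ||f(x)||} with the Euclidean norm
#' over the concatenated concentration vector of the whole population.
#' The result is clipped to \code{[dtau_min, dtau_max]}; at equilibrium
#' (\code{||f|| = 0}) it is \code{dtau_max}, and for a zero state with
#' non-zero drift \code{dtau_min}.
#'
#' @param x concatenated concentration vector (all cells, all species).
#' @param fx the drift \code{ndr_rhs} evaluated at \code{x}, concatenated
#'   the same way.
#' @param params a \code{"pathway_params"}.
#' @return scalar chunk length dtau.
#' @examples
#' adaptive_chunk(c(1, 0), c(2, 0), pathway_params())  # 0.025
#' @export
adaptive_chunk <- function(x, fx, params = pathway_params()) {
  nf <- sqrt(sum(fx^2))
  nx <- sqrt(sum(x^2))
  if (nf == 0) return(params$dtau_max)
  if (nx == 0) return(params$dtau_min)
  min(params$dtau_max, max(params$dtau_min, params$chunk_safety * nx / nf))
}

# next seed for a compiled kernel, drawn from the R stream so that runs are
# reproducible under set.seed()
draw_seed <- function() {
  floor(stats::runif(1) * 2^31)
}

#' Gillespie simulation of a signaling cell population
#'
#' Simulates the well-stirred stochastic pathway over a static contact
#' graph with the split-step signal-freezing scheme: repeatedly (i) compute
#' all cells' signals from the current counts, (ii) choose the chunk length
#' by \code{\link{adaptive_chunk}} on the population concentration vector,
#' (iii) advance every cell independently by Gillespie's direct method over
#' the chunk with signals frozen; until \code{t_end}.
#'
#' @param initial n x 3 integer matrix of per-cell (N, D, R) counts.
#' @param contacts a \code{"contact_graph"} for the same cells.
#' @param params a \code{"pathway_params"}.
#' @param t_end simulation horizon (>= 0).
#' @param seed integer seed fixing the whole trajectory; \code{NULL} uses
#'   the current RNG state.
#' @param times output times (defaults to \code{t_end} only).
#' @param channels logical vector of length 9 enabling individual reaction
#'   channels (in the documented order); all enabled by default.
#' @return A data frame with columns \code{time}, \code{cell}, \code{N},
#'   \code{D}, \code{R}, in long format, at the requested output times.
#' @examples
#' lat <- build_hex_lattice(3, 3)
#' g <- contact_graph(lat, protrusion_spec(3.5), pathway_params())
#' init <- random_initial_counts(9, pathway_params(), seed = 1)
#' traj <- ssa_population(init, g, pathway_params(), t_end = 1, seed = 1)
#' @export
ssa_population <- function(initial, contacts, params = pathway_params(),
                           t_end, seed = NULL, times = NULL,
                           channels = rep(TRUE, 9)) {
  if (t_end < 0) stop("t_end must be non-negative", call. = FALSE)
  initial <- rbind(initial)
  stopifnot(inherits(contacts, "contact_graph"),
            nrow(initial) == contacts$n, length(channels) == 9L)
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(as.integer(initial), nrow(initial), 3)
  times <- sort(unique(if (is.null(times)) t_end else times))
  if (any(times < 0) || any(times > t_end))
    stop("output times must lie in [0, t_end]", call. = FALSE)
  en <- as.integer(channels)
  pv <- params_vec(params)
  om <- params$omega
  n <- nrow(counts)
  rec <- vector("list", length(times))
  t <- 0
  ti <- 1L
  while (ti <= length(times) && times[ti] <= t) {
    rec[[ti]] <- data.frame(time = times[ti], cell = seq_len(n),
                            N = counts[, 1], D = counts[, 2], R = counts[, 3])
    ti <- ti + 1L
  }
  while (t < t_end && ti <= length(times)) {
    sig <- aggregate_signals(counts, contacts)
    x <- as.numeric(counts) / om
    fx <- as.numeric(ndr_rhs(counts / om, sig / om, params))
    dtau <- adaptive_chunk(x, fx, params)
    t_next <- min(t + dtau, times[ti], t_end)
    if (t_next > t)
      counts <- ssa_chunk_cpp(counts, sig, pv, en, t_next - t, draw_seed())
    t <- t_next
    while (ti <= length(times) && times[ti] <= t) {
      rec[[ti]] <- data.frame(time = times[ti], cell = seq_len(n),
                              N = counts[, 1], D = counts[, 2],
                              R = counts[, 3])
      ti <- ti + 1L
    }
  }
  do.call(rbind, rec)
}

#' Random initial molecule counts
#'
#' The default random initial configuration for pattern-formation runs:
#' per cell and species, counts are Poisson with mean \code{Omega * u},
#' \code{u ~ Uniform(0, 1)} drawn independently per cell and species, for
#' N and D; the reporter starts at 0.
#'
#' @param n_cells number of cells.
#' @param params a \code{"pathway_params"} (for \code{omega}).
#' @param seed optional integer seed.
#' @return n x 3 integer matrix of (N, D, R) counts.
#' @export
random_initial_counts <- function(n_cells, params = pathway_params(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  om <- params$omega
  cbind(N = stats::rpois(n_cells, om * stats::runif(n_cells)),
        D = stats::rpois(n_cells, om * stats::runif(n_cells)),
        R = rep(0L, n_cells))
}

#' Deterministic solution of the pathway ODEs
#'
#' Integrates the per-cell ODE system with a static contact graph (signals
#' recomputed continuously from the current concentrations) or, for an
#' isolated cell, with zero signals. Uses \pkg{deSolve}.
#'
#' @param init n x 3 matrix of initial concentrations.
#' @param contacts a \code{"contact_graph"} or \code{NULL} for isolated
#'   cells (all signals zero).
#' @param params a \code{"pathway_params"}.
#' @param times output times.
#' @return deSolve output matrix: first column time, then the concatenated
#'   concentrations (all n, then all d, then all r).
#' @export
ndr_ode <- function(init, contacts = NULL, params = pathway_params(),
                    times) {
  init <- rbind(init)
  n <- nrow(init)
  deriv <- function(t, y, parms) {
    st <- matrix(pmax(y, 0), n, 3)
    sig <- if (is.null(contacts)) matrix(0, n, 3)
           else aggregate_signals(st, contacts)
    list(as.numeric(ndr_rhs(st, sig, params)))
  }
  deSolve::ode(y = as.numeric(init), times = times, func = deriv,
               parms = NULL)
}

#' Write a trajectory to CSV
#'
#' @param traj trajectory data frame from \code{\link{ssa_population}} or
#'   \code{\link{run_coupled}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}
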