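#' Notch-Delta-Reporter pathway parameters
#'
#' Container for all rate constants, Hill coefficients, signal weights and
#' numerical safety factors of the Notch-Delta-Reporter lateral-inhibition
#' model with protrusional signaling. The defaults are the non-dimensional
#' baseline used throughout the package: production strengths
#' \code{c(beta_n, beta_d, beta_r) = c(100, 500, 3e5)}, interaction constants
#' \code{c(k_t, k_c, k_rs) = c(2, 0.5, 1e7)}, Hill coefficients
#' \code{m = s = 2}, system volume \code{omega = 400}, and unit signal
#' weights.
#'
#' @param beta_n,beta_d,beta_r production strengths of Notch, Delta and the
#'   Notch reporter (non-dimensional rates).
#' @param k_t trans-interaction constant: half-saturation of the mutual
#'   Notch/Delta degradation driven by neighbor signals.
#' @param k_c cis-interaction constant for within-cell Notch-Delta
#'   annihilation.
#' @param k_rs half-saturation constant of reporter activation (units of
#'   squared concentration raised to \code{s}).
#' @param m,s Hill coefficients of reporter repression of Delta and of
#'   reporter activation; positive integers.
#' @param omega system volume: molecules per unit concentration in the
#'   stochastic interpretation.
#' @param w_a,w_b weights of junctional and protrusional contributions to
#'   incoming Delta/Notch signals.
#' @param q_a,q_b weights of junctional and protrusional contributions to
#'   outgoing (receptor-activating) Delta.
#' @param chunk_safety safety factor of the adaptive signal-freezing step:
#'   the chunk length is chosen so that a forward-Euler step would change
#'   the state by about this relative amount (default 0.05, i.e. 5\%).
#' @param dtau_min,dtau_max bounds on the adaptive chunk length, guarding
#'   the degenerate limits (equilibrium gives an unbounded step, a zero
#'   state a vanishing one).
#' @param collier_const the constant multiplying the Delta equation of the
#'   classical two-species lateral-inhibition model (ratio of decay time
#'   scales); defaults to 1.
#'
#' @return An object of class \code{"pathway_params"}: a validated named
#'   list.
#' @examples
#' p <- pathway_params()
#' p$beta_d
#' @export
pathway_params <- function(beta_n = 100, beta_d = 500, beta_r = 3e5,
                           k_t = 2, k_c = 0.5, k_rs = 1e7,
                           m = 2L, s = 2L, omega = 400,
                           w_a = 1, w_b = 1, q_a = 1, q_b = 1,
                           chunk_safety = 0.05,
                           dtau_min = 1e-6, dtau_max = 0.5,
                           collier_const = 1) {
  p <- list(beta_n = beta_n, beta_d = beta_d, beta_r = beta_r,
            k_t = k_t, k_c = k_c, k_rs = k_rs,
            m = as.integer(m), s = as.integer(s), omega = omega,
            w_a = w_a, w_b = w_b, q_a = q_a, q_b = q_b,
            chunk_safety = chunk_safety,
            dtau_min = dtau_min, dtau_max = dtau_max,
            collier_const = collier_const)
  validate_pathway_params(p)
  structure(p, class = "pathway_params")
}

validate_pathway_params <- function(p) {
  pos <- c("k_t", "k_c", "k_rs", "omega",
           "chunk_safety", "dtau_min", "dtau_max", "collier_const")
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("pathway_params: '", f, "' must be a single positive number",
           call. = FALSE)
  }
  # production strengths may be zero (a zero beta disables that channel)
  for (f in c("beta_n", "beta_d", "beta_r")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("pathway_params: '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  for (f in c("m", "s")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("pathway_params: '", f, "' must be a positive integer",
           call. = FALSE)
  }
  for (f in c("w_a", "w_b", "q_a", "q_b")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("pathway_params: '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (p$dtau_min > p$dtau_max)
    stop("pathway_params: 'dtau_min' must not exceed 'dtau_max'",
         call. = FALSE)
  invisible(p)
}

# params vector in the fixed layout the C++ kernels expect
params_vec <- function(params) {
  c(params$beta_n, params$beta_d, params$beta_r,
    params$k_t, params$k_c, params$k_rs,
    params$m, params$s, params$omega)
}

#' @export
print.pathway_params <- function(x, ...) {
  cat("Notch-Delta-Reporter pathway parameters\n")
  cat(sprintf("  production  beta = [%g, %g, %g]\n",
              x$beta_n, x$beta_d, x$beta_r))
  cat(sprintf("  saturation  k    = [%g, %g, %g]   Hill m = %d, s = %d\n",
              x$k_t, x$k_c, x$k_rs, x$m, x$s))
  cat(sprintf("  volume Omega = %g\n", x$omega))
  cat(sprintf("  weights [w_a, q_a, w_b, q_b] = [%g, %g, %g, %g]\n",
              x$w_a, x$q_a, x$w_b, x$q_b))
  cat(sprintf("  chunk safety = %g  (dtau in [%g, %g])\n",
              x$chunk_safety, x$dtau_min, x$dtau_max))
  invisible(x)
}

#' Growth and movement parameters of the cell-population layer
#'
#' Parameters of nutrient-limited proliferation and pressure-driven movement
#' on the population lattice. Nutrient enters at the population boundary at
#' concentration \code{c_b}, diffuses through the population, and is consumed
#' at rate \code{kappa} per cell; a cell in a singly occupied voxel whose
#' nutrient concentration is at least \code{c_thr} divides at rate \code{mu}.
#' Pressure currents are converted to movement rates by the factor
#' \code{d_move}.
#'
#' @param kappa nutrient consumption per cell (concentration per unit time).
#' @param mu proliferation rate of a nutrient-sufficient cell.
#' @param c_thr nutrient threshold below which a cell does not divide.
#' @param c_b boundary nutrient concentration.
#' @param d_move conversion factor from pressure current to movement rate.
#' @param target_size population size at which a growth simulation stops
#'   (\code{Inf} to run to a time horizon instead).
#' @param keep_connected zero the conversion factor for moves that would
#'   fragment the populated set (default \code{TRUE}); see
#'   \code{\link{movement_rates}}.
#' @return An object of class \code{"growth_params"}.
#' @examples
#' growth_params(target_size = 300)
#' @export
growth_params <- function(kappa = 0.02, mu = 1, c_thr = 0.5, c_b = 1,
                          d_move = 1, target_size = Inf,
                          keep_connected = TRUE) {
  for (f in c("kappa", "mu", "c_thr", "c_b", "d_move")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("growth_params: '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (!is.numeric(target_size) || length(target_size) != 1L ||
      is.na(target_size) || target_size < 1)
    stop("growth_params: 'target_size' must be >= 1", call. = FALSE)
  structure(list(kappa = kappa, mu = mu, c_thr = c_thr, c_b = c_b,
                 d_move = d_move, target_size = target_size,
                 keep_connected = isTRUE(keep_connected)),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Population growth parameters\n")
  cat(sprintf("  nutrient: consumption kappa = %g, boundary c_b = %g, threshold c_thr = %g\n",
              x$kappa, x$c_b, x$c_thr))
  cat(sprintf("  division rate mu = %g, movement factor D = %g, target size = %g\n",
              x$mu, x$d_move, x$target_size))
  invisible(x)
}
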