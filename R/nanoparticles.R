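# Boltzmann-equilibrium allocation of charged nanoparticles over a map of
# cell potentials.

#' Nanoparticle specification
#'
#' @param total_count Fixed number of particles to distribute (>= 0).
#' @param valence Dimensionless particle charge number; positive = cationic
#'   (default 1). Cationic particles accumulate around hyperpolarized
#'   (negative-potential) cells.
#' @return An object of class `nanoparticle_spec`.
#' @export
nanoparticle_spec <- function(total_count = 10000, valence = 1) {
  total_count <- as.integer(total_count)
  if (is.na(total_count) || total_count < 0)
    stop("total_count must be a non-negative integer", call. = FALSE)
  structure(list(total_count = total_count, valence = valence),
            class = "nanoparticle_spec")
}

#' Boltzmann weights over a potential map
#'
#' Equilibrium occupancy of each cell's neighborhood,
#' `w_i = exp(-z V_i / V_T) / sum_j exp(-z V_j / V_T)`. The electrostatic
#' energy of a particle of valence z at potential V is z e V, so for
#' cationic particles (z > 0) the weight decreases strictly with V and the
#' hyperpolarized cells attract the most particles. The maximum exponent is
#' shifted out before exponentiation, which also makes the weights exactly
#' invariant under adding a constant to every potential.
#'
#' @param V_map Potentials in millivolts (vector or matrix; finite).
#' @param valence Particle charge number z.
#' @param V_T Thermal potential in millivolts (> 0).
#' @return Numeric weights of the same shape as `V_map`, summing to 1.
#' @examples
#' w <- boltzmann_weights(c(-60, 0), valence = 1, V_T = 27)
#' w[1] / w[2]  # exp(60 / 27), about 9.23
#' @export
boltzmann_weights <- function(V_map, valence = 1, V_T = 27) {
  if (any(!is.finite(V_map))) stop("potentials must be finite", call. = FALSE)
  if (V_T <= 0) stop("V_T must be > 0", call. = FALSE)
  e <- -valence * V_map / V_T
  w <- exp(e - max(e))
  w / sum(w)
}

#' Integer allocation of particles to cells
#'
#' Largest-remainder (Hamilton) rounding of the real-valued quotas
#' `N_p * w_i`: each cell receives the floor of its quota and the leftover
#' particles go to the cells with the largest fractional remainders, ties
#' broken by cell index. Counts sum to `N_p` exactly and each count is
#' within 1 of its quota.
#'
#' @param N_p Total particle count (non-negative integer).
#' @param weights Normalized weights (sum to 1 within tolerance).
#' @return Integer counts, same shape as `weights`, summing to `N_p`.
#' @export
allocate_particles <- function(N_p, weights) {
  N_p <- as.integer(N_p)
  if (is.na(N_p) || N_p < 0) stop("N_p must be a non-negative integer", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  quota <- N_p * as.numeric(weights)
  counts <- floor(quota)
  leftover <- N_p - as.integer(sum(counts))
  if (leftover > 0) {
    rem <- quota - counts
    ord <- order(-rem, seq_along(rem))  # ties to the lower cell index
    counts[ord[seq_len(leftover)]] <- counts[ord[seq_len(leftover)]] + 1
  }
  counts <- as.integer(counts)
  if (!is.null(dim(weights))) dim(counts) <- dim(weights)
  counts
}

#' Distribute nanoparticles over an ensemble snapshot
#'
#' Convenience wrapper: computes Boltzmann weights from the millivolt
#' potential map of a state and allocates the particle budget.
#'
#' @param state An `ensemble_state`.
#' @param model A `membrane_model` (for V_T and the mV conversion).
#' @param spec A `nanoparticle_spec`.
#' @return A data.frame with one row per cell: `cell_row`, `cell_col`,
#'   `V_mV`, `weight`, `count`.
#' @export
distribute_nanoparticles <- function(state, model, spec = nanoparticle_spec()) {
  stopifnot(inherits(state, "ensemble_state"), inherits(spec, "nanoparticle_spec"))
  V <- as_grid(state, model)
  w <- boltzmann_weights(V, valence = spec$valence, V_T = model$V_T)
  cnt <- allocate_particles(spec$total_count, w)
  data.frame(
    cell_row = rep(seq_len(nrow(V)), times = ncol(V)),
    cell_col = rep(seq_len(ncol(V)), each = nrow(V)),
    V_mV = as.vector(V),
    weight = as.vector(w),
    count = as.vector(cnt))
}
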