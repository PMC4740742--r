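# Gap-junction-coupled square lattice. Cells are indexed column-major
# (R matrix order): cell (r, c) on a rows x cols grid is element
# (c - 1) * rows + r of the state vector. The dimensionless dynamics are
#   dv_i/dt_hat = -i_total(v_i) + sum_nn g_ij (v_j - v_i)
# integrated with a constant-matrix IMEX scheme: the linear coupling is
# implicit, the nonlinear channel current explicit.

#' Square-lattice specification
#'
#' A rows x cols grid of cells with the 4-neighbor (von Neumann)
#' neighborhood and truncated boundaries: edge cells simply have fewer
#' neighbors (degree 4 interior, 3 edge, 2 corner), the discrete analogue
#' of a no-flux boundary for a finite patch of tissue.
#'
#' @param rows,cols Positive integer grid dimensions.
#' @return An object of class `lattice_spec` with `rows`, `cols` and
#'   `n = rows * cols`.
#' @export
lattice_spec <- function(rows, cols = rows) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L)
    stop("lattice dimensions must be positive integers", call. = FALSE)
  structure(list(rows = rows, cols = cols, n = rows * cols),
            class = "lattice_spec")
}

# Edge list of the 4-neighbor lattice: two-column matrix of cell indices,
# each undirected edge once (i < j).
lattice_edges <- function(lattice) {
  r <- lattice$rows; cc <- lattice$cols
  idx <- matrix(seq_len(r * cc), nrow = r)
  vert <- if (r > 1L) cbind(as.vector(idx[-r, , drop = FALSE]),
                            as.vector(idx[-1, , drop = FALSE])) else
    matrix(integer(0), ncol = 2)
  horz <- if (cc > 1L) cbind(as.vector(idx[, -cc, drop = FALSE]),
                             as.vector(idx[, -1, drop = FALSE])) else
    matrix(integer(0), ncol = 2)
  rbind(vert, horz)
}

#' Gap-junction coupling parameters
#'
#' @param g Dimensionless junction conductance ratio `G / G_ref`, either a
#'   single value applied to every lattice edge or a vector with one value
#'   per edge (ordering of [build_laplacian()]'s edge list). Must be >= 0.
#' @param capacitance_ratio Dimensionless junction capacitance ratio.
#'   Accepted for forward compatibility but must be 0: the junction
#'   capacitive term is dominated by the conductive one at physiological
#'   values and is dropped from the dynamics.
#' @return An object of class `coupling_params`.
#' @export
coupling_params <- function(g = 0.25, capacitance_ratio = 0) {
  if (!is.numeric(g) || any(!is.finite(g)) || any(g < 0))
    stop("junction conductance ratio g must be >= 0", call. = FALSE)
  if (!identical(as.numeric(capacitance_ratio), 0))
    stop("junction capacitance_ratio must be 0 in this version", call. = FALSE)
  structure(list(g = as.numeric(g), capacitance_ratio = 0),
            class = "coupling_params")
}

#' Graph Laplacian of the coupled lattice
#'
#' Builds the symmetric positive semi-definite sparse matrix L with
#' `L[i, j] = -g_ij` on lattice edges and row sums zero, so that the
#' coupling term of the dynamics is `-(L v)_i = sum_nn g_ij (v_j - v_i)`.
#'
#' @param lattice A `lattice_spec`.
#' @param coupling A `coupling_params` (scalar or per-edge `g`).
#' @return A `dsCMatrix` sparse symmetric matrix of dimension n x n.
#' @export
build_laplacian <- function(lattice, coupling) {
  stopifnot(inherits(lattice, "lattice_spec"), inherits(coupling, "coupling_params"))
  edges <- lattice_edges(lattice)
  g <- coupling$g
  if (length(g) == 1L) g <- rep(g, nrow(edges))
  if (length(g) != nrow(edges))
    stop("per-edge g must have one value per lattice edge (",
         nrow(edges), ")", call. = FALSE)
  n <- lattice$n
  if (nrow(edges) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n), symmetric = TRUE))
  deg <- numeric(n)
  for (k in seq_len(nrow(edges))) {
    deg[edges[k, 1]] <- deg[edges[k, 1]] + g[k]
    deg[edges[k, 2]] <- deg[edges[k, 2]] + g[k]
  }
  Matrix::sparseMatrix(
    i = c(edges[, 1], seq_len(n)),
    j = c(edges[, 2], seq_len(n)),
    x = c(-g, deg),
    dims = c(n, n), symmetric = TRUE)
}

#' Ensemble state
#'
#' Per-cell dimensionless membrane potentials on the lattice at a given
#' dimensionless time. The reference potential of the extracellular
#' microenvironment is zero.
#'
#' @param v Numeric vector of length `lattice$n` (column-major cell order)
#'   or a rows x cols matrix.
#' @param lattice A `lattice_spec`.
#' @param t_hat Dimensionless time of the snapshot.
#' @return An object of class `ensemble_state`.
#' @export
ensemble_state <- function(v, lattice, t_hat = 0) {
  stopifnot(inherits(lattice, "lattice_spec"))
  if (is.matrix(v)) {
    if (!all(dim(v) == c(lattice$rows, lattice$cols)))
      stop("state matrix shape does not match lattice", call. = FALSE)
    v <- as.vector(v)
  }
  if (length(v) != lattice$n || any(!is.finite(v)))
    stop("state must be ", lattice$n, " finite values", call. = FALSE)
  structure(list(v = as.numeric(v), lattice = lattice, t_hat = t_hat),
            class = "ensemble_state")
}

#' Reshape an ensemble state to its grid
#'
#' @param state An `ensemble_state`.
#' @param model Optional `membrane_model`; if given, the grid is returned in
#'   millivolts instead of dimensionless units.
#' @return A rows x cols numeric matrix.
#' @export
as_grid <- function(state, model = NULL) {
  stopifnot(inherits(state, "ensemble_state"))
  v <- state$v
  if (!is.null(model)) v <- dimensionalize(v, model, "potential")
  matrix(v, nrow = state$lattice$rows, ncol = state$lattice$cols)
}

#' Per-cell channel fields
#'
#' The only spatially varying single-cell parameter is the conductance
#' ratio `G_out / G_in`; the equilibrium potentials, thresholds and gating
#' charge are global constants of the membrane model.
#'
#' @param ratio `G_out / G_in` as a single value, a length-n vector or a
#'   rows x cols matrix (>= 0 everywhere).
#' @param lattice A `lattice_spec`.
#' @return An object of class `cell_fields` with vector element `ratio`.
#' @export
cell_fields <- function(ratio, lattice) {
  stopifnot(inherits(lattice, "lattice_spec"))
  if (is.matrix(ratio)) {
    if (!all(dim(ratio) == c(lattice$rows, lattice$cols)))
      stop("ratio grid shape does not match lattice", call. = FALSE)
    ratio <- as.vector(ratio)
  }
  if (length(ratio) == 1L) ratio <- rep(ratio, lattice$n)
  if (length(ratio) != lattice$n)
    stop("ratio field must have one value per cell", call. = FALSE)
  if (any(!is.finite(ratio)) || any(ratio < 0))
    stop("conductance ratio must be finite and >= 0", call. = FALSE)
  structure(list(ratio = as.numeric(ratio), lattice = lattice),
            class = "cell_fields")
}

#' Explicit (channel) part of the lattice dynamics
#'
#' Returns `-i_total(v_i)` per cell in dimensionless units, evaluating the
#' two-channel current with each cell's local `G_out / G_in`.
#'
#' @param state An `ensemble_state`.
#' @param fields A `cell_fields` on the same lattice.
#' @param model A `membrane_model`.
#' @return Numeric vector of length n.
#' @export
channel_rhs <- function(state, fields, model) {
  stopifnot(inherits(state, "ensemble_state"), inherits(fields, "cell_fields"),
            inherits(model, "membrane_model"))
  if (fields$lattice$n != state$lattice$n)
    stop("fields and state lattices differ", call. = FALSE)
  V <- dimensionalize(state$v, model, "potential")
  I <- total_current(V, model, ratio = fields$ratio)
  -nondimensionalize(I, model, "current")
}

#' Constant IMEX step matrix
#'
#' `A = I + dt_hat * L`, assembled once and reused for every step of a run.
#' A is symmetric positive definite (smallest eigenvalue >= 1).
#'
#' @param laplacian Sparse Laplacian from [build_laplacian()].
#' @param dt_hat Dimensionless time step (> 0).
#' @return A list of class `step_matrix` holding the matrix `A`, its sparse
#'   Cholesky factorization, and `dt_hat`.
#' @export
assemble_step_matrix <- function(laplacian, dt_hat) {
  if (!is.numeric(dt_hat) || length(dt_hat) != 1L || dt_hat <= 0)
    stop("dt_hat must be a positive number", call. = FALSE)
  n <- nrow(laplacian)
  A <- Matrix::Diagonal(n) + dt_hat * laplacian
  A <- Matrix::forceSymmetric(A)
  fact <- Matrix::Cholesky(A, LDL = FALSE)
  structure(list(A = A, factorization = fact, dt_hat = dt_hat),
            class = "step_matrix")
}

#' One IMEX time step
#'
#' The splitting follows the constant-matrix scheme: the right-hand side
#' `B_i = dt_hat * [channel_rhs(v^n)_i - (L v^n)_i]` collects the explicit
#' channel current and the coupling residual at the current state, the
#' linear system `A dv = B` is solved with the prefactored Cholesky
#' decomposition, and `v^(n+1) = v^n + dv`. A uniform state with zero
#' channel current is exactly stationary; as `dt_hat -> 0` the step agrees
#' with explicit Euler to O(dt_hat^2).
#'
#' @param state An `ensemble_state`.
#' @param step_matrix A `step_matrix` from [assemble_step_matrix()]
#'   (assembled for this lattice and `dt_hat`).
#' @param fields A `cell_fields`.
#' @param model A `membrane_model`.
#' @param laplacian The Laplacian used to assemble `step_matrix`.
#' @return The advanced `ensemble_state` (time advanced by `dt_hat`).
#' @export
step_ensemble <- function(state, step_matrix, fields, model, laplacian) {
  stopifnot(inherits(step_matrix, "step_matrix"))
  dt <- step_matrix$dt_hat
  B <- dt * (channel_rhs(state, fields, model) -
               as.numeric(laplacian %*% state$v))
  dv <- as.numeric(Matrix::solve(step_matrix$factorization, B, system = "A"))
  if (any(!is.finite(dv))) stop("IMEX solve produced non-finite update", call. = FALSE)
  ensemble_state(state$v + dv, state$lattice, state$t_hat + dt)
}

#' Simulation configuration
#'
#' @param dt_hat Dimensionless time step (default 0.01).
#' @param t_hat_final Dimensionless final time (default 10, i.e. 1 s at the
#'   default `tau = 100` ms).
#' @param snapshot_times Dimensionless times at which to record snapshots;
#'   must lie in `[0, t_hat_final]`. Snapshots are taken at the first step
#'   reaching each requested time.
#' @param steady_state_tol If positive, the run may stop early once
#'   `max |dv| / dt_hat` falls below this tolerance; the stop time is
#'   recorded. 0 disables early stopping.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt_hat = 0.01, t_hat_final = 10,
                       snapshot_times = c(0, t_hat_final),
                       steady_state_tol = 0) {
  if (dt_hat <= 0) stop("dt_hat must be > 0", call. = FALSE)
  if (t_hat_final <= 0) stop("t_hat_final must be > 0", call. = FALSE)
  if (any(snapshot_times < 0 | snapshot_times > t_hat_final + 1e-12))
    stop("snapshot times must lie in [0, t_hat_final]", call. = FALSE)
  structure(list(dt_hat = dt_hat, t_hat_final = t_hat_final,
                 snapshot_times = sort(unique(snapshot_times)),
                 steady_state_tol = steady_state_tol),
            class = "sim_config")
}

#' Integrate the coupled lattice
#'
#' Runs the constant-matrix IMEX scheme from an initial state, recording
#' snapshots at the requested dimensionless times. Deterministic given its
#' inputs.
#'
#' @param initial An `ensemble_state` at `t_hat = 0`.
#' @param fields A `cell_fields`.
#' @param model A `membrane_model`.
#' @param coupling A `coupling_params`.
#' @param config A `sim_config`.
#' @return A list of class `trajectory`: `snapshots` (list of
#'   `ensemble_state`), `final` (the last state), `stopped_early` and
#'   `stop_t_hat` (NA unless the steady-state tolerance triggered).
#' @export
simulate_ensemble <- function(initial, fields, model, coupling, config) {
  stopifnot(inherits(initial, "ensemble_state"), inherits(config, "sim_config"))
  L <- build_laplacian(initial$lattice, coupling)
  A <- assemble_step_matrix(L, config$dt_hat)
  state <- initial
  n_steps <- ceiling(config$t_hat_final / config$dt_hat - 1e-9)
  want <- config$snapshot_times
  snapshots <- list()
  take <- function(s) snapshots[[length(snapshots) + 1L]] <<- s
  if (length(want) && want[1] <= 1e-12) { take(state); want <- want[-1] }
  stopped <- FALSE; stop_t <- NA_real_
  for (k in seq_len(n_steps)) {
    prev <- state$v
    state <- step_ensemble(state, A, fields, model, L)
    while (length(want) && state$t_hat >= want[1] - 1e-9) {
      take(state); want <- want[-1]
    }
    if (config$steady_state_tol > 0 &&
        max(abs(state$v - prev)) / config$dt_hat < config$steady_state_tol) {
      stopped <- TRUE; stop_t <- state$t_hat
      break
    }
  }
  if (length(want)) take(state)  # early stop: remaining requests get the final state
  structure(list(snapshots = snapshots, final = state,
                 stopped_early = stopped, stop_t_hat = stop_t),
            class = "trajectory")
}

#' Initial-condition builder
#'
#' Builds an `ensemble_state` from the stable resting potentials of the
#' local single-cell model: all cells at the hyperpolarized root with,
#' optionally, a centered rectangular patch (default 10 x 10) or an
#' arbitrary logical mask set to the depolarized root.
#'
#' @param lattice A `lattice_spec`.
#' @param pattern `"uniform"`, `"central_patch"` or `"mask"`.
#' @param model A `membrane_model` used to locate the stable roots.
#' @param ratio Conductance ratio at which the roots are computed
#'   (default 1, the bistable reference).
#' @param patch Length-2 (rows, cols) patch size for `"central_patch"`.
#' @param mask Logical rows x cols matrix for `"mask"` (TRUE = depolarized).
#' @param levels Optional length-2 numeric `(hyper, depol)` dimensionless
#'   potentials overriding the computed roots.
#' @return An `ensemble_state` at `t_hat = 0`.
#' @export
make_initial_condition <- function(lattice,
                                   pattern = c("uniform", "central_patch", "mask"),
                                   model = membrane_model(), ratio = 1,
                                   patch = c(10, 10), mask = NULL,
                                   levels = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(inherits(lattice, "lattice_spec"))
  if (is.null(levels)) {
    fp <- find_fixed_points(model, ratio = ratio)
    st <- fp$V_star[fp$stability == "stable"]
    if (length(st) < 1L) stop("local model has no stable root", call. = FALSE)
    hyper <- nondimensionalize(min(st), model, "potential")
    depol <- nondimensionalize(max(st), model, "potential")
  } else {
    hyper <- levels[1]; depol <- levels[2]
  }
  v <- matrix(hyper, lattice$rows, lattice$cols)
  if (pattern == "central_patch") {
    if (any(patch > c(lattice$rows, lattice$cols)))
      stop("patch larger than lattice", call. = FALSE)
    r0 <- floor((lattice$rows - patch[1]) / 2) + 1L
    c0 <- floor((lattice$cols - patch[2]) / 2) + 1L
    v[r0:(r0 + patch[1] - 1L), c0:(c0 + patch[2] - 1L)] <- depol
  } else if (pattern == "mask") {
    if (is.null(mask) || !is.logical(mask) ||
        !all(dim(mask) == c(lattice$rows, lattice$cols)))
      stop("mask must be a logical rows x cols matrix", call. = FALSE)
    v[mask] <- depol
  }
  ensemble_state(v, lattice, t_hat = 0)
}

#' Summary metrics of a potential map
#'
#' A cell counts as depolarized when its potential exceeds the unstable
#' zero-current root of its local single-cell model — the basin boundary of
#' the isolated-cell dynamics. Where the local model is monostable (no
#' unstable root) the cell is classified by which channel equilibrium
#' potential its value is nearer to.
#'
#' @param state An `ensemble_state`.
#' @param model A `membrane_model`.
#' @param fields A `cell_fields` giving each cell's conductance ratio.
#' @return A list: `fraction_depolarized`, `mean_potential_mV`, `min_mV`,
#'   `max_mV`.
#' @export
summarize_state <- function(state, model, fields) {
  stopifnot(inherits(state, "ensemble_state"), inherits(fields, "cell_fields"))
  V <- dimensionalize(state$v, model, "potential")
  thr <- depolarization_threshold(model, fields$ratio)
  list(fraction_depolarized = mean(V > thr),
       mean_potential_mV = mean(V), min_mV = min(V), max_mV = max(V))
}

# Per-cell basin threshold in mV: the local unstable root where the local
# model is bistable, else +/-Inf according to whether the single stable root
# is nearer E_in (never depolarized) or E_out (always depolarized).
# Cached over the distinct ratio values of the field.
depolarization_threshold <- function(model, ratio) {
  uniq <- unique(ratio)
  midpoint <- (model$inward$E + model$outward$E) / 2
  thr_of <- vapply(uniq, function(r) {
    fp <- find_fixed_points(model, ratio = r)
    uns <- fp$V_star[fp$stability == "unstable"]
    if (length(uns)) uns[1]
    else if (fp$V_star[1] <= midpoint) Inf else -Inf
  }, numeric(1))
  thr_of[match(ratio, uniq)]
}
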