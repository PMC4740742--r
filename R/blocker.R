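# Channel-blocker microenvironment: prescribed concentration/ratio profiles
# in 1-D and 2-D, a hyperbolic blocking law, and explicit finite-difference
# diffusion with no-flux boundaries.

#' Blocking law of the outward rectifier
#'
#' Local equilibrium binding of the blocker to the outward-rectifying
#' channel reduces its conductance hyperbolically:
#' `G_out(c) = G_out0 / (1 + K c)`, i.e. the ratio
#' `r(c) = r0 / (1 + K c)` with `r0 = G_out0 / G_in` the unblocked ratio.
#' `r(0) = r0`, r is strictly decreasing in c and tends to 0 (maximum
#' blocking) as c grows. The unblocked conductance may exceed `G_in` under
#' channel upregulation, so `r0 > 1` is allowed.
#'
#' @param K Blocking constant in inverse concentration units (>= 0).
#' @param r0 Unblocked conductance ratio `G_out0 / G_in` (>= 0).
#' @return An object of class `blocking_law`.
#' @export
blocking_law <- function(K, r0) {
  if (!is.numeric(K) || K < 0) stop("blocking constant K must be >= 0", call. = FALSE)
  if (!is.numeric(r0) || r0 < 0) stop("unblocked ratio r0 must be >= 0", call. = FALSE)
  structure(list(K = K, r0 = r0), class = "blocking_law")
}

#' Conductance ratio from blocker concentration
#'
#' @param c_conc Blocker concentration (>= 0, vectorized; arbitrary units —
#'   only the product `K * c` is meaningful).
#' @param law A `blocking_law`.
#' @return `G_out / G_in` values in `(0, r0]`.
#' @examples
#' law <- blocking_law(K = 1, r0 = 2.5)
#' ratio_from_concentration(0, law)   # 2.5 (unblocked)
#' ratio_from_concentration(1, law)   # 1.25 (half blocking at K*c = 1)
#' @export
ratio_from_concentration <- function(c_conc, law) {
  stopifnot(inherits(law, "blocking_law"))
  if (any(!is.finite(c_conc)) || any(c_conc < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  law$r0 / (1 + law$K * c_conc)
}

#' Axial conductance-ratio profile
#'
#' A 1-D profile of `G_out / G_in` along the x (column) direction, constant
#' along y, pinned exactly to `ratio_endpoints` at the first and last
#' columns. Three monotone families are provided: `linear` (arithmetic),
#' `exponential` (geometric, the shape a steady exponential blocker
#' gradient induces through the hyperbolic law) and `logistic` (sigmoidal
#' front, rescaled to hit the endpoints exactly).
#'
#' @param family `"linear"`, `"exponential"` or `"logistic"`.
#' @param lattice A `lattice_spec`.
#' @param ratio_endpoints Length-2 positive `(left, right)` ratios; the
#'   default (0.05, 2.50) spans maximum blocking on the left to unblocked
#'   upregulation on the right.
#' @param steepness Logistic steepness (dimensionless, in units of the
#'   normalized coordinate); ignored by the other families.
#' @return A rows x cols matrix of ratios.
#' @export
make_axial_profile <- function(family = c("linear", "exponential", "logistic"),
                               lattice, ratio_endpoints = c(0.05, 2.50),
                               steepness = 8) {
  family <- match.arg(family)
  stopifnot(inherits(lattice, "lattice_spec"))
  if (any(ratio_endpoints <= 0)) stop("ratio endpoints must be > 0", call. = FALSE)
  r0 <- ratio_endpoints[1]; r1 <- ratio_endpoints[2]
  nc <- lattice$cols
  x <- if (nc > 1L) (seq_len(nc) - 1) / (nc - 1) else 0.5
  vals <- switch(family,
    linear = r0 + (r1 - r0) * x,
    exponential = r0 * (r1 / r0)^x,
    logistic = {
      s <- stats::plogis(steepness * (x - 0.5))
      u <- (s - s[1]) / (s[length(s)] - s[1])
      if (nc == 1L) u <- 0.5
      r0 + (r1 - r0) * u
    })
  matrix(rep(vals, each = lattice$rows), nrow = lattice$rows)
}

#' Two-dimensional cross-shaped ratio profile
#'
#' Emulates a blocker released along the central row and central column of
#' the ensemble: the concentration decays exponentially with the normalized
#' distance to the nearer of the two cross axes,
#' `c(x, y) = max(exp(-a d_x), exp(-a d_y))`, and is mapped to
#' `G_out / G_in` through the hyperbolic blocking law with `K` and the
#' unblocked ratio solved so that the ratio equals `ratio_min` everywhere
#' on the cross (maximum concentration) and `ratio_max` at the four corners
#' (minimum concentration). The profile is symmetric under reflection about
#' either central axis.
#'
#' @param lattice A `lattice_spec` of at least 3 x 3.
#' @param ratio_min,ratio_max Ratios on the cross and at the corners.
#' @param decay Exponential decay rate `a` of the concentration in units of
#'   the half-grid; must satisfy `exp(-a) < ratio_min / ratio_max` so the
#'   blocking law can span the requested range (default 6).
#' @return A rows x cols matrix of ratios.
#' @export
make_2d_profile <- function(lattice, ratio_min = 0.05, ratio_max = 2.5,
                            decay = 6) {
  stopifnot(inherits(lattice, "lattice_spec"))
  if (lattice$rows < 3L || lattice$cols < 3L)
    stop("2-D profile needs a lattice of at least 3 x 3", call. = FALSE)
  if (ratio_min <= 0 || ratio_max <= ratio_min)
    stop("need 0 < ratio_min < ratio_max", call. = FALSE)
  cmin <- exp(-decay)
  if (cmin >= ratio_min / ratio_max)
    stop("decay too shallow: need exp(-decay) < ratio_min / ratio_max",
         call. = FALSE)
  # K and unblocked ratio pinned by r(c=1) = ratio_min, r(c=cmin) = ratio_max
  K <- (ratio_max - ratio_min) / (ratio_min - ratio_max * cmin)
  law <- blocking_law(K, r0 = ratio_min * (1 + K))
  rows <- lattice$rows; cols <- lattice$cols
  dy <- abs(seq_len(rows) - (rows + 1) / 2) / ((rows - 1) / 2)
  dx <- abs(seq_len(cols) - (cols + 1) / 2) / ((cols - 1) / 2)
  conc <- outer(exp(-decay * dy), exp(-decay * dx), pmax)
  ratio_from_concentration(conc, law)
}

#' Explicit diffusion configuration
#'
#' Forward-time centered-space diffusion of the blocker with no-flux
#' boundaries. The explicit stability bound `D dt / dx^2 <= 1/2` (1-D) or
#' `<= 1/4` (2-D) is enforced at construction.
#'
#' @param D Diffusion coefficient in m^2/s (> 0).
#' @param L Domain length in m (> 0).
#' @param n_grid Number of grid cells along the domain.
#' @param dt Time step in s (> 0).
#' @param dimensionality 1 or 2 (a 2-D run uses an L x L square with the
#'   same spacing in both directions).
#' @return An object of class `diffusion_config` with the derived spacing
#'   `dx = L / n_grid` and the stability number `r = D dt / dx^2`.
#' @export
diffusion_config <- function(D, L, n_grid, dt, dimensionality = 1) {
  if (D <= 0 || L <= 0 || dt <= 0 || n_grid < 2)
    stop("D, L, dt must be > 0 and n_grid >= 2", call. = FALSE)
  if (!dimensionality %in% c(1, 2)) stop("dimensionality must be 1 or 2", call. = FALSE)
  dx <- L / n_grid
  r <- D * dt / dx^2
  bound <- if (dimensionality == 1) 0.5 else 0.25
  if (r > bound + 1e-12)
    stop(sprintf(
      "explicit diffusion unstable: D*dt/dx^2 = %.4g exceeds the %s bound %.2g",
      r, if (dimensionality == 1) "1-D" else "2-D", bound), call. = FALSE)
  structure(list(D = D, L = L, n_grid = as.integer(n_grid), dt = dt,
                 dx = dx, r = r, dimensionality = dimensionality),
            class = "diffusion_config")
}

#' Diffuse a blocker concentration field
#'
#' Advances the concentration by `n_steps` forward-time centered-space
#' steps under no-flux (zero-gradient) boundaries. Total mass `sum(c) * dx`
#' (or `* dx^2` in 2-D) is conserved to machine precision and no new
#' extrema are created (discrete maximum principle, guaranteed by the
#' stability bound).
#'
#' @param c_grid Numeric vector (1-D) or matrix (2-D) of concentrations
#'   matching `config$n_grid`.
#' @param config A `diffusion_config`.
#' @param n_steps Number of steps (non-negative integer).
#' @return The advanced field, same shape as `c_grid`.
#' @export
diffuse <- function(c_grid, config, n_steps) {
  stopifnot(inherits(config, "diffusion_config"))
  if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  if (any(!is.finite(c_grid)) || any(c_grid < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  r <- config$r
  if (config$dimensionality == 1) {
    if (!is.null(dim(c_grid)) || length(c_grid) != config$n_grid)
      stop("1-D field must be a vector of length n_grid", call. = FALSE)
    c_cur <- as.numeric(c_grid)
    n <- length(c_cur)
    for (k in seq_len(n_steps)) {
      # ghost cells mirror the boundary values (zero-flux)
      left <- c(c_cur[1], c_cur[-n])
      right <- c(c_cur[-1], c_cur[n])
      c_cur <- c_cur + r * (left - 2 * c_cur + right)
    }
    c_cur
  } else {
    if (!is.matrix(c_grid) || !all(dim(c_grid) == config$n_grid))
      stop("2-D field must be an n_grid x n_grid matrix", call. = FALSE)
    c_cur <- c_grid
    n <- config$n_grid
    for (k in seq_len(n_steps)) {
      up <- rbind(c_cur[1, , drop = FALSE], c_cur[-n, , drop = FALSE])
      down <- rbind(c_cur[-1, , drop = FALSE], c_cur[n, , drop = FALSE])
      lft <- cbind(c_cur[, 1, drop = FALSE], c_cur[, -n, drop = FALSE])
      rgt <- cbind(c_cur[, -1, drop = FALSE], c_cur[, n, drop = FALSE])
      c_cur <- c_cur + r * (up + down + lft + rgt - 4 * c_cur)
    }
    c_cur
  }
}

#' Characteristic diffusional time
#'
#' `tau_d = L^2 / D`: the time for the blocker to spread across an
#' ensemble of length L. For L = 1 mm (about 100 cell diameters) and
#' D = 1e-10 m^2/s this is 1e4 s, roughly three hours — far slower than
#' the electrical relaxation time of the network.
#'
#' @param L Ensemble length in m (> 0).
#' @param D Diffusion coefficient in m^2/s (> 0).
#' @return Time in seconds.
#' @export
diffusion_time <- function(L, D) {
  if (any(L <= 0) || any(D <= 0)) stop("L and D must be > 0", call. = FALSE)
  L^2 / D
}

#' Attach a conductance-ratio grid to the ensemble
#'
#' The channel responds instantaneously to the local blocker concentration
#' (fast blocking reaction), so a steady ratio grid maps pointwise onto the
#' per-cell fields with no lag state.
#'
#' @param ratio_grid A rows x cols matrix of `G_out / G_in` values.
#' @param lattice A `lattice_spec` with matching shape.
#' @return A `cell_fields` object.
#' @export
couple_to_ensemble <- function(ratio_grid, lattice) {
  cell_fields(ratio_grid, lattice)
}
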