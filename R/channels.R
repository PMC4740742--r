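# Single-cell membrane model: two generic voltage-gated rectifier channels
# with Boltzmann gating. Currents are positive outward; the isolated-cell
# dynamics are C * dV/dt = -I_total(V), so zero-current roots with positive
# slope dI/dV are stable.

#' Voltage-gated channel parameters
#'
#' Describes one phenomenological voltage-gated channel by its maximum
#' conductance, equilibrium (reversal) potential, threshold potential (the
#' voltage of half-maximal open probability), effective gating charge and
#' rectification direction.
#'
#' @param G Maximum conductance in nanosiemens (>= 0).
#' @param E Equilibrium potential in millivolts; the channel current is zero
#'   and changes sign at `V = E`.
#' @param V_th Threshold potential in millivolts; `open_probability(V_th)`
#'   is exactly 0.5.
#' @param z Effective gating charge (dimensionless, > 0); sets the steepness
#'   of the gating sigmoid.
#' @param rectification `"inward"` (open at hyperpolarized potentials) or
#'   `"outward"` (open at depolarized potentials).
#' @return An object of class `channel_params`.
#' @examples
#' ch <- channel_params(G = 1, E = -60, V_th = -25, z = 3, "inward")
#' open_probability(-25, ch, V_T = 27)  # 0.5 at threshold
#' @export
channel_params <- function(G, E, V_th, z, rectification = c("inward", "outward")) {
  rectification <- match.arg(rectification)
  stopifnot(is.numeric(G), length(G) == 1L, is.finite(G),
            is.numeric(E), length(E) == 1L, is.finite(E),
            is.numeric(V_th), length(V_th) == 1L, is.finite(V_th),
            is.numeric(z), length(z) == 1L, is.finite(z))
  if (G < 0) stop("channel conductance G must be >= 0", call. = FALSE)
  if (z <= 0) stop("gating charge z must be > 0", call. = FALSE)
  structure(list(G = G, E = E, V_th = V_th, z = z,
                 rectification = rectification),
            class = "channel_params")
}

#' Two-channel membrane model
#'
#' Bundles the inward- and outward-rectifying channel pair with the thermal
#' potential and the reference conductance/capacitance used for
#' nondimensionalization. The defaults are the canonical bistable parameter
#' set: `G_in = G_out = 1` nS, `V_th = -25` mV, `z = 3`, `E_in = -60` mV,
#' `E_out = 0` mV, `V_T = 27` mV, `C_0 = 100` pF.
#'
#' @param inward,outward `channel_params` objects; `inward` must have
#'   `rectification = "inward"` and `outward` the mirror.
#' @param V_T Thermal potential RT/F in millivolts (> 0). Stored as the
#'   literal model constant (27 mV by default, i.e. T = 310 K); see
#'   [thermal_potential()] to compute RT/F for an arbitrary temperature.
#' @param G_ref Reference conductance for nondimensionalization in
#'   nanosiemens; defaults to the inward channel conductance.
#' @param C_0 Reference cell capacitance in picofarads; with `G_ref` it sets
#'   the electrical relaxation time `tau = C_0 / G_ref`.
#' @return An object of class `membrane_model`.
#' @examples
#' m <- membrane_model()
#' total_current(-25, m)  # 5 pA at the shared threshold
#' @export
membrane_model <- function(inward = channel_params(1, -60, -25, 3, "inward"),
                           outward = channel_params(1, 0, -25, 3, "outward"),
                           V_T = 27, G_ref = inward$G, C_0 = 100) {
  stopifnot(inherits(inward, "channel_params"), inherits(outward, "channel_params"))
  if (inward$rectification != "inward" || outward$rectification != "outward")
    stop("channel rectification directions do not match their roles", call. = FALSE)
  if (!is.numeric(V_T) || length(V_T) != 1L || !is.finite(V_T) || V_T <= 0)
    stop("thermal potential V_T must be a positive number", call. = FALSE)
  if (G_ref <= 0) stop("reference conductance G_ref must be > 0", call. = FALSE)
  if (C_0 <= 0) stop("reference capacitance C_0 must be > 0", call. = FALSE)
  structure(list(inward = inward, outward = outward, V_T = V_T,
                 G_ref = G_ref, C_0 = C_0),
            class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat("Two-channel membrane model\n")
  cat(sprintf("  inward : G = %g nS, E = %g mV, V_th = %g mV, z = %g\n",
              x$inward$G, x$inward$E, x$inward$V_th, x$inward$z))
  cat(sprintf("  outward: G = %g nS, E = %g mV, V_th = %g mV, z = %g\n",
              x$outward$G, x$outward$E, x$outward$V_th, x$outward$z))
  cat(sprintf("  V_T = %g mV, G_ref = %g nS, C_0 = %g pF (tau = %g ms)\n",
              x$V_T, x$G_ref, x$C_0, x$C_0 / x$G_ref))
  invisible(x)
}

#' Thermal potential RT/F
#'
#' @param temperature Absolute temperature in kelvin.
#' @return RT/F in millivolts (8.314462618 * T / 96485.33212 * 1000).
#' @examples
#' round(thermal_potential(310))  # 27 mV at body temperature
#' @export
thermal_potential <- function(temperature = 310) {
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop("temperature must be positive (kelvin)", call. = FALSE)
  8.314462618 * temperature / 96485.33212 * 1000
}

#' Channel open probability
#'
#' Boltzmann gating sigmoid. For an inward rectifier
#' `p(V) = 1 / (1 + exp(z (V - V_th) / V_T))` (open at hyperpolarized
#' potentials, p -> 1 as V -> -Inf); the outward rectifier carries the
#' opposite gating-exponent sign and is its mirror image. `p(V_th) = 0.5`
#' for both.
#'
#' @param V Membrane potential in millivolts (vectorized).
#' @param ch A `channel_params` object.
#' @param V_T Thermal potential in millivolts (> 0).
#' @return Open probability in (0, 1), same length as `V`.
#' @export
open_probability <- function(V, ch, V_T) {
  stopifnot(inherits(ch, "channel_params"))
  if (!is.numeric(V_T) || length(V_T) != 1L || !is.finite(V_T) || V_T <= 0)
    stop("thermal potential V_T must be a positive number", call. = FALSE)
  s <- if (ch$rectification == "inward") 1 else -1
  stats::plogis(-s * ch$z * (V - ch$V_th) / V_T)
}

#' Single-channel current
#'
#' `I(V) = G p(V) (V - E)` in picoamperes (nS times mV), positive outward.
#' The current vanishes exactly at the equilibrium potential and changes
#' sign there.
#'
#' @inheritParams open_probability
#' @return Current in picoamperes, same length as `V`.
#' @export
channel_current <- function(V, ch, V_T) {
  ch$G * open_probability(V, ch, V_T) * (V - ch$E)
}

#' Total membrane current of the two-channel model
#'
#' Sum of the inward- and outward-rectifier currents, `I_in + I_out`.
#' An optional conductance-ratio override rescales the outward conductance
#' as `G_out = ratio * G_in` without rebuilding the model; this is how
#' channel upregulation and blocker fields enter the ensemble dynamics.
#'
#' @param V Membrane potential in millivolts (vectorized).
#' @param model A `membrane_model`.
#' @param ratio Optional `G_out / G_in`; `NULL` uses the model's own
#'   conductances.
#' @return Current in picoamperes.
#' @export
total_current <- function(V, model, ratio = NULL) {
  stopifnot(inherits(model, "membrane_model"))
  I_in <- channel_current(V, model$inward, model$V_T)
  if (is.null(ratio)) {
    I_out <- channel_current(V, model$outward, model$V_T)
  } else {
    if (any(ratio < 0)) stop("conductance ratio must be >= 0", call. = FALSE)
    I_out <- ratio * model$inward$G *
      open_probability(V, model$outward, model$V_T) * (V - model$outward$E)
  }
  I_in + I_out
}

# Analytic dI/dV of the total current, used for stability classification.
total_current_slope <- function(V, model, ratio = NULL) {
  slope1 <- function(ch, G) {
    s <- if (ch$rectification == "inward") 1 else -1
    p <- open_probability(V, ch, model$V_T)
    dp <- -s * ch$z / model$V_T * p * (1 - p)
    G * (dp * (V - ch$E) + p)
  }
  G_out <- if (is.null(ratio)) model$outward$G else ratio * model$inward$G
  slope1(model$inward, model$inward$G) + slope1(model$outward, G_out)
}

#' Zero-current fixed points of the membrane model
#'
#' Scans the total current on a dense grid, brackets every sign change and
#' refines each root with [stats::uniroot()] to `tol`. Roots are classified
#' stable/unstable by the sign of the analytic slope dI/dV: with the
#' positive-outward current convention the relaxation is
#' `C dV/dt = -I_total`, so positive slope means stable. Grid points where
#' the current vanishes without a sign change (tangential/degenerate roots)
#' are reported once with a warning.
#'
#' @param model A `membrane_model`.
#' @param V_range Length-2 millivolt interval to search (default the
#'   physiological window c(-100, 40)).
#' @param scan_step Bracketing grid spacing in millivolts (0 < step <= 1).
#' @param ratio Optional `G_out / G_in` override (see [total_current()]).
#' @param tol Root refinement tolerance in millivolts.
#' @return A data.frame with columns `V_star` (mV, sorted ascending),
#'   `stability` (`"stable"`/`"unstable"`), of class `fixed_points`.
#' @examples
#' fp <- find_fixed_points(membrane_model())
#' fp  # three roots: stable near -59 mV, unstable, stable near -8 mV
#' @export
find_fixed_points <- function(model, V_range = c(-100, 40), scan_step = 0.1,
                              ratio = NULL, tol = 1e-6) {
  stopifnot(inherits(model, "membrane_model"))
  if (length(V_range) != 2L || !all(is.finite(V_range)) || V_range[1] >= V_range[2])
    stop("V_range must be a finite increasing interval", call. = FALSE)
  if (!is.numeric(scan_step) || scan_step <= 0 || scan_step > 1)
    stop("scan_step must be in (0, 1] mV", call. = FALSE)
  f <- function(V) total_current(V, model, ratio = ratio)
  grid <- seq(V_range[1], V_range[2], by = scan_step)
  if (grid[length(grid)] < V_range[2]) grid <- c(grid, V_range[2])
  fg <- f(grid)
  roots <- numeric(0)
  exact <- which(fg == 0)
  if (length(exact)) {
    # a grid point sitting exactly on a root; tangential if no sign change around
    for (i in exact) {
      lo <- max(i - 1L, 1L); hi <- min(i + 1L, length(grid))
      if (fg[lo] * fg[hi] >= 0 && !(i %in% c(1L, length(grid))))
        warning("tangential (degenerate) zero-current root at ",
                format(grid[i]), " mV reported as a single root")
      roots <- c(roots, grid[i])
    }
  }
  sc <- which(fg[-1] * fg[-length(fg)] < 0)
  for (i in sc) {
    r <- stats::uniroot(f, c(grid[i], grid[i + 1]), tol = tol)$root
    roots <- c(roots, r)
  }
  roots <- sort(roots)
  if (length(roots) > 1L) roots <- roots[c(TRUE, diff(roots) > 10 * tol)]
  slope <- total_current_slope(roots, model, ratio = ratio)
  out <- data.frame(V_star = roots,
                    stability = ifelse(slope > 0, "stable", "unstable"),
                    stringsAsFactors = FALSE)
  class(out) <- c("fixed_points", "data.frame")
  out
}

#' Bifurcation diagram of the resting potential
#'
#' Sweeps the inward equilibrium potential `E_in` for each conductance
#' ratio `G_out / G_in` and records every zero-current root with its
#' stability, distinguishing mono- and bistable regions. Saddle-node (fold)
#' boundaries are reported as the `E_in` grid values at which the root
#' count changes.
#'
#' @param model A `membrane_model` (its `E_in` is overridden per sweep point).
#' @param E_in_values Millivolt values of the inward equilibrium potential.
#' @param conductance_ratios Non-negative `G_out / G_in` values.
#' @param V_range,scan_step Passed to [find_fixed_points()].
#' @return A list of class `bifurcation_diagram` with elements `branches`
#'   (data.frame: `E_in`, `ratio`, `V_star`, `stability`, `n_roots`) and
#'   `folds` (data.frame: `ratio`, `E_in_lo`, `E_in_hi`, `from`, `to` — the
#'   bracketing grid values of each root-count change).
#' @export
bifurcation_diagram <- function(model, E_in_values,
                                conductance_ratios = 1,
                                V_range = c(-100, 40), scan_step = 0.1) {
  stopifnot(inherits(model, "membrane_model"))
  if (any(conductance_ratios < 0)) stop("ratios must be >= 0", call. = FALSE)
  rows <- vector("list", 0L)
  folds <- vector("list", 0L)
  for (r in conductance_ratios) {
    prev_n <- NA_integer_
    for (k in seq_along(E_in_values)) {
      E <- E_in_values[k]
      m <- model
      m$inward <- channel_params(model$inward$G, E, model$inward$V_th,
                                 model$inward$z, "inward")
      fp <- find_fixed_points(m, V_range = V_range, scan_step = scan_step,
                              ratio = r)
      n <- nrow(fp)
      if (n > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          E_in = E, ratio = r, V_star = fp$V_star,
          stability = fp$stability, n_roots = n, stringsAsFactors = FALSE)
      if (!is.na(prev_n) && n != prev_n)
        folds[[length(folds) + 1L]] <- data.frame(
          ratio = r, E_in_lo = E_in_values[k - 1L], E_in_hi = E,
          from = prev_n, to = n)
      prev_n <- n
    }
  }
  structure(list(
    branches = if (length(rows)) do.call(rbind, rows) else
      data.frame(E_in = numeric(0), ratio = numeric(0), V_star = numeric(0),
                 stability = character(0), n_roots = integer(0)),
    folds = if (length(folds)) do.call(rbind, folds) else
      data.frame(ratio = numeric(0), E_in_lo = numeric(0),
                 E_in_hi = numeric(0), from = integer(0), to = integer(0))),
    class = "bifurcation_diagram")
}

#' Dimensionless and dimensional conversions
#'
#' The model is integrated in dimensionless variables: potentials are scaled
#' by the thermal potential (`v = V / V_T`), currents by `G_ref * V_T`
#' (`i = I / (G_ref V_T)`), and time by the electrical relaxation time
#' `tau = C_0 / G_ref` (`t_hat = t / tau`). With the default constants
#' (`V_T = 27` mV, `G_ref = 1` nS, `C_0 = 100` pF) a potential of 54 mV is
#' `v = 2`, a current of 54 pA is `i = 2`, and `t_hat = 10` is 1 s.
#' `dimensionalize()` is the exact inverse of `nondimensionalize()`.
#'
#' @param x Numeric value(s): mV, pA or ms for `nondimensionalize`;
#'   dimensionless for `dimensionalize`.
#' @param model A `membrane_model` supplying `V_T`, `G_ref`, `C_0`.
#' @param quantity Which physical quantity `x` is.
#' @return Numeric vector of the same length as `x`. Time is in
#'   milliseconds (pF / nS = ms).
#' @examples
#' m <- membrane_model()
#' nondimensionalize(54, m, "potential")       # 2
#' dimensionalize(10, m, "time")               # 1000 ms = 1 s
#' @export
nondimensionalize <- function(x, model, quantity = c("potential", "current", "time")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(model, "membrane_model"))
  switch(quantity,
         potential = x / model$V_T,
         current = x / (model$G_ref * model$V_T),
         time = x / (model$C_0 / model$G_ref))
}

#' @rdname nondimensionalize
#' @export
dimensionalize <- function(x, model, quantity = c("potential", "current", "time")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(model, "membrane_model"))
  switch(quantity,
         potential = x * model$V_T,
         current = x * (model$G_ref * model$V_T),
         time = x * (model$C_0 / model$G_ref))
}
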