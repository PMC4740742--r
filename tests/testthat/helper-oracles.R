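# Independent oracles kept deliberately naive: they re-derive expected
# values by brute force or closed form, never through the code paths they
# check.

default_model <- function() membrane_model()

# Dense-scan root oracle: sign changes of the total current on a fine grid,
# refined by plain bisection (no uniroot).
oracle_roots <- function(model, ratio = NULL, lo = -100, hi = 40, by = 0.01) {
  V <- seq(lo, hi, by = by)
  f <- total_current(V, model, ratio = ratio)
  sc <- which(f[-1] * f[-length(f)] < 0)
  vapply(sc, function(i) {
    a <- V[i]; b <- V[i + 1]
    for (k in 1:60) {
      m <- (a + b) / 2
      if (total_current(a, model, ratio = ratio) *
          total_current(m, model, ratio = ratio) <= 0) b <- m else a <- m
    }
    (a + b) / 2
  }, numeric(1))
}

# Count of zero-current roots on a dense grid (continuation oracle).
oracle_root_count <- function(model, E_in, ratio, by = 0.01) {
  m <- model
  m$inward <- channel_params(model$inward$G, E_in, model$inward$V_th,
                             model$inward$z, "inward")
  V <- seq(-100, 40, by = by)
  f <- total_current(V, m, ratio = ratio)
  sum(f[-1] * f[-length(f)] < 0)
}

# Explicit-Euler reference integrator for the full lattice ODE
#   dv/dt = -i(v) + (coupling), dense Laplacian.
euler_reference <- function(v0, lattice, fields, model, g, dt, n_steps) {
  L <- as.matrix(build_laplacian(lattice, coupling_params(g)))
  v <- v0
  for (k in seq_len(n_steps)) {
    st <- ensemble_state(v, lattice, 0)
    v <- v + dt * (channel_rhs(st, fields, model) - as.numeric(L %*% v))
  }
  v
}

# Largest-remainder apportionment, re-derived independently.
oracle_largest_remainder <- function(N, w) {
  q <- N * w
  base <- floor(q)
  rem <- q - base
  extra <- N - sum(base)
  if (extra > 0) {
    ord <- order(rem, -seq_along(rem), decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

# Truncated cosine-series solution of the 1-D heat equation with no-flux
# boundaries for a left-half step initial condition, evaluated at cell
# centers.
fourier_step_solution <- function(x, t, D, L, n_terms = 50) {
  out <- rep(0.5, length(x))
  for (n in seq_len(n_terms)) {
    b_n <- 2 / (n * pi) * sin(n * pi / 2)
    out <- out + b_n * cos(n * pi * x / L) * exp(-D * (n * pi / L)^2 * t)
  }
  out
}
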