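test_that("lattice Laplacian has the hand-checked structure", {
  # 1x1: the zero matrix
  L1 <- build_laplacian(lattice_spec(1, 1), coupling_params(0.25))
  expect_equal(as.matrix(L1), matrix(0, 1, 1), ignore_attr = TRUE)
  # 2x1 single edge
  L2 <- build_laplacian(lattice_spec(2, 1), coupling_params(0.25))
  expect_equal(as.matrix(L2), matrix(c(0.25, -0.25, -0.25, 0.25), 2),
               ignore_attr = TRUE)
  # 3x3: center cell (index 5) has diagonal 4g, corners 2g, edges 3g
  g <- 0.4
  L3 <- as.matrix(build_laplacian(lattice_spec(3, 3), coupling_params(g)))
  expect_equal(diag(L3), g * c(2, 3, 2, 3, 4, 3, 2, 3, 2), ignore_attr = TRUE)
  expect_equal(rowSums(L3), rep(0, 9))
  expect_equal(L3, t(L3))
  ev <- eigen(L3, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  expect_error(coupling_params(-0.1), "g must be")
  expect_error(coupling_params(0.25, capacitance_ratio = 0.1), "capacitance")
})

test_that("step matrix is I + dt L, SPD with eigenvalues >= 1", {
  lat <- lattice_spec(2, 1)
  L <- build_laplacian(lat, coupling_params(0.25))
  A <- assemble_step_matrix(L, 0.1)
  expect_equal(as.matrix(A$A),
               matrix(c(1.025, -0.025, -0.025, 1.025), 2), ignore_attr = TRUE)
  # g = 0 gives the identity
  A0 <- assemble_step_matrix(build_laplacian(lat, coupling_params(0)), 0.1)
  expect_equal(as.matrix(A0$A), diag(2), ignore_attr = TRUE)
  L4 <- build_laplacian(lattice_spec(4, 5), coupling_params(0.3))
  A4 <- assemble_step_matrix(L4, 0.05)
  ev <- eigen(as.matrix(A4$A), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= 1 - 1e-12))
  expect_error(assemble_step_matrix(L4, 0), "dt_hat")
})

test_that("channel RHS vanishes at single-cell fixed points", {
  m <- default_model()
  lat <- lattice_spec(3, 3)
  fields <- cell_fields(1, lat)
  fp <- find_fixed_points(m)
  for (V in fp$V_star) {
    st <- ensemble_state(rep(V / 27, 9), lat, 0)
    expect_equal(channel_rhs(st, fields, m), rep(0, 9), tolerance = 1e-7)
  }
  # single decoupled cell with only the inward channel is at rest at E_in
  lat1 <- lattice_spec(1, 1)
  st1 <- ensemble_state(-60 / 27, lat1, 0)
  expect_equal(channel_rhs(st1, cell_fields(0, lat1), m), 0)
  # matches the dimensionless single-cell current at the threshold (5 pA)
  st2 <- ensemble_state(-25 / 27, lat1, 0)
  expect_equal(channel_rhs(st2, cell_fields(1, lat1), m), -5 / 27)
})

test_that("a uniform state at a stable fixed point is exactly stationary", {
  m <- default_model()
  lat <- lattice_spec(4, 4)
  fields <- cell_fields(1, lat)
  fp <- find_fixed_points(m)
  v_star <- fp$V_star[1] / 27
  L <- build_laplacian(lat, coupling_params(0.25))
  A <- assemble_step_matrix(L, 0.01)
  st <- ensemble_state(rep(v_star, 16), lat, 0)
  st1 <- step_ensemble(st, A, fields, m, L)
  expect_equal(st1$v, st$v, tolerance = 1e-10)
  expect_equal(st1$t_hat, 0.01)
})

test_that("pure coupling relaxes a 2-cell difference as exp(-2 g t)", {
  # channels disabled via zero conductances; only the junction term remains
  m0 <- membrane_model(inward = channel_params(0, -60, -25, 3, "inward"),
                       outward = channel_params(0, 0, -25, 3, "outward"),
                       G_ref = 1)
  lat <- lattice_spec(2, 1)
  fields <- cell_fields(1, lat)
  g <- 0.25; dt <- 0.001
  L <- build_laplacian(lat, coupling_params(g))
  A <- assemble_step_matrix(L, dt)
  st <- ensemble_state(c(1, 0), lat, 0)
  for (k in 1:1000) st <- step_ensemble(st, A, fields, m0, L)
  # difference decays with rate 2g; the mean is conserved
  expect_equal(st$v[1] - st$v[2], exp(-2 * g * 1), tolerance = 1e-3)
  expect_equal(sum(st$v), 1, tolerance = 1e-12)
})

test_that("IMEX matches a fine explicit-Euler reference and converges at order >= 1", {
  m <- default_model()
  lat <- lattice_spec(5, 5)
  fields <- cell_fields(1, lat)
  # deterministic non-uniform start straddling the two basins
  v0 <- nondimensionalize(seq(-60, -5, length.out = 25), m, "potential")
  ref <- euler_reference(v0, lat, fields, m, g = 0.25, dt = 1e-4, n_steps = 10000)
  errs <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    cfg <- sim_config(dt_hat = dt, t_hat_final = 1, snapshot_times = 1)
    tr <- simulate_ensemble(ensemble_state(v0, lat, 0), fields, m,
                            coupling_params(0.25), cfg)
    max(abs(tr$final$v - ref))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  order_obs <- log2(errs[1] / errs[2])
  expect_gte(order_obs, 1)
  # an uncoupled single cell follows a dt/100 Euler trajectory closely
  lat1 <- lattice_spec(1, 1)
  f1 <- cell_fields(1, lat1)
  ref1 <- euler_reference(-1, lat1, f1, m, g = 0, dt = 1e-4, n_steps = 5000)
  tr1 <- simulate_ensemble(ensemble_state(-1, lat1, 0), f1, m,
                           coupling_params(0), sim_config(0.01, 0.5, 0.5))
  expect_equal(tr1$final$v, ref1, tolerance = 1e-3)
})

test_that("pure-coupling dynamics conserve the total potential", {
  m0 <- membrane_model(inward = channel_params(0, -60, -25, 3, "inward"),
                       outward = channel_params(0, 0, -25, 3, "outward"),
                       G_ref = 1)
  lat <- lattice_spec(4, 6)
  fields <- cell_fields(1, lat)
  v0 <- sin(seq_len(24))  # fixed, irregular
  tr <- simulate_ensemble(ensemble_state(v0, lat, 0), fields, m0,
                          coupling_params(0.3), sim_config(0.01, 2, 2))
  expect_equal(sum(tr$final$v), sum(v0), tolerance = 1e-10)
})

test_that("results are independent of the cell indexing orientation", {
  m <- default_model()
  lat <- lattice_spec(3, 5)
  ratio <- matrix(seq(0.5, 2, length.out = 15), 3, 5)
  v0 <- matrix(seq(-2.2, -0.2, length.out = 15), 3, 5)
  run <- function(v, r, lt) {
    tr <- simulate_ensemble(ensemble_state(v, lt, 0), cell_fields(r, lt), m,
                            coupling_params(0.2), sim_config(0.01, 1, 1))
    as_grid(tr$final)
  }
  out <- run(v0, ratio, lat)
  out_t <- run(t(v0), t(ratio), lattice_spec(5, 3))
  expect_equal(out_t, t(out), tolerance = 1e-12)
  # and under flipping both axes
  flip <- function(x) x[rev(seq_len(nrow(x))), rev(seq_len(ncol(x)))]
  out_f <- run(flip(v0), flip(ratio), lat)
  expect_equal(out_f, flip(out), tolerance = 1e-12)
})

test_that("initial-condition builder places the stable roots exactly", {
  m <- default_model()
  lat <- lattice_spec(50, 50)
  fp <- find_fixed_points(m)
  hyper <- fp$V_star[1] / 27; depol <- fp$V_star[3] / 27
  st_u <- make_initial_condition(lat, "uniform", m)
  expect_true(all(st_u$v == st_u$v[1]))
  expect_equal(st_u$v[1], hyper, tolerance = 1e-9)
  st_p <- make_initial_condition(lat, "central_patch", m)
  expect_identical(sum(abs(st_p$v - depol) < 1e-9), 100L)
  g <- as_grid(st_p)
  expect_true(all(abs(g[21:30, 21:30] - depol) < 1e-9))
  # mask pattern equals its mask
  mk <- matrix(FALSE, 4, 4); mk[1, 4] <- TRUE; mk[3, 2] <- TRUE
  st_m <- make_initial_condition(lattice_spec(4, 4), "mask", m, mask = mk)
  expect_equal(as_grid(st_m) > (fp$V_star[2] / 27), mk)
  expect_error(make_initial_condition(lattice_spec(5, 5), "central_patch", m,
                                      patch = c(10, 10)), "patch")
})

test_that("state summaries classify cells by the local basin threshold", {
  m <- default_model()
  lat <- lattice_spec(50, 50)
  f <- cell_fields(1, lat)
  st_u <- make_initial_condition(lat, "uniform", m)
  expect_equal(summarize_state(st_u, m, f)$fraction_depolarized, 0)
  st_p <- make_initial_condition(lat, "central_patch", m)
  expect_equal(summarize_state(st_p, m, f)$fraction_depolarized, 100 / 2500)
  # monostable local model (ratio 0): single hyperpolarized root, fraction 0
  f0 <- cell_fields(0, lat)
  expect_equal(summarize_state(st_p, m, f0)$fraction_depolarized, 0)
  s <- summarize_state(st_p, m, f)
  expect_lt(s$min_mV, s$mean_potential_mV)
  expect_gt(s$max_mV, s$mean_potential_mV)
})

test_that("patch reversion time is non-increasing in the junction conductance", {
  m <- default_model()
  lat <- lattice_spec(20, 20)
  f <- cell_fields(1, lat)
  ic <- make_initial_condition(lat, "central_patch", m, patch = c(4, 4))
  frac_at <- function(g, t) {
    tr <- simulate_ensemble(ic, f, m, coupling_params(g),
                            sim_config(0.01, t, t))
    summarize_state(tr$final, m, f)$fraction_depolarized
  }
  # remaining depolarized fraction at a fixed horizon decreases with g
  fr <- vapply(c(0.10, 0.15, 0.20, 0.25), frac_at, numeric(1), t = 3)
  expect_true(all(diff(fr) <= 0))
})

test_that("early stopping triggers at steady state and records the time", {
  m <- default_model()
  lat <- lattice_spec(5, 5)
  f <- cell_fields(1, lat)
  st <- make_initial_condition(lat, "uniform", m)
  cfg <- sim_config(0.01, 50, snapshot_times = c(0, 50), steady_state_tol = 1e-8)
  tr <- simulate_ensemble(st, f, m, coupling_params(0.25), cfg)
  expect_true(tr$stopped_early)
  expect_lt(tr$stop_t_hat, 1)
  expect_identical(length(tr$snapshots), 2L)
})
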