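# Scenario registry: named presets that reproduce the canonical model
# experiments end-to-end from their configuration alone. Each scenario
# composes the default membrane model with a lattice, coupling, a
# conductance-ratio field and an initial condition, runs the IMEX solver,
# and writes snapshots plus a run record.

scenario_defaults <- function() {
  list(
    grid = c(50L, 50L), patch = c(10L, 10L),
    g = 0.25, ratio = 1,
    dt = 0.01, t_final = 10, snapshots = NULL,
    family = "exponential", ratio_endpoints = c(0.05, 2.50),
    decay = 6,
    n_particles = 10000L, valence = 1,
    jitter_sd = 0, seed = NULL)
}

scenario_registry <- function() {
  list(
    fig2_single_cell = list(
      outcome = "three zero-current roots: stable/unstable/stable",
      description = "Fixed points of the default bistable single cell"),
    fig4_normalization = list(
      outcome = "depolarized central patch reverts at strong coupling",
      description = "50x50 ensemble, 10x10 depolarized patch, uniform G_out/G_in = 1"),
    fig5_upregulation = list(
      outcome = "depolarized patch invades under outward-channel upregulation",
      description = "As fig4 at g = 0.25 but global G_out/G_in raised (default 2.5)"),
    fig6_blocker_axial = list(
      outcome = "hyperpolarized on the blocked (left) side, depolarized on the right",
      description = "Axial blocker profile pinning G_out/G_in to 0.05 (left) / 2.50 (right)"),
    fig7_blocker_cross = list(
      outcome = "hyperpolarized central cross, depolarized corners",
      description = "2-D cross-shaped blocker profile, ratio 0.05 on the cross, 2.5 at corners"),
    fig8_nanoparticles = list(
      outcome = "particles concentrate on the hyperpolarized cross",
      description = "Boltzmann allocation of cationic particles over the fig7 final map"))
}

#' List registered scenarios
#'
#' @return A data.frame with `name`, `description` and the expected
#'   qualitative `outcome` of each registered scenario.
#' @export
list_scenarios <- function() {
  reg <- scenario_registry()
  data.frame(name = names(reg),
             description = vapply(reg, `[[`, "", "description"),
             outcome = vapply(reg, `[[`, "", "outcome"),
             row.names = NULL)
}

#' Run a registered scenario
#'
#' Executes one of the preset model experiments from its configuration
#' alone, writes potential-map snapshots (and scenario-specific tables) as
#' delimited text under `output_dir`, and returns a run record sufficient
#' to reproduce the run.
#'
#' @param name A scenario name from [list_scenarios()].
#' @param overrides Named list overriding scenario parameters: `grid`
#'   (length-2), `patch`, `g`, `ratio`, `dt`, `t_final`, `snapshots`,
#'   `family`, `ratio_endpoints`, `decay`, `n_particles`, `valence`,
#'   `jitter_sd`, `seed`.
#' @param output_dir Directory for output files (created if needed).
#' @param model A `membrane_model` (defaults to the canonical parameters).
#' @return A list of class `run_record`: `scenario`, `params` (full echo),
#'   `seed`, `tool_version`, `files`, `summary`.
#' @examples
#' \donttest{
#' rec <- run_scenario("fig2_single_cell", output_dir = tempfile())
#' rec$summary$n_fixed_points  # 3
#' }
#' @export
run_scenario <- function(name, overrides = list(),
                         output_dir = tempfile("bioelec_run_"),
                         model = membrane_model()) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; see list_scenarios()", call. = FALSE)
  params <- utils::modifyList(scenario_defaults(), overrides)
  bad <- setdiff(names(overrides), names(scenario_defaults()))
  if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  summary <- list()

  if (name == "fig2_single_cell") {
    fp <- find_fixed_points(model, ratio = if (is.null(overrides$ratio)) NULL
                            else params$ratio)
    path <- file.path(output_dir, "fixed_points.tsv")
    con <- file(path, "w")
    writeLines(sprintf("# scenario: %s", name), con)
    writeLines(sprintf("# tool_version: %s",
                       as.character(utils::packageVersion("bioelec"))), con)
    utils::write.table(fp, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
    files <- path
    summary <- list(n_fixed_points = nrow(fp),
                    V_stable_mV = fp$V_star[fp$stability == "stable"],
                    V_unstable_mV = fp$V_star[fp$stability == "unstable"])
    return(new_run_record(name, params, files, summary))
  }

  lattice <- lattice_spec(params$grid[1], params$grid[2])
  fields <- switch(name,
    fig4_normalization = cell_fields(1, lattice),
    fig5_upregulation = cell_fields(
      if (is.null(overrides$ratio)) 2.5 else params$ratio, lattice),
    fig6_blocker_axial = couple_to_ensemble(
      make_axial_profile(params$family, lattice, params$ratio_endpoints),
      lattice),
    fig7_blocker_cross = ,
    fig8_nanoparticles = couple_to_ensemble(
      make_2d_profile(lattice, params$ratio_endpoints[1],
                      params$ratio_endpoints[2], params$decay),
      lattice))

  initial <- switch(name,
    fig4_normalization = ,
    fig5_upregulation = make_initial_condition(
      lattice, "central_patch", model, patch = params$patch),
    fig6_blocker_axial = ,
    fig7_blocker_cross = ,
    fig8_nanoparticles = {
      # abnormal tissue: every cell starts at the depolarized resting state
      fp <- find_fixed_points(model)
      depol <- nondimensionalize(max(fp$V_star[fp$stability == "stable"]),
                                 model, "potential")
      make_initial_condition(lattice, "uniform", model,
                             levels = c(depol, depol))
    })
  seed_used <- NULL
  if (params$jitter_sd > 0) {
    if (is.null(params$seed))
      stop("initial-condition jitter requires an explicit seed", call. = FALSE)
    seed_used <- as.integer(params$seed)
    set.seed(seed_used)
    initial <- ensemble_state(
      initial$v + stats::rnorm(lattice$n, sd = params$jitter_sd),
      lattice, 0)
  }

  snaps <- if (is.null(params$snapshots)) c(0, params$t_final / 2, params$t_final)
           else params$snapshots
  config <- sim_config(dt_hat = params$dt, t_hat_final = params$t_final,
                       snapshot_times = snaps)
  g_used <- params$g
  traj <- simulate_ensemble(initial, fields, model,
                            coupling_params(g_used), config)
  tau_ms <- model$C_0 / model$G_ref
  for (s in traj$snapshots) {
    path <- file.path(output_dir, sprintf("potential_map_t%07.3f.tsv", s$t_hat))
    write_grid(as_grid(s, model), path, meta = list(
      scenario = name, t_hat = s$t_hat, t_ms = s$t_hat * tau_ms,
      rows = lattice$rows, cols = lattice$cols, g = g_used,
      ratio_min = min(fields$ratio), ratio_max = max(fields$ratio),
      param_hash = param_hash(params), units = "mV"))
    files <- c(files, path)
  }
  sm <- summarize_state(traj$final, model, fields)
  summary <- c(sm, list(t_hat_final = traj$final$t_hat,
                        stopped_early = traj$stopped_early))

  if (name == "fig8_nanoparticles") {
    spec <- nanoparticle_spec(params$n_particles, params$valence)
    tab <- distribute_nanoparticles(traj$final, model, spec)
    path <- file.path(output_dir, "nanoparticles.tsv")
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, path)
    summary$total_particles <- sum(tab$count)
  }
  new_run_record(name, params, files, summary, seed = seed_used)
}

new_run_record <- function(scenario, params, files, summary, seed = NULL) {
  structure(list(scenario = scenario, params = params, seed = seed,
                 tool_version = as.character(utils::packageVersion("bioelec")),
                 files = files, summary = summary),
            class = "run_record")
}

# Order-independent fingerprint of the parameter list for output headers.
param_hash <- function(params) {
  s <- paste(names(params)[order(names(params))],
             vapply(params[order(names(params))],
                    function(x) paste(format(x, digits = 15), collapse = ","),
                    character(1)),
             sep = "=", collapse = ";")
  # 31-adic rolling hash mod a Mersenne prime
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.run_record <- function(x, ...) {
  cat("Scenario run:", x$scenario, "\n")
  cat("  files:", length(x$files), "\n")
  for (k in names(x$summary)) {
    v <- x$summary[[k]]
    cat(sprintf("  %s: %s\n", k, paste(format(v, digits = 6), collapse = ", ")))
  }
  invisible(x)
}
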