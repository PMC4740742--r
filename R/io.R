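# Delimited-text grid I/O. Snapshots and profile grids are written as
# whitespace-separated matrices preceded by commented "# key: value"
# header lines, so files are self-describing and readable by any table
# reader that skips comments.

#' Write a numeric grid with a commented metadata header
#'
#' @param grid Numeric matrix.
#' @param path Output file path.
#' @param meta Named list of scalar metadata written as `# key: value`
#'   lines before the data. A `tool_version` entry is added automatically.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, meta = list()) {
  if (!is.matrix(grid) || !is.numeric(grid))
    stop("grid must be a numeric matrix", call. = FALSE)
  meta$nrow <- nrow(grid)
  meta$ncol <- ncol(grid)
  if (is.null(meta$tool_version))
    meta$tool_version <- as.character(utils::packageVersion("bioelec"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 17)), con)
  utils::write.table(format(grid, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a grid written by [write_grid()]
#'
#' @param path File path.
#' @return The numeric matrix, with the parsed header as attribute `meta`
#'   (numeric-looking values converted to numeric).
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  first_data <- which(!is_hdr & nzchar(trimws(lines)))[1]
  if (is.na(first_data)) stop("no data rows in ", path, call. = FALSE)
  if (any(!is_hdr[seq_len(first_data - 1)] & nzchar(trimws(lines[seq_len(first_data - 1)]))))
    stop("malformed header in ", path, call. = FALSE)
  meta <- list()
  for (i in which(is_hdr[seq_len(first_data - 1)])) {
    m <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3)
      stop(sprintf("cannot parse header line %d of %s: '%s'", i, path, lines[i]),
           call. = FALSE)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  data_lines <- lines[seq(first_data, length(lines))]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  rows <- lapply(seq_along(data_lines), function(k) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(data_lines[k]), "\\s+")[[1]]))
    if (any(is.na(vals)))
      stop(sprintf("non-numeric value on data line %d of %s",
                   first_data + k - 1L, path), call. = FALSE)
    vals
  })
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1L)
    stop("ragged rows in ", path, call. = FALSE)
  grid <- do.call(rbind, rows)
  attr(grid, "meta") <- meta
  grid
}

#' Long-format trajectory table
#'
#' Flattens a trajectory into one row per (snapshot, cell).
#'
#' @param trajectory A `trajectory` from [simulate_ensemble()].
#' @param model A `membrane_model` for the millivolt conversion.
#' @return A data.frame with columns `t_hat`, `cell_row`, `cell_col`, `v`
#'   (dimensionless) and `V_mV`.
#' @export
trajectory_table <- function(trajectory, model) {
  stopifnot(inherits(trajectory, "trajectory"))
  do.call(rbind, lapply(trajectory$snapshots, function(s) {
    lat <- s$lattice
    data.frame(
      t_hat = s$t_hat,
      cell_row = rep(seq_len(lat$rows), times = lat$cols),
      cell_col = rep(seq_len(lat$cols), each = lat$rows),
      v = s$v,
      V_mV = dimensionalize(s$v, model, "potential"))
  }))
}

#' Render a potential map as a heatmap image
#'
#' Best-effort PNG rendering with a fixed blue-to-red color scale anchored
#' at the two stable resting potentials (depolarized = blue, hyperpolarized
#' = red, matching the convention that red marks the normal state), with an
#' optional nanoparticle-count overlay. Rendering failures never abort an
#' analysis: the function warns and returns `NA` instead.
#'
#' @param state An `ensemble_state`.
#' @param path Output PNG path.
#' @param model A `membrane_model` (anchors the color scale at its stable
#'   roots).
#' @param particles Optional data.frame from [distribute_nanoparticles()].
#' @return `path` on success, `NA` on rendering failure (with a warning).
#' @export
render_heatmap <- function(state, path, model = membrane_model(),
                           particles = NULL) {
  tryCatch({
    V <- as_grid(state, model)
    fp <- find_fixed_points(model)
    st <- fp$V_star[fp$stability == "stable"]
    rng <- if (length(st) >= 2) range(st) else range(V)
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(64)
    grDevices::png(path, width = 640, height = 640)
    on.exit(grDevices::dev.off(), add = TRUE)
    Vc <- pmin(pmax(V, rng[1]), rng[2])
    # image() draws x along rows; transpose and flip so row 1 is on top
    graphics::image(x = seq_len(ncol(V)), y = seq_len(nrow(V)),
                    z = t(Vc[rev(seq_len(nrow(V))), , drop = FALSE]),
                    zlim = rng, col = pal, xlab = "column", ylab = "row",
                    main = sprintf("V_m map, t_hat = %g", state$t_hat),
                    useRaster = TRUE)
    if (!is.null(particles) && nrow(particles)) {
      has <- particles$count > 0
      graphics::points(particles$cell_col[has],
                       nrow(V) + 1 - particles$cell_row[has],
                       cex = 0.2 + 1.5 * sqrt(particles$count[has] /
                                                max(particles$count)),
                       pch = 1)
    }
    path
  }, error = function(e) {
    warning("heatmap rendering failed: ", conditionMessage(e), call. = FALSE)
    NA_character_
  })
}
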