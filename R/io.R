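#' Load and validate a run configuration file
#'
#' YAML with two optional blocks, `params` (model parameters, see
#' [model_params()]) and `run` (schedule, see [run_config()]). Unknown keys
#' are rejected with the offending name; missing values fall back to the
#' scenario defaults, so an empty file yields the standard MDCK setup.
#'
#' @param path YAML file path.
#' @return list with validated `params` and `run`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("params", "run"))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  run_keys <- c("grid", "steps", "frame_every", "seed", "S0", "scenario",
                "um_per_lu", "min_per_step", "store_flow")
  run_in <- raw$run %||% list()
  bad <- setdiff(names(run_in), run_keys)
  if (length(bad)) stop("unknown run key(s): ", paste(bad, collapse = ", "))
  par_in <- raw$params %||% list()
  for (blk in list(run_in, par_in)) {
    for (nm in names(blk)) {
      v <- blk[[nm]]
      if (!nm %in% c("scenario", "store_flow") && !is.numeric(v))
        stop("config key '", nm, "' must be numeric, got: ", deparse(v))
    }
  }
  scenario <- run_in$scenario %||% "mdck"
  run <- do.call(run_config, c(run_in, if (is.null(run_in$scenario))
    list(scenario = scenario)))
  params <- do.call(model_params, c(list(scenario = scenario), par_in))
  list(params = params, run = run)
}

#' Write an analysis report to disk
#'
#' Deterministic, diffable outputs: `summary.json` (extensile, interface and
#' contractile fractions with standard deviations, defect counts,
#' colocalization — `null`, not 0, when no defects were seen),
#' `series.csv` (per-frame statistics), plus any correlation curves and the
#' misalignment histogram as CSV.
#'
#' @param summary list from [summarize_run()] (or compatible).
#' @param out_dir output directory (created if needed).
#' @param curves optional named list of data frames written as
#'   `<name>.csv`.
#' @return invisibly, the paths written.
#' @export
write_report <- function(summary, out_dir, curves = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(
    extensile_pct = summary$means[["ext_pct"]],
    extensile_sd = summary$sds[["ext_pct"]],
    interface_pct = summary$means[["interface_pct"]],
    interface_sd = summary$sds[["interface_pct"]],
    colocalization_pct = if (is.finite(summary$means[["coloc_pct"]]))
      summary$means[["coloc_pct"]] else NULL,
    mean_defect_count = summary$means[["defect_count"]],
    steady_index = summary$steady_index,
    steady_flagged = summary$flagged)
  paths <- file.path(out_dir, "summary.json")
  jsonlite::write_json(js, paths[1], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  p <- file.path(out_dir, "series.csv")
  write.csv(summary$series, p, row.names = FALSE)
  paths <- c(paths, p)
  for (nm in names(curves)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(curves[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read and write per-cell tables
#'
#' CSV dialect with header `x_um, y_um, angle_deg, aspect_ratio, sxx, sxy,
#' syy` — the on-disk form of [cell_table()].
#'
#' @param cells a [cell_table()].
#' @param path CSV path.
#' @return `read_cell_table` returns a [cell_table()].
#' @export
write_cell_table <- function(cells, path) {
  write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  d <- read.csv(path)
  need <- c("x_um", "y_um", "angle_deg", "aspect_ratio", "sxx", "sxy", "syy")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("cell table missing column(s): ",
                         paste(miss, collapse = ", "))
  cell_table(d$x_um, d$y_um, d$angle_deg, d$aspect_ratio, d$sxx, d$sxy, d$syy)
}

#' Read and write coarse stress grids
#'
#' Long-format CSV (`x_um, y_um, sxx, sxy, syy`) on a regular lattice; the
#' spacing is recovered from the coordinates on read.
#'
#' @param grid list with matrices `sxx`, `sxy`, `syy`, plus `spacing_um`
#'   and `origin`.
#' @param path CSV path.
#' @export
write_stress_grid <- function(grid, path) {
  n <- nrow(grid$sxx); m <- ncol(grid$sxx)
  x <- grid$origin[1] + (rep(seq_len(n), m) - 0.5) * grid$spacing_um
  y <- grid$origin[2] + (rep(seq_len(m), each = n) - 0.5) * grid$spacing_um
  write.csv(data.frame(x_um = x, y_um = y,
                       sxx = as.numeric(grid$sxx),
                       sxy = as.numeric(grid$sxy),
                       syy = as.numeric(grid$syy)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stress_grid
#' @export
read_stress_grid <- function(path) {
  d <- read.csv(path)
  xs <- sort(unique(d$x_um)); ys <- sort(unique(d$y_um))
  h <- diff(xs)[1]
  n <- length(xs); m <- length(ys)
  ix <- match(d$x_um, xs); iy <- match(d$y_um, ys)
  put <- function(v) { z <- matrix(NA_real_, n, m); z[cbind(ix, iy)] <- v; z }
  list(sxx = put(d$sxx), sxy = put(d$sxy), syy = put(d$syy),
       spacing_um = h, origin = c(min(xs) - h / 2, min(ys) - h / 2))
}

#' Serialize a simulation trajectory
#'
#' One CSV per frame (`frame_000300.csv` ... with columns `x, y, Qnxx, Qnxy,
#' Qmxx, Qmxy[, ux, uy]`) plus `manifest.json` carrying the configuration,
#' parameters, seed and unit calibration. Re-reading reproduces the
#' trajectory arrays exactly; re-running with the manifest's seed reproduces
#' the run bit-identically.
#'
#' @param traj an `an_trajectory`.
#' @param dir output directory.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(traj$Qnxx)
  xy <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  for (k in seq_len(d[3])) {
    df <- data.frame(xy,
                     Qnxx = as.numeric(traj$Qnxx[, , k]),
                     Qnxy = as.numeric(traj$Qnxy[, , k]),
                     Qmxx = as.numeric(traj$Qmxx[, , k]),
                     Qmxy = as.numeric(traj$Qmxy[, , k]))
    if (!is.null(traj$ux)) {
      df$ux <- as.numeric(traj$ux[, , k]); df$uy <- as.numeric(traj$uy[, , k])
    }
    write.csv(df, file.path(dir, sprintf("frame_%06d.csv", traj$steps[k])),
              row.names = FALSE)
  }
  manifest <- list(grid = d[1:2], frames = d[3], steps = traj$steps,
                   mass = traj$mass, max_speed = traj$max_speed,
                   config = unclass(traj$config),
                   params = unclass(traj$params)[
                     !names(traj$params) %in% c("scenario", "R", "C_prime")],
                   scenario = traj$params$scenario)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  nx <- man$grid[1]; ny <- man$grid[2]; nf <- man$frames
  arr <- function() array(0, c(nx, ny, nf))
  out <- list(Qnxx = arr(), Qnxy = arr(), Qmxx = arr(), Qmxy = arr(),
              steps = man$steps, mass = man$mass, max_speed = man$max_speed)
  has_flow <- NULL
  for (k in seq_len(nf)) {
    df <- read.csv(file.path(dir, sprintf("frame_%06d.csv", man$steps[k])))
    if (is.null(has_flow)) {
      has_flow <- "ux" %in% names(df)
      if (has_flow) { out$ux <- arr(); out$uy <- arr() }
    }
    out$Qnxx[, , k] <- df$Qnxx; out$Qnxy[, , k] <- df$Qnxy
    out$Qmxx[, , k] <- df$Qmxx; out$Qmxy[, , k] <- df$Qmxy
    if (has_flow) { out$ux[, , k] <- df$ux; out$uy[, , k] <- df$uy }
  }
  cfg <- man$config
  out$config <- do.call(run_config, cfg[setdiff(names(cfg), character(0))])
  out$params <- do.call(model_params,
                        c(list(scenario = man$scenario %||% "mdck"), man$params))
  class(out) <- "an_trajectory"
  out
}
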