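#' Per-frame misalignment, defect and interface statistics of a run
#'
#' For every frame: the misalignment map between the shape and stress
#' directors, the extensile area fraction, the interface-domain fractions
#' at the stress-resolution half-width, the shape-director defects and their
#' colocalization with the interface band. This is the measurement protocol
#' applied to simulations; the same operations serve experiment-like data
#' through [cells_to_grid()].
#'
#' @param traj an `an_trajectory` from [simulate_monolayer()].
#' @param r_interface_um interface half-width in um (stress resolution).
#' @param frames frame indices to analyse (default all).
#' @return list with `series` (a data frame: one row per frame with
#'   `frame`, `step`, `ext_frac`, `interface_frac`, `defect_count`,
#'   `coloc`, `mean_theta`) and the calibration used.
#' @export
analyze_trajectory <- function(traj, r_interface_um = 5.2, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  r_lu <- r_interface_um / traj$config$um_per_lu
  rows <- lapply(frames, function(k) {
    # image-processing steps allocate native memory the R heap heuristics
    # do not see; collect periodically so long trajectories stay bounded
    if (k %% 25 == 0) gc(FALSE)
    fr <- get_frame(traj, k)
    mm <- frame_misalignment(fr)
    idom <- interface_domains(mm, r_max = r_lu)
    dn <- find_defects(director_from_q(fr$Qn)$angle, periodic = TRUE)
    data.frame(frame = k, step = fr$step,
               ext_frac = mean(mm$extensile[mm$valid]),
               interface_frac = idom$fractions[["interface"]],
               defect_count = nrow(dn),
               coloc = defect_interface_colocalization(dn, idom$interface),
               mean_theta = mean(mm$theta, na.rm = TRUE))
  })
  list(series = do.call(rbind, rows),
       r_interface_um = r_interface_um, um_per_lu = traj$config$um_per_lu)
}

frame_misalignment <- function(fr) {
  dn <- director_from_q(fr$Qn); dm <- director_from_q(fr$Qm)
  misalignment(
    director_grid(dn$angle, dn$S, periodic = TRUE, isotropic = dn$isotropic),
    director_grid(dm$angle, dm$S, periodic = TRUE, isotropic = dm$isotropic),
    frame = fr$step)
}

#' Steady-state summary of a simulation run
#'
#' Runs [analyze_trajectory()], finds the steady state with
#' [detect_steady_state()], and averages the extensile area fraction,
#' interface fraction and defect-interface colocalization over the final
#' `measure` frames (the standard measurement window).
#'
#' @inheritParams analyze_trajectory
#' @param measure number of trailing frames to average over.
#' @param window,alpha passed to [detect_steady_state()].
#' @return list with `means` (named vector, percentages for the three
#'   fractions), `sds`, `steady_index`, `flagged` and the per-frame
#'   `series`.
#' @export
summarize_run <- function(traj, r_interface_um = 5.2, measure = 150,
                          window = 50, alpha = 0.05) {
  an <- analyze_trajectory(traj, r_interface_um)
  ss <- detect_steady_state(an$series, window = window, alpha = alpha,
                            measure = measure)
  n <- nrow(an$series)
  idx <- max(ss$index, n - measure + 1):n
  tailf <- an$series[idx, ]
  means <- c(ext_pct = 100 * mean(tailf$ext_frac),
             interface_pct = 100 * mean(tailf$interface_frac),
             coloc_pct = 100 * mean(tailf$coloc, na.rm = TRUE),
             defect_count = mean(tailf$defect_count))
  sds <- c(ext_pct = 100 * sd(tailf$ext_frac),
           interface_pct = 100 * sd(tailf$interface_frac),
           coloc_pct = 100 * sd(tailf$coloc, na.rm = TRUE),
           defect_count = sd(tailf$defect_count))
  list(means = means, sds = sds, steady_index = ss$index,
       flagged = ss$flagged, measured_frames = idx, series = an$series)
}
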