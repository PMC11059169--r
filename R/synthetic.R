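#' Configuration of the synthetic monolayer generator
#'
#' Defaults emulate the imaging geometry and the measured statistics of the
#' MDCK experiments: a 1 mm circular island sampled every 15 min, shape
#' orientations correlated over ~100 um and stress orientations over
#' ~50 um, a ~300 min orientational persistence time, stress grids at the
#' 5.2 um monolayer-stress-microscopy resolution and a target extensile
#' fraction of 0.27.
#'
#' @param island_diameter_um island diameter.
#' @param n_cells cells per frame (~2500 gives MDCK-like density).
#' @param frame_interval_min minutes between frames.
#' @param n_frames number of frames (48 = 12 h at 15 min).
#' @param ell_shape_um,ell_stress_um orientation correlation lengths.
#' @param extensile_target target extensile fraction in `[0, 1]`.
#' @param persistence_min temporal 1/e persistence of the orientations.
#' @param stress_spacing_um stress-grid spacing.
#' @param stress_scale magnitude scale of the contractile stress (arbitrary
#'   units); the isotropic part is `-stress_scale/2` on the diagonal.
#' @param seed integer seed; recorded in the output.
#' @return a `synth_config` list.
#' @export
synth_config <- function(island_diameter_um = 1000, n_cells = 2500,
                         frame_interval_min = 15, n_frames = 48,
                         ell_shape_um = 100, ell_stress_um = 50,
                         extensile_target = 0.27, persistence_min = 300,
                         stress_spacing_um = 5.2, stress_scale = 300,
                         seed = 1) {
  stopifnot(island_diameter_um > 0, ell_shape_um > 0, ell_stress_um > 0,
            persistence_min > 0, stress_spacing_um > 0,
            extensile_target >= 0, extensile_target <= 1, n_cells >= 4)
  structure(as.list(environment()), class = "synth_config")
}

# Component correlation rho at which the angular correlation
# E cos(phi - phi') of two 2-D Gaussian vectors equals `level`:
# E cos(dphi) = (pi/4) rho 2F1(1/2, 1/2; 2; rho^2).
angular_corr <- function(rho) {
  z <- rho^2
  term <- 1; s <- 1
  for (k in 1:40) {
    term <- term * (0.5 + k - 1)^2 / ((2 + k - 1) * k) * z
    s <- s + term
  }
  (pi / 4) * rho * s
}

rho_for_level <- function(level = exp(-1)) {
  uniroot(function(r) angular_corr(r) - level, c(1e-6, 0.999999),
          tol = 1e-10)$root
}

# Kernel sd (sites) so the nematic correlation decays to 1/e at ell sites:
# Gaussian-smoothed white noise has component correlation exp(-r^2/(4 s^2)).
sigma_for_ell <- function(ell) {
  rs <- rho_for_level()
  ell / (2 * sqrt(log(1 / rs)))
}

fft_gauss_smooth <- function(m, sigma) {
  if (sigma < 0.3) return(m)
  nx <- nrow(m); ny <- ncol(m)
  kx <- 2 * pi * c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  ky <- 2 * pi * c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  ker <- exp(-outer(kx^2, ky^2, "+") * sigma^2 / 2)
  Re(fft(fft(m) * ker, inverse = TRUE)) / (nx * ny)
}

unit_var <- function(m) m / sd(as.numeric(m))

#' Smooth random nematic angle field with a prescribed correlation length
#'
#' Gaussian-filtered white noise on the nematic components
#' `(cos 2 psi, sin 2 psi)`, renormalized and converted back to an angle.
#' The filter width is calibrated so the orientation correlation
#' (measurable with [orientation_correlation()]) decays to `1/e` at `ell`
#' lattice units. `ell -> 0` reduces to site-independent angles.
#'
#' @param n grid size (n x n sites, periodic).
#' @param ell target correlation length in lattice units (`ell < n`).
#' @param seed optional seed.
#' @param components return the underlying Gaussian component fields too
#'   (used by the frame generator's temporal evolution).
#' @return angle matrix in `[0, pi)`, or a list when `components = TRUE`.
#' @export
smooth_nematic_field <- function(n, ell, seed = NULL, components = FALSE) {
  stopifnot(ell < n)
  if (!is.null(seed)) set.seed(seed)
  sigma <- sigma_for_ell(ell)
  xc <- unit_var(fft_gauss_smooth(matrix(rnorm(n * n), n, n), sigma))
  xs <- unit_var(fft_gauss_smooth(matrix(rnorm(n * n), n, n), sigma))
  ang <- wrap_pi(0.5 * atan2(xs, xc))
  if (components) list(angle = ang, xc = xc, xs = xs, sigma = sigma) else ang
}

#' Generate experiment-like monolayer frames
#'
#' Emulates the structure the analysis pipeline assumes in measured data:
#' cell centroids uniform in the circular island; shape angles sampled from
#' a spatially correlated nematic field evolving with AR(1) temporal mixing
#' at the configured persistence; stress orientations built by adding a
#' bias of weight `beta = cos(pi * extensile_target)` along the local shape
#' axis to a unit noise vector with the stress correlation length — a
#' projected mixture whose site-wise extensile probability is exactly the
#' target; stress magnitudes declining with the misalignment angle; stress
#' tensors reassembled from (orientation, magnitude, isotropic part) on a
#' grid at the stress-microscopy spacing. The analysis operations must be
#' run to recover the configured statistics — nothing is stored directly.
#'
#' @param cfg a [synth_config()].
#' @return list with `cells` (list of [cell_table()]s), `stress` (list of
#'   stress grids: `sxx`, `sxy`, `syy`, `spacing_um`, `origin`), the angle
#'   fields' lattice info, and the echoed `cfg`.
#' @export
generate_frames <- function(cfg) {
  set.seed(cfg$seed)
  h <- cfg$stress_spacing_um
  D <- cfg$island_diameter_um
  n_core <- ceiling(D / h)
  sig_n <- sigma_for_ell(cfg$ell_shape_um / h)
  n_lat <- n_core + 2 * ceiling(3 * sig_n) # periodic margin so the island
  n_lat <- n_lat + n_lat %% 2              # sees an effectively open field
  a_mix <- rho_for_level()^(cfg$frame_interval_min / cfg$persistence_min)
  beta <- cos(pi * cfg$extensile_target)
  sig_m <- sigma_for_ell(cfg$ell_stress_um / h)

  smooth_pair <- function(sig) list(
    c = unit_var(fft_gauss_smooth(matrix(rnorm(n_lat^2), n_lat, n_lat), sig)),
    s = unit_var(fft_gauss_smooth(matrix(rnorm(n_lat^2), n_lat, n_lat), sig)))
  mix <- function(old, sig) {
    fresh <- smooth_pair(sig)
    list(c = a_mix * old$c + sqrt(1 - a_mix^2) * fresh$c,
         s = a_mix * old$s + sqrt(1 - a_mix^2) * fresh$s)
  }

  # fixed centroids + small per-frame jitter (cells move slowly)
  rad <- D / 2
  rr <- rad * sqrt(runif(cfg$n_cells)); phi <- runif(cfg$n_cells, 0, 2 * pi)
  cx0 <- rad + rr * cos(phi); cy0 <- rad + rr * sin(phi)
  ar <- 1 + rlnorm(cfg$n_cells, meanlog = log(0.5) + 0.25, sdlog = 0.5)

  Xn <- smooth_pair(sig_n); Xm <- smooth_pair(sig_m)
  core <- seq_len(n_core)
  grid_x <- (core - 0.5) * h
  cells <- vector("list", cfg$n_frames)
  stress <- vector("list", cfg$n_frames)
  for (t in seq_len(cfg$n_frames)) {
    if (t > 1) { Xn <- mix(Xn, sig_n); Xm <- mix(Xm, sig_m) }
    nrm_n <- sqrt(Xn$c^2 + Xn$s^2); nrm_m <- sqrt(Xm$c^2 + Xm$s^2)
    un_c <- Xn$c / nrm_n; un_s <- Xn$s / nrm_n
    vx <- beta * un_c + Xm$c / nrm_m
    vy <- beta * un_s + Xm$s / nrm_m
    psi_n <- wrap_pi(0.5 * atan2(un_s, un_c))
    psi_m <- wrap_pi(0.5 * atan2(vy, vx))
    dth <- abs(psi_n - psi_m) %% pi
    theta <- rad2deg(pmin(dth, pi - dth))
    mag <- cfg$stress_scale * (0.35 + 0.65 * cos(deg2rad(theta))^2) *
      rlnorm(n_lat^2, 0, 0.25)
    iso <- -cfg$stress_scale / 2
    sxx_f <- mag * cos(2 * psi_m) + iso
    sxy_f <- mag * sin(2 * psi_m)
    syy_f <- -mag * cos(2 * psi_m) + iso
    stress[[t]] <- list(sxx = sxx_f[core, core], sxy = sxy_f[core, core],
                        syy = syy_f[core, core], spacing_um = h,
                        origin = c(0, 0))
    cx <- cx0 + rnorm(cfg$n_cells, 0, 1.5)
    cy <- cy0 + rnorm(cfg$n_cells, 0, 1.5)
    # nearest lattice site (max offset h/2 = 2.6 um, below cell scale):
    # keeps the per-cell misalignment distribution exactly as calibrated
    ix <- pmin(pmax(round(cx / h + 0.5), 1), n_lat)
    iy <- pmin(pmax(round(cy / h + 0.5), 1), n_lat)
    samp <- function(m) m[cbind(ix, iy)]
    cells[[t]] <- cell_table(
      x = cx, y = cy,
      angle_deg = rad2deg(samp(psi_n)),
      aspect_ratio = ar,
      sxx = samp(sxx_f), sxy = samp(sxy_f), syy = samp(syy_f))
  }
  list(cells = cells, stress = stress, lattice_n = n_core, spacing_um = h,
       cfg = cfg)
}

#' Degrade a simulation frame into an experiment-like cell table
#'
#' Turns `n_cells` random lattice sites of a simulation frame into "cells":
#' shape angle and aspect ratio from the shape tensor's director and order,
#' stress tensor rebuilt from the active stress `-zeta Q^m` plus an
#' isotropic offset (which the trace-removal step of the analysis discards).
#' Feeding the result back through the analysis pipeline reproduces the
#' frame's gridded misalignment statistics up to sampling error; with
#' `n_cells` equal to all sites the mapping is lossless.
#'
#' @param frame a frame from [get_frame()].
#' @param n_cells number of cells to sample (at most all sites).
#' @param seed optional seed for the site sample.
#' @param zeta activity used to rebuild the stress (sign matters).
#' @param iso_offset isotropic stress offset added to the diagonal.
#' @param um_per_lu physical calibration.
#' @return list with `cells` (a [cell_table()]) and the island extent `L_um`.
#' @export
sample_simulation_as_cells <- function(frame, n_cells, seed = NULL,
                                       zeta = -0.03, iso_offset = 0,
                                       um_per_lu = 3) {
  nx <- nrow(frame$Qn$xx); ny <- ncol(frame$Qn$xx)
  if (n_cells > nx * ny) stop("n_cells exceeds the number of lattice sites")
  if (!is.null(seed)) set.seed(seed)
  sel <- if (n_cells == nx * ny) seq_len(nx * ny)
         else sample.int(nx * ny, n_cells)
  ii <- (sel - 1) %% nx + 1; jj <- (sel - 1) %/% nx + 1
  dn <- director_from_q(frame$Qn)
  txx <- -zeta * frame$Qm$xx[sel]; txy <- -zeta * frame$Qm$xy[sel]
  cells <- cell_table(
    x = (ii - 0.5) * um_per_lu, y = (jj - 0.5) * um_per_lu,
    angle_deg = rad2deg(dn$angle[sel]),
    aspect_ratio = 1 + dn$S[sel],
    sxx = txx + iso_offset, sxy = txy, syy = -txx + iso_offset)
  list(cells = cells, L_um = nx * um_per_lu)
}

#' @importFrom stats rnorm rlnorm
NULL
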