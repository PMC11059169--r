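#' Configuration of the pinned-defect (LP-9) scenario
#'
#' A passive circular island: nematic order forms only inside radius `R`
#' (the exterior quartic energy melts it outside), a `+1/2` defect in the
#' shape director is imprinted at the island centre and held fixed, and the
#' stress field relaxes towards the free-energy minimum with zero activity.
#'
#' @param box box size in lattice units (square, periodic embedding).
#' @param R island radius (`R < box/2`).
#' @param centre defect centre; defaults to the box centre (off-lattice, so
#'   no site sits exactly on the core).
#' @param seed seed for the random initial stress orientations.
#' @param S0 initial stress-order magnitude.
#' @param tol convergence threshold on `max |gamma H^m|`.
#' @param max_steps relaxation step cap.
#' @param snapshot_every snapshot interval (steps).
#' @return an `lp9_config` list.
#' @export
lp9_config <- function(box = 200, R = 80, centre = NULL, seed = 1, S0 = 1,
                       tol = 1e-7, max_steps = 500000, snapshot_every = NULL) {
  if (R >= box / 2) stop("island radius R must be below box/2")
  structure(list(box = as.integer(box), R = R,
                 centre = centre %||% c((box + 1) / 2, (box + 1) / 2),
                 seed = as.integer(seed), S0 = S0, tol = tol,
                 max_steps = as.integer(max_steps),
                 snapshot_every = as.integer(snapshot_every %||%
                                               max(1000, max_steps %/% 100))),
            class = "lp9_config")
}

#' Imprint a +1/2 defect in the shape director
#'
#' Sets the director angle to half the polar angle around `centre`
#' (`psi = phi/2`, winding `+pi`, charge `+1/2`). The order magnitude ramps
#' from zero at the core as `tanh(r/2)` and decays smoothly to zero outside
#' the island radius; the bulk value is the energy minimum `sqrt(2/3)`.
#'
#' @param box grid size (square).
#' @param centre defect position `c(x, y)` in site coordinates.
#' @param R island radius.
#' @param S_bulk bulk order magnitude.
#' @param core_width core regularization length (lattice units).
#' @return a [qtensor_field()] with attributes `interior` (logical island
#'   mask), `centre` and `R`.
#' @export
imprint_defect <- function(box, centre, R, S_bulk = sqrt(2 / 3),
                           core_width = 2) {
  x <- matrix(seq_len(box), box, box)
  y <- matrix(seq_len(box), box, box, byrow = TRUE)
  dx <- x - centre[1]; dy <- y - centre[2]
  r <- sqrt(dx^2 + dy^2)
  psi <- atan2(dy, dx) / 2
  S <- S_bulk * tanh(r / core_width) * 0.5 * (1 - tanh((r - R) / 2))
  Q <- q_from_director(S, psi)
  attr(Q, "interior") <- r <= R
  attr(Q, "centre") <- centre
  attr(Q, "R") <- R
  Q
}

#' Relax the stress field around a pinned shape defect
#'
#' The shape tensor is held fixed; the stress tensor evolves by pure
#' relaxation `dQ^m/dt = gamma H^m` (no advection, no flow, zero activity)
#' until `max |gamma H^m|` drops below the tolerance or the step cap is
#' reached (then flagged as metastable drift). The competition between the
#' stress elasticity (smooth `m`) and the shape-stress coupling (`m`
#' tracking the defected `n`) leaves a misaligned, extensile region near
#' the defect whose geometry depends on the initial condition — the
#' metastability seen in passive monolayers.
#'
#' @param config an [lp9_config()].
#' @param params a [model_params()], default the LP-9 set.
#' @return an `lp9_result`: final `Qm`, pinned `Qn`, snapshots of `Qm`, the
#'   residual trace, `converged`, and the geometry.
#' @export
relax_stress <- function(config = lp9_config(), params = model_params("lp9")) {
  if (params$zeta != 0) stop("LP-9 scenario requires zeta = 0")
  Qn <- imprint_defect(config$box, config$centre, config$R)
  interior <- attr(Qn, "interior")
  set.seed(config$seed)
  psi0 <- matrix(runif(config$box^2, 0, pi), config$box, config$box)
  Qm0 <- q_from_director(config$S0, psi0)
  r <- .relax_stress_cpp(Qn$xx, Qn$xy, Qm0$xx, Qm0$xy,
                         params$C, params$K_n, params$K_m, params$J,
                         params$gamma,
                         matrix(as.integer(interior), config$box, config$box),
                         params$C_prime, config$tol, config$max_steps,
                         config$snapshot_every, coupling_code(params))
  if (!r$converged)
    warning(sprintf(
      "metastable drift: residual %.2e after %d steps (tol %.1e)",
      r$snap_maxH[r$n_snapshots], r$steps, config$tol))
  ns <- r$n_snapshots
  structure(list(Qm = qtensor_field(r$Qmxx, r$Qmxy),
                 Qn = Qn, interior = interior,
                 snapshots = list(Qmxx = r$snap_Qmxx[, , seq_len(ns)],
                                  Qmxy = r$snap_Qmxy[, , seq_len(ns)],
                                  steps = r$snap_steps[seq_len(ns)],
                                  maxH = r$snap_maxH[seq_len(ns)]),
                 steps = r$steps, converged = r$converged,
                 config = config, params = params),
            class = "lp9_result")
}

#' @export
print.lp9_result <- function(x, ...) {
  cat(sprintf("<lp9_result box %d, R %.0f, %d steps, %s>\n", x$config$box,
              x$config$R, x$steps,
              if (x$converged) "converged" else "metastable drift"))
  invisible(x)
}

#' Measure the extensile patch next to the pinned defect
#'
#' Misalignment map restricted to the island, connected-component analysis
#' of the extensile (`theta > 45` degree) mask, and the largest patch's area
#' fraction of the island and centroid offset from the defect core. Also
#' counts stress-director defects in the island interior.
#'
#' @param result an `lp9_result` (or supply `Qm`, `Qn`, `interior`,
#'   `centre` directly).
#' @param Qm,Qn,interior,centre used when `result` is `NULL`.
#' @param margin radial margin (lattice units) excluded at the island rim
#'   for the defect count.
#' @return list with `extensile_fraction` (of the island), `patch_fraction`
#'   (largest connected patch), `patch_centroid`, `centroid_offset` (from
#'   the defect), `n_patches`, `stress_defects` (a `defect_set`) and the
#'   `theta` map (`NA` outside the island).
#' @export
measure_patch <- function(result = NULL, Qm = NULL, Qn = NULL,
                          interior = NULL, centre = NULL, margin = 5) {
  if (!is.null(result)) {
    Qm <- result$Qm; Qn <- result$Qn
    interior <- result$interior; centre <- result$config$centre
  }
  dn <- director_from_q(Qn); dm <- director_from_q(Qm)
  d <- abs(dn$angle - dm$angle) %% pi
  theta <- rad2deg(pmin(d, pi - d))
  theta[!interior | dn$isotropic | dm$isotropic] <- NA
  ext <- !is.na(theta) & theta > 45
  island_n <- sum(interior)
  lab <- EBImage::bwlabel(EBImage::Image(ext * 1))
  lab <- as.matrix(lab)
  n_patches <- max(lab)
  if (n_patches == 0) {
    return(list(extensile_fraction = 0, patch_fraction = 0,
                patch_centroid = c(NA, NA), centroid_offset = NA_real_,
                n_patches = 0, stress_defects = NULL, theta = theta))
  }
  sizes <- tabulate(lab[lab > 0], nbins = n_patches)
  big <- which.max(sizes)
  sel <- which(lab == big)
  px <- (sel - 1) %% nrow(lab) + 1; py <- (sel - 1) %/% nrow(lab) + 1
  centroid <- c(mean(px), mean(py))
  # stress defects strictly inside the ordered region
  dm_def <- find_defects(dm$angle, periodic = TRUE)
  if (nrow(dm_def)) {
    inside <- sqrt((dm_def$x - centre[1])^2 + (dm_def$y - centre[2])^2) <
      (attr(Qn, "R") - margin)
    dm_def <- dm_def[inside, ]
  }
  list(extensile_fraction = sum(ext) / island_n,
       patch_fraction = sizes[big] / island_n,
       patch_centroid = centroid,
       centroid_offset = sqrt(sum((centroid - centre)^2)),
       n_patches = n_patches,
       stress_defects = dm_def,
       theta = theta)
}
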