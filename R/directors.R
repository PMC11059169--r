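#' Per-cell table for one frame
#'
#' Validates the experiment-like record: centroid (um), shape-orientation
#' angle (degrees, wrapped mod 180), aspect ratio >= 1 and the symmetric
#' in-plane stress tensor at the cell.
#'
#' @param x,y centroids in um.
#' @param angle_deg shape angle in degrees.
#' @param aspect_ratio cell aspect ratio (>= 1).
#' @param sxx,sxy,syy stress components (any consistent unit).
#' @return a `cell_table` data frame.
#' @export
cell_table <- function(x, y, angle_deg, aspect_ratio = 1.5,
                       sxx = 0, sxy = 0, syy = 0) {
  d <- data.frame(x_um = x, y_um = y, angle_deg = angle_deg %% 180,
                  aspect_ratio = aspect_ratio, sxx = sxx, sxy = sxy, syy = syy)
  if (nrow(d) == 0) stop("empty cell table")
  if (any(d$aspect_ratio < 1)) stop("aspect_ratio must be >= 1")
  class(d) <- c("cell_table", "data.frame")
  d
}

#' Director field on a regular lattice
#'
#' The common currency between experiment-like data and simulation output:
#' an angle field (radians, wrapped to `[0, pi)`) with non-negative
#' magnitude weights (aspect-ratio deviation or stress magnitude), lattice
#' constant `dl` and origin. Sites are cell-centred: site `(i, j)` sits at
#' `origin + (i - 1/2, j - 1/2) * dl`.
#'
#' @param angle matrix of director angles (radians).
#' @param magnitude matrix of weights (>= 0); scalar recycled.
#' @param dl lattice constant (um, or LB units for simulation grids).
#' @param origin lower-left corner `c(x0, y0)`.
#' @param periodic logical.
#' @param isotropic optional logical matrix flagging undefined-angle sites.
#' @export
director_grid <- function(angle, magnitude = 1, dl = 1, origin = c(0, 0),
                          periodic = FALSE, isotropic = NULL) {
  angle <- wrap_pi(as.matrix(angle))
  if (length(magnitude) == 1) magnitude <- matrix(magnitude, nrow(angle), ncol(angle))
  if (is.null(isotropic)) isotropic <- matrix(FALSE, nrow(angle), ncol(angle))
  stopifnot(all(magnitude >= 0, na.rm = TRUE))
  structure(list(angle = angle, magnitude = magnitude, dl = dl,
                 origin = origin, periodic = isTRUE(periodic),
                 isotropic = isotropic),
            class = "director_grid")
}

#' @export
print.director_grid <- function(x, ...) {
  cat(sprintf("<director_grid %d x %d, dl = %.3g%s>\n", nrow(x$angle),
              ncol(x$angle), x$dl, if (x$periodic) ", periodic" else ""))
  invisible(x)
}

#' Central-disc mask of a director grid
#'
#' Logical matrix marking sites within a disc centred on the grid — the
#' island averaging protocol restricts statistics to a central
#' disc (default diameter 312 um) to avoid edge effects.
#'
#' @param grid a [director_grid()].
#' @param diameter disc diameter, in the grid's length units.
#' @param centre disc centre `c(x, y)`; defaults to the grid centre.
#' @return logical matrix of the grid's dimension.
#' @export
site_disc_mask <- function(grid, diameter = 312, centre = NULL) {
  sc <- site_coords(grid)
  centre <- centre %||% c(mean(range(sc$x)), mean(range(sc$y)))
  outer(sc$x - centre[1], sc$y - centre[2],
        function(a, b) a^2 + b^2) <= (diameter / 2)^2
}

site_coords <- function(grid) {
  list(x = grid$origin[1] + (seq_len(nrow(grid$angle)) - 0.5) * grid$dl,
       y = grid$origin[2] + (seq_len(ncol(grid$angle)) - 0.5) * grid$dl)
}

#' Map a cell table onto a square lattice
#'
#' Lattice constant `dl = L / sqrt(N)` (one site per cell on average); each
#' cell is assigned to its closest lattice site. When several cells land on
#' one site the closest cell wins (ties broken by row order); sites left
#' empty are filled from the nearest occupied site.
#'
#' @param cells a [cell_table()].
#' @param L island extent (um); the lattice spans `[origin, origin + L]`.
#' @param origin lower-left corner of the mapped region.
#' @param source `"shape"` (cell angles, magnitude = aspect ratio - 1) or
#'   `"stress"` (principal contractile axis of the per-cell stress tensor,
#'   magnitude = principal deviatoric stress).
#' @return a [director_grid()].
#' @export
cells_to_grid <- function(cells, L, origin = c(0, 0),
                          source = c("shape", "stress")) {
  source <- match.arg(source)
  n_cell <- nrow(cells)
  if (n_cell < 4) stop("need at least 4 cells")
  nside <- round(sqrt(n_cell))
  dl <- L / nside
  if (source == "shape") {
    ang <- deg2rad(cells$angle_deg)
    mag <- pmax(cells$aspect_ratio - 1, 0)
    iso <- rep(FALSE, n_cell)
  } else {
    pr <- principal_stress_axis(cells$sxx, cells$sxy, cells$syy)
    ang <- pr$angle
    mag <- pr$magnitude
    iso <- pr$isotropic
    ang[iso] <- 0
  }
  ix <- pmin(pmax(round((cells$x_um - origin[1]) / dl + 0.5), 1), nside)
  iy <- pmin(pmax(round((cells$y_um - origin[2]) / dl + 0.5), 1), nside)
  site <- ix + (iy - 1) * nside
  sx <- origin[1] + (ix - 0.5) * dl
  sy <- origin[2] + (iy - 0.5) * dl
  d2 <- (cells$x_um - sx)^2 + (cells$y_um - sy)^2
  ord <- order(site, d2, seq_len(n_cell)) # nearest wins, then input order
  keep <- ord[!duplicated(site[ord])]
  angle_m <- matrix(NA_real_, nside, nside)
  mag_m <- matrix(NA_real_, nside, nside)
  iso_m <- matrix(FALSE, nside, nside)
  angle_m[site[keep]] <- ang[keep]
  mag_m[site[keep]] <- mag[keep]
  iso_m[site[keep]] <- iso[keep]
  empty <- which(is.na(angle_m))
  if (length(empty)) {
    occ <- which(!is.na(angle_m))
    gx <- (seq_len(nside) - 0.5) * dl
    ex <- gx[(empty - 1) %% nside + 1]; ey <- gx[(empty - 1) %/% nside + 1]
    ox <- gx[(occ - 1) %% nside + 1];   oy <- gx[(occ - 1) %/% nside + 1]
    nearest <- apply(outer(ex, ox, "-")^2 + outer(ey, oy, "-")^2, 1, which.min)
    angle_m[empty] <- angle_m[occ[nearest]]
    mag_m[empty] <- mag_m[occ[nearest]]
    iso_m[empty] <- iso_m[occ[nearest]]
  }
  director_grid(angle_m, mag_m, dl = dl, origin = origin, periodic = FALSE,
                isotropic = iso_m)
}

# Bilinear interpolation of matrix `m` (nodes at integer coords 1..n) at
# fractional coordinates (px, py); periodic wrap or clamped edges.
bilinear <- function(m, px, py, periodic) {
  nx <- nrow(m); ny <- ncol(m)
  i0 <- floor(px); j0 <- floor(py)
  fx <- px - i0; fy <- py - j0
  wrap <- function(i, n) if (periodic) ((i - 1) %% n) + 1 else pmin(pmax(i, 1), n)
  i0w <- wrap(i0, nx); i1w <- wrap(i0 + 1, nx)
  j0w <- wrap(j0, ny); j1w <- wrap(j0 + 1, ny)
  m[cbind(i0w, j0w)] * (1 - fx) * (1 - fy) + m[cbind(i1w, j0w)] * fx * (1 - fy) +
    m[cbind(i0w, j1w)] * (1 - fx) * fy + m[cbind(i1w, j1w)] * fx * fy
}

#' Refine a director grid by interpolation
#'
#' Linear interpolation onto a mesh `factor` times finer, performed on the
#' nematic components `(cos 2 psi, sin 2 psi)` (equivalently the Q-tensor
#' components) and never on raw angles, which are ill-defined at the 180-degree
#' wrap: the midpoint of 10 and 170 degrees is 0 degrees, not 90. Needed
#' before defect finding on coarse cell-derived lattices.
#'
#' @param grid a [director_grid()].
#' @param factor integer >= 1; 1 returns the grid unchanged.
#' @return a [director_grid()] with lattice constant `dl / factor`.
#' @export
refine_grid <- function(grid, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(grid)
  nx <- nrow(grid$angle); ny <- ncol(grid$angle)
  cc <- cos(2 * grid$angle); ss <- sin(2 * grid$angle)
  if (grid$periodic) {
    px <- seq(1, nx + 1 - 1 / factor, by = 1 / factor)
    py <- seq(1, ny + 1 - 1 / factor, by = 1 / factor)
  } else {
    px <- seq(1, nx, by = 1 / factor)
    py <- seq(1, ny, by = 1 / factor)
  }
  P <- expand.grid(px = px, py = py)
  c2 <- bilinear(cc, P$px, P$py, grid$periodic)
  s2 <- bilinear(ss, P$px, P$py, grid$periodic)
  mg <- bilinear(grid$magnitude, P$px, P$py, grid$periodic)
  ang <- wrap_pi(0.5 * atan2(s2, c2))
  dims <- c(length(px), length(py))
  director_grid(matrix(ang, dims[1], dims[2]),
                matrix(mg, dims[1], dims[2]),
                dl = grid$dl / factor,
                origin = grid$origin, periodic = grid$periodic)
}

#' Principal axis of contractile stress
#'
#' The measured stress tensor is first made traceless by adding the constant
#' `c = -(sxx + syy)/2` to the diagonal; the contractile orientation `m` is
#' the eigendirection of the positive principal (outward-pulling) stress,
#' `theta_p = atan2(2 sxy, sxx - syy)/2`, with magnitude equal to the
#' positive eigenvalue `sqrt(((sxx - syy)/2)^2 + sxy^2)`. Isotropic tensors
#' (zero magnitude) have undefined orientation and are flagged.
#'
#' @param sxx,sxy,syy stress components (vectors or matrices).
#' @param tol isotropy threshold on the magnitude.
#' @return list with `angle` (radians in `[0, pi)`; `NA` where isotropic),
#'   `magnitude` and the logical `isotropic` flag.
#' @export
principal_stress_axis <- function(sxx, sxy, syy, tol = 1e-12) {
  mag <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  iso <- mag < tol
  angle <- wrap_pi(0.5 * atan2(2 * sxy, sxx - syy))
  angle[iso] <- NA_real_
  list(angle = angle, magnitude = mag, isotropic = iso)
}

#' Misalignment between shape and stress directors
#'
#' `theta` is the minimum angular distance between the two headless
#' directors, in degrees within `[0, 90]`. Sites with `theta > 45` are
#' extensile (the cell pulls along its short axis), `theta <= 45` contractile;
#' the tie at exactly 45 degrees is classified contractile. Sites flagged
#' isotropic in either input are excluded (`NA`).
#'
#' @param n_grid,m_grid co-registered [director_grid()]s (same dimension and
#'   lattice constant).
#' @param frame optional provenance tag.
#' @return a `misalignment_map`: list with `theta` (degrees), logical
#'   `extensile` and `valid` matrices, `dl`, `periodic`, `frame`.
#' @export
misalignment <- function(n_grid, m_grid, frame = NA) {
  stopifnot(identical(dim(n_grid$angle), dim(m_grid$angle)))
  d <- abs(n_grid$angle - m_grid$angle) %% pi
  theta <- rad2deg(pmin(d, pi - d))
  valid <- !(n_grid$isotropic | m_grid$isotropic | is.na(theta))
  theta[!valid] <- NA_real_
  structure(list(theta = theta, extensile = !is.na(theta) & theta > 45,
                 valid = valid, dl = n_grid$dl,
                 periodic = n_grid$periodic && m_grid$periodic, frame = frame),
            class = "misalignment_map")
}

#' @export
print.misalignment_map <- function(x, ...) {
  cat(sprintf(
    "<misalignment_map %d x %d, extensile fraction %.3f>\n",
    nrow(x$theta), ncol(x$theta),
    sum(x$extensile[x$valid]) / max(1, sum(x$valid))))
  invisible(x)
}

#' @param x a `misalignment_map`.
#' @param ... passed to [graphics::image()].
#' @rdname misalignment
#' @export
plot.misalignment_map <- function(x, ...) {
  graphics::image(x$theta, zlim = c(0, 90), useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "Blue-Red", rev = TRUE),
                  main = "misalignment angle (degrees)", ...)
  invisible(x)
}
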