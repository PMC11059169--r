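#' Detect half-integer topological defects in a director field
#'
#' Computes the winding number of the director angle around every unit
#' plaquette, with successive corner differences wrapped into
#' `(-pi/2, pi/2]`; a winding of `+pi` (`-pi`) marks a `+1/2` (`-1/2`)
#' defect. Adjacent same-charge plaquettes are merged into a single defect
#' at their centroid. The orientation of each defect is extracted from the
#' local Q-gradient polarity: for `+1/2` the comet axis
#' `atan2(<dx Qxy - dy Qxx>, <dx Qxx + dy Qxy>)`, for `-1/2` one of the
#' three symmetry axes (reported mod `2 pi / 3`); both conventions are
#' rotation-equivariant.
#'
#' On coarse cell-derived lattices, [refine_grid()] first.
#'
#' @param grid a [director_grid()] (or a bare angle matrix in radians).
#' @param periodic used when `grid` is a bare matrix.
#' @return a `defect_set` data frame with columns `x`, `y` (site
#'   coordinates, 1-based, plaquette centres at half-integers), `charge`
#'   (`+0.5`/`-0.5`) and `orientation` (radians). On a periodic domain the
#'   total charge is zero.
#' @export
find_defects <- function(grid, periodic = NULL) {
  if (is.matrix(grid)) grid <- director_grid(grid, periodic = periodic %||% TRUE)
  psi <- grid$angle
  nx <- nrow(psi); ny <- ncol(psi)
  if (grid$periodic) {
    p00 <- psi
    p10 <- shift_mat(psi, 1, 0); p11 <- shift_mat(psi, 1, 1)
    p01 <- shift_mat(psi, 0, 1)
  } else {
    p00 <- psi[-nx, -ny]; p10 <- psi[-1, -ny]
    p11 <- psi[-1, -1];   p01 <- psi[-nx, -1]
  }
  w <- wrap_half_pi(p10 - p00) + wrap_half_pi(p11 - p10) +
    wrap_half_pi(p01 - p11) + wrap_half_pi(p00 - p01)
  charge_m <- round(w / (2 * pi) * 2) / 2 # 0 or +-1/2 (rarely +-1)
  hit <- which(charge_m != 0)
  empty <- structure(
    data.frame(x = numeric(0), y = numeric(0), charge = numeric(0),
               orientation = numeric(0)),
    class = c("defect_set", "data.frame"), total_charge = 0)
  if (!length(hit)) return(empty)
  mx <- nrow(charge_m)
  px <- (hit - 1) %% mx + 1
  py <- (hit - 1) %/% mx + 1
  ch <- charge_m[hit]
  cl <- cluster_plaquettes(px, py, ch, nx, ny, grid$periodic)
  # merged defect positions: circular-mean of member plaquette centres
  pos <- t(vapply(seq_len(max(cl)), function(g) {
    sel <- which(cl == g)
    c(periodic_mean(px[sel] + 0.5, nx, grid$periodic),
      periodic_mean(py[sel] + 0.5, ny, grid$periodic),
      ch[sel[1]])
  }, numeric(3)))
  ori <- defect_orientation(psi, pos[, 1], pos[, 2], pos[, 3], grid$periodic)
  out <- data.frame(x = pos[, 1], y = pos[, 2], charge = pos[, 3],
                    orientation = ori)
  structure(out, class = c("defect_set", "data.frame"),
            total_charge = sum(out$charge))
}

# Merge 8-adjacent same-charge plaquettes into single defects (transitive
# closure, i.e. single linkage at lattice adjacency). Label propagation on
# the plaquette grid keeps this O(grid) even for the defect-dense random
# initial frames, where pairwise-distance clustering would need gigabytes.
cluster_plaquettes <- function(px, py, ch, mx, my, periodic) {
  k <- length(px)
  if (k == 1) return(1L)
  sel <- cbind(px, py)
  lab <- matrix(0L, mx, my); lab[sel] <- seq_len(k)
  chm <- matrix(0, mx, my); chm[sel] <- ch
  occ <- lab > 0L
  shift_open <- function(m, dx, dy) {
    s <- shift_mat(m, dx, dy)
    if (!periodic) { # zero out values that wrapped around the boundary
      if (dx == 1) s[mx, ] <- 0 else if (dx == -1) s[1, ] <- 0
      if (dy == 1) s[, my] <- 0 else if (dy == -1) s[, 1] <- 0
    }
    s
  }
  repeat {
    new_lab <- lab
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      nb <- shift_open(lab, dx, dy)
      nb_ch <- shift_open(chm, dx, dy)
      take <- occ & nb > 0L & nb_ch == chm & nb < new_lab
      new_lab[take] <- nb[take]
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  match(lab[sel], sort(unique(lab[sel])))
}

periodic_mean <- function(v, n, periodic) {
  if (!periodic || diff(range(v)) < n / 2) return(mean(v))
  # cluster straddles the seam: average on the circle
  a <- 2 * pi * v / n
  (atan2(mean(sin(a)), mean(cos(a))) %% (2 * pi)) * n / (2 * pi)
}

defect_orientation <- function(psi, x, y, charge, periodic) {
  Qxx <- 0.5 * cos(2 * psi); Qxy <- 0.5 * sin(2 * psi)
  if (periodic) {
    a <- ddx(Qxx) + ddy(Qxy)
    b <- ddx(Qxy) - ddy(Qxx)
  } else {
    a <- b <- matrix(0, nrow(psi), ncol(psi))
    in_x <- 2:(nrow(psi) - 1); in_y <- 2:(ncol(psi) - 1)
    a[in_x, in_y] <- (Qxx[in_x + 1, in_y] - Qxx[in_x - 1, in_y]) / 2 +
      (Qxy[in_x, in_y + 1] - Qxy[in_x, in_y - 1]) / 2
    b[in_x, in_y] <- (Qxy[in_x + 1, in_y] - Qxy[in_x - 1, in_y]) / 2 -
      (Qxx[in_x, in_y + 1] - Qxx[in_x, in_y - 1]) / 2
  }
  nx <- nrow(psi); ny <- ncol(psi)
  vapply(seq_along(x), function(i) {
    ii <- round(x[i]) + (-2:2); jj <- round(y[i]) + (-2:2)
    if (periodic) {
      ii <- (ii - 1) %% nx + 1; jj <- (jj - 1) %% ny + 1
    } else {
      ii <- ii[ii >= 1 & ii <= nx]; jj <- jj[jj >= 1 & jj <= ny]
    }
    if (charge[i] > 0) {
      atan2(mean(b[ii, jj]), mean(a[ii, jj]))
    } else {
      gx <- outer(ii - x[i], rep(1, length(jj)))
      gy <- outer(rep(1, length(ii)), jj - y[i])
      phi <- atan2(gy, gx)
      z <- sum(complex(real = a[ii, jj], imaginary = b[ii, jj]) *
                 exp(2i * phi))
      (Arg(z) / 3) %% (2 * pi / 3)
    }
  }, numeric(1))
}

#' Fraction of defects lying inside the interface band
#'
#' Each defect position is rounded to its nearest lattice site and checked
#' against the interface mask. With no defects the fraction is undefined and
#' returned as `NA` (flagged), never 0.
#'
#' @param defects a `defect_set` from [find_defects()].
#' @param interface logical interface mask (from [interface_domains()]).
#' @param periodic whether defect coordinates wrap.
#' @return scalar fraction in `[0, 1]`, or `NA` for an empty defect set.
#' @export
defect_interface_colocalization <- function(defects, interface,
                                            periodic = TRUE) {
  if (nrow(defects) == 0) return(NA_real_)
  nx <- nrow(interface); ny <- ncol(interface)
  ix <- round(defects$x); iy <- round(defects$y)
  if (periodic) {
    ix <- (ix - 1) %% nx + 1; iy <- (iy - 1) %% ny + 1
  } else {
    ix <- pmin(pmax(ix, 1), nx); iy <- pmin(pmax(iy, 1), ny)
  }
  mean(interface[cbind(ix, iy)])
}
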