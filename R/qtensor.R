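#' Symmetric traceless Q-tensor field on a regular grid
#'
#' Stores only the two independent components `xx` and `xy`; `Qyy = -Qxx` and
#' `Qyx = Qxy` are implied, so tracelessness and symmetry hold by
#' construction. Grid spacing is one lattice unit.
#'
#' @param xx,xy numeric matrices of equal dimension.
#' @param periodic logical; whether the grid wraps (simulation domains do).
#' @return an object of class `qtensor_field`.
#' @export
qtensor_field <- function(xx, xy, periodic = TRUE) {
  xx <- as.matrix(xx); xy <- as.matrix(xy)
  stopifnot(identical(dim(xx), dim(xy)))
  structure(list(xx = xx, xy = xy, periodic = isTRUE(periodic)),
            class = "qtensor_field")
}

#' @export
print.qtensor_field <- function(x, ...) {
  d <- director_from_q(x)
  cat(sprintf("<qtensor_field %d x %d (%s), mean S = %.4f>\n",
              nrow(x$xx), ncol(x$xx),
              if (x$periodic) "periodic" else "bounded", mean(d$S)))
  invisible(x)
}

#' Build a Q-tensor field from order magnitude and director angle
#'
#' `Q = S (d d - I/2)` with director `d = (cos angle, sin angle)`, giving
#' `Qxx = (S/2) cos 2angle` and `Qxy = (S/2) sin 2angle`.
#'
#' @param S order magnitude, a non-negative scalar or matrix.
#' @param angle director angle in radians, a matrix (or scalar with `dim`).
#' @param dim grid dimension `c(nx, ny)` when both `S` and `angle` are scalar.
#' @param periodic passed to [qtensor_field()].
#' @return a [qtensor_field()].
#' @export
q_from_director <- function(S, angle, dim = NULL, periodic = TRUE) {
  if (any(S < 0)) stop("order magnitude S must be non-negative")
  if (!is.null(dim)) {
    angle <- matrix(angle, dim[1], dim[2])
    if (length(S) == 1) S <- matrix(S, dim[1], dim[2])
  }
  angle <- as.matrix(angle)
  qtensor_field(xx = (S / 2) * cos(2 * angle),
                xy = (S / 2) * sin(2 * angle),
                periodic = periodic)
}

#' Recover order magnitude and director angle from a Q-tensor field
#'
#' Inverse of [q_from_director()]: `S = 2 sqrt(Qxx^2 + Qxy^2)`,
#' `angle = atan2(Qxy, Qxx) / 2` wrapped into `[0, pi)`. Isotropic sites
#' (`S` below `tol`) get angle 0 by convention and are flagged.
#'
#' @param Q a [qtensor_field()].
#' @param tol isotropy threshold on `S`.
#' @return list with matrices `S`, `angle` (radians in `[0, pi)`) and the
#'   logical flag matrix `isotropic`.
#' @export
director_from_q <- function(Q, tol = 1e-12) {
  S <- 2 * sqrt(Q$xx^2 + Q$xy^2)
  iso <- S < tol
  angle <- wrap_pi(0.5 * atan2(Q$xy, Q$xx))
  angle[iso] <- 0
  list(S = S, angle = angle, isotropic = iso)
}

# Full tensor contraction A:B = sum_ij A_ij B_ij = 2 (Axx Bxx + Axy Bxy).
q_contract <- function(A, B) 2 * (A$xx * B$xx + A$xy * B$xy)
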