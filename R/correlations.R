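#' Spatial and temporal orientation correlation functions
#'
#' Nematic two-point correlator
#' `C(r) = < cos 2(psi(r0 + r) - psi(r0)) >` over space and frames (spatial
#' mode) or `C(t) = < cos 2(psi(r0, t0 + t) - psi(r0, t0)) >` over sites and
#' time origins (temporal mode). Applies to the shape angle, the stress
#' angle, or the misalignment angle itself. `C(0) = 1` exactly. Spatial
#' averaging can be restricted to a mask (e.g. a central disc on island
#' data, to avoid edge effects); simulation domains use the full periodic
#' box.
#'
#' Spatial correlations are computed with FFTs (mask-normalized,
#' zero-padded for bounded domains) and binned by rounded Euclidean
#' distance; bins with fewer than `min_pairs` site pairs are dropped.
#'
#' @param psi angle field(s) in radians: a matrix, a list of matrices, or a
#'   3-D array with frames along the third dimension.
#' @param mode `"spatial"` or `"temporal"`.
#' @param mask optional logical matrix restricting the average.
#' @param periodic whether the domain wraps (ignored when `mask` given).
#' @param dl lattice constant: output `r` is in these units.
#' @param frame_interval time between frames; output `t` is in these units.
#' @param max_lag maximum temporal lag, in frames.
#' @param min_pairs minimum pair count per spatial bin.
#' @return data frame with `r` (or `t`), `C` and `npairs`.
#' @export
orientation_correlation <- function(psi, mode = c("spatial", "temporal"),
                                    mask = NULL, periodic = TRUE, dl = 1,
                                    frame_interval = 1, max_lag = NULL,
                                    min_pairs = 10) {
  mode <- match.arg(mode)
  frames <- as_frame_list(psi)
  if (mode == "spatial") {
    acc <- NULL
    for (f in frames) {
      cur <- field_autocorr(list(cos(2 * f), sin(2 * f)), mask, periodic)
      acc <- if (is.null(acc)) cur else
        list(num = acc$num + cur$num, den = acc$den + cur$den, r = cur$r)
    }
    radial_bin(acc, dl, min_pairs)
  } else {
    if (length(frames) < 2) stop("temporal mode needs at least 2 frames")
    temporal_corr(frames, mask, frame_interval, max_lag,
                  function(a, b) cos(2 * (a - b)))
  }
}

#' Velocity autocorrelation function
#'
#' `C(r) = <u(r0 + r) . u(r0)> / <|u(r0)|^2>`, normalized so `C(0) = 1`;
#' same spatial binning machinery as [orientation_correlation()]. A flow
#' that is zero everywhere has an undefined correlation (`NA`, flagged).
#'
#' @param ux,uy velocity components: matrices, lists, or 3-D arrays.
#' @inheritParams orientation_correlation
#' @return data frame with `r`, `C`, `npairs`.
#' @export
velocity_correlation <- function(ux, uy, mask = NULL, periodic = TRUE,
                                 dl = 1, min_pairs = 10) {
  fx <- as_frame_list(ux); fy <- as_frame_list(uy)
  if (max(abs(unlist(fx)), abs(unlist(fy))) == 0) {
    out <- data.frame(r = 0, C = NA_real_, npairs = 0)
    attr(out, "flagged") <- "zero velocity field"
    return(out)
  }
  acc <- NULL
  for (k in seq_along(fx)) {
    cur <- field_autocorr(list(fx[[k]], fy[[k]]), mask, periodic)
    acc <- if (is.null(acc)) cur else
      list(num = acc$num + cur$num, den = acc$den + cur$den, r = cur$r)
  }
  out <- radial_bin(acc, dl, min_pairs)
  out$C <- out$C / out$C[1]
  out
}

as_frame_list <- function(x) {
  if (is.list(x)) lapply(x, as.matrix)
  else if (length(dim(x)) == 3) lapply(seq_len(dim(x)[3]), function(k) x[, , k])
  else list(as.matrix(x))
}

# Sum over components of the (mask-normalized) spatial autocorrelation.
# Returns per-displacement numerator/pair-count grids and the distance grid.
field_autocorr <- function(comps, mask, periodic) {
  nx <- nrow(comps[[1]]); ny <- ncol(comps[[1]])
  if (is.null(mask) && periodic) {
    num <- Reduce(`+`, lapply(comps, function(m) {
      F <- fft(m); Re(fft(F * Conj(F), inverse = TRUE)) / length(m)
    }))
    den <- matrix(nx * ny, nx, ny)
    dx <- pmin(0:(nx - 1), nx - 0:(nx - 1))
    dy <- pmin(0:(ny - 1), ny - 0:(ny - 1))
  } else {
    if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
    px <- 2 * nx; py <- 2 * ny
    padded <- function(m) { z <- matrix(0, px, py); z[1:nx, 1:ny] <- m; z }
    mm <- padded(mask * 1)
    FM <- fft(mm)
    num <- Reduce(`+`, lapply(comps, function(m) {
      F <- fft(padded(ifelse(mask, m, 0)))
      Re(fft(F * Conj(F), inverse = TRUE)) / (px * py)
    }))
    den <- Re(fft(FM * Conj(FM), inverse = TRUE)) / (px * py)
    dx <- pmin(0:(px - 1), px - 0:(px - 1))
    dy <- pmin(0:(py - 1), py - 0:(py - 1))
  }
  r <- sqrt(outer(dx^2, dy^2, "+"))
  list(num = num, den = den, r = r)
}

radial_bin <- function(acc, dl, min_pairs) {
  bin <- round(acc$r)
  ok <- acc$den > 0.5
  num_b <- tapply(acc$num[ok], bin[ok], sum)
  den_b <- tapply(acc$den[ok], bin[ok], sum)
  rr <- as.numeric(names(num_b))
  keep <- den_b >= min_pairs
  out <- data.frame(r = rr[keep] * dl, C = (num_b / den_b)[keep],
                    npairs = round(den_b[keep]))
  rownames(out) <- NULL
  out[order(out$r), , drop = FALSE]
}

temporal_corr <- function(frames, mask, frame_interval, max_lag, kernel) {
  nt <- length(frames)
  max_lag <- min(max_lag %||% (nt - 1), nt - 1)
  sel <- if (is.null(mask)) TRUE else mask
  C <- vapply(0:max_lag, function(lag) {
    v <- vapply(seq_len(nt - lag), function(t0) {
      mean(kernel(frames[[t0 + lag]][sel], frames[[t0]][sel]))
    }, numeric(1))
    mean(v)
  }, numeric(1))
  data.frame(t = (0:max_lag) * frame_interval, C = C,
             npairs = (nt - 0:max_lag))
}

#' Decay length (or time) of a correlation curve
#'
#' First crossing of `C` below `level` (default `1/e`), linearly
#' interpolated. Returns `NA` (flagged) if the curve never crosses.
#'
#' @param curve data frame from the correlation functions (`r` or `t`, `C`).
#' @param level threshold.
#' @return scalar crossing position, in the curve's units.
#' @export
correlation_length <- function(curve, level = exp(-1)) {
  x <- curve[[1]]; C <- curve$C
  below <- which(C < level)
  if (!length(below)) {
    out <- NA_real_; attr(out, "flagged") <- "no crossing"; return(out)
  }
  i <- below[1]
  if (i == 1) return(x[1])
  x[i - 1] + (level - C[i - 1]) * (x[i] - x[i - 1]) / (C[i] - C[i - 1])
}

#' Stress magnitude binned by misalignment angle
#'
#' Within each sample (frame or experiment) magnitudes are rescaled by their
#' maximum, then pooled and averaged in `n_bins` equal bins of `theta` over
#' `[0, 90]` degrees. The rescaling makes the curve invariant to global
#' stress scale per sample.
#'
#' @param magnitude stress magnitudes: matrix/vector or list of such (one
#'   element per sample).
#' @param theta misalignment angles in degrees, same shape as `magnitude`.
#' @param n_bins number of theta bins.
#' @return data frame with `theta` (bin centres), `mean`, `sd`, `n`; empty
#'   bins are reported with `n = 0` and `NA` statistics (flagged).
#' @export
stress_vs_misalignment <- function(magnitude, theta, n_bins = 9) {
  if (!is.list(magnitude)) { magnitude <- list(magnitude); theta <- list(theta) }
  vals <- unlist(lapply(seq_along(magnitude), function(k) {
    m <- as.numeric(magnitude[[k]])
    mx <- max(m, na.rm = TRUE)
    if (mx > 0) m / mx else m
  }))
  th <- unlist(lapply(theta, as.numeric))
  ok <- !is.na(vals) & !is.na(th)
  breaks <- seq(0, 90, length.out = n_bins + 1)
  b <- cut(pmin(pmax(th[ok], 0), 90), breaks, include.lowest = TRUE)
  data.frame(theta = (head(breaks, -1) + tail(breaks, -1)) / 2,
             mean = as.numeric(tapply(vals[ok], b, mean)),
             sd = as.numeric(tapply(vals[ok], b, sd)),
             n = as.numeric(table(b)))
}

#' Distribution of the misalignment angle
#'
#' Density-normalized histogram of `theta` over `[0, 90]` degrees, reported
#' together with the extensile fraction (`theta > 45`, strict).
#'
#' @param theta misalignment angles in degrees (vector, matrix or
#'   `misalignment_map`); `NA`s are dropped.
#' @param n_bins number of bins.
#' @return data frame with `theta` (bin centres), `density` and `count`;
#'   the extensile fraction is attached as attribute `extensile_fraction`.
#' @export
misalignment_histogram <- function(theta, n_bins = 18) {
  if (inherits(theta, "misalignment_map")) theta <- theta$theta
  th <- as.numeric(theta)
  th <- th[!is.na(th)]
  stopifnot(all(th >= 0 & th <= 90))
  breaks <- seq(0, 90, length.out = n_bins + 1)
  h <- hist(th, breaks = breaks, plot = FALSE)
  out <- data.frame(theta = h$mids, density = h$density, count = h$counts)
  attr(out, "extensile_fraction") <- mean(th > 45)
  out
}

#' @importFrom graphics hist
NULL
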