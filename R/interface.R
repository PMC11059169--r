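#' Interface domains between extensile and contractile regions
#'
#' A site belongs to the interface domain when its Euclidean distance to the
#' nearest site of the opposite class is at most `r_max` — the band of
#' tissue within the stress-measurement resolution (5.2 um, i.e. ~1.73
#' lattice units at 3 um per lattice unit) of an extensile/contractile
#' boundary. Interface sites are removed from the extensile and contractile
#' tallies so the three area fractions partition the tissue.
#'
#' @param mask logical extensile mask (or a `misalignment_map`).
#' @param r_max interface half-width, in units of `dl`.
#' @param dl lattice constant (same units as `r_max`).
#' @param periodic whether the domain wraps.
#' @param valid optional logical matrix restricting the statistics.
#' @return list with the logical `interface` mask and `fractions`, a named
#'   vector `(interface, extensile, contractile)` summing to 1.
#' @export
interface_domains <- function(mask, r_max, dl = 1, periodic = TRUE,
                              valid = NULL) {
  if (inherits(mask, "misalignment_map")) {
    if (is.null(valid)) valid <- mask$valid
    dl <- mask$dl; periodic <- mask$periodic
    mask <- mask$extensile
  }
  if (is.null(valid)) valid <- matrix(TRUE, nrow(mask), ncol(mask))
  if (r_max <= 0) stop("r_max must be positive")
  r_sites <- r_max / dl
  if (all(mask[valid]) || !any(mask[valid])) {
    interface <- matrix(FALSE, nrow(mask), ncol(mask))
  } else {
    d_opp <- dist_to_opposite(mask, periodic, pad = ceiling(r_sites) + 1)
    interface <- d_opp <= r_sites + 1e-9
  }
  nv <- sum(valid)
  fr <- c(interface = sum(interface & valid) / nv,
          extensile = sum(mask & !interface & valid) / nv,
          contractile = sum(!mask & !interface & valid) / nv)
  list(interface = interface, fractions = fr)
}

# Distance from every site to the nearest opposite-class site, via the
# EBImage distance transform on a wrap-padded (or edge-padded) array.
dist_to_opposite <- function(mask, periodic, pad = 4) {
  nx <- nrow(mask); ny <- ncol(mask)
  if (periodic) {
    big <- mask[c((nx - pad + 1):nx, 1:nx, 1:pad),
                c((ny - pad + 1):ny, 1:ny, 1:pad)]
  } else {
    big <- mask[c(rep(1, pad), 1:nx, rep(nx, pad)),
                c(rep(1, pad), 1:ny, rep(ny, pad))]
  }
  # distmap: distance of foreground pixels to nearest background pixel
  d_fg <- as.matrix(EBImage::distmap(EBImage::Image(big * 1)))
  d_bg <- as.matrix(EBImage::distmap(EBImage::Image((!big) * 1)))
  d <- ifelse(big, d_fg, d_bg)
  d[pad + (1:nx), pad + (1:ny)]
}
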