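#' Bulk free-energy density of the coupled order parameters
#'
#' Per-site value of
#' \deqn{\frac{C}{2}(1-3Q^n\!:\!Q^n)^2 + \frac{C}{2}(1-3Q^m\!:\!Q^m)^2 +
#'       \frac{J}{2}(1-3Q^n\!:\!Q^m)^2.}
#' The `C` terms select ordered states with `S = sqrt(2/3)`; the `J` term
#' aligns the stress director with the shape director. With
#' `model_params(coupling = "harmonic")` the alignment term is
#' `(J/2)|Qn - Qm|^2` instead.
#'
#' @param Qn,Qm shape and stress [qtensor_field()]s on a shared grid.
#' @param params a [model_params()] list.
#' @return matrix of energy densities (LB units).
#' @export
bulk_energy_density <- function(Qn, Qm, params) {
  stopifnot(identical(dim(Qn$xx), dim(Qm$xx)))
  qqn <- q_contract(Qn, Qn)
  qqm <- q_contract(Qm, Qm)
  order_terms <- (params$C / 2) * (1 - 3 * qqn)^2 +
    (params$C / 2) * (1 - 3 * qqm)^2
  if (coupling_code(params) == 0L) {
    qnm <- q_contract(Qn, Qm)
    order_terms + (params$J / 2) * (1 - 3 * qnm)^2
  } else {
    order_terms + params$J * ((Qn$xx - Qm$xx)^2 + (Qn$xy - Qm$xy)^2)
  }
}

coupling_code <- function(params) {
  if (identical(params$coupling %||% "quartic", "harmonic")) 1L else 0L
}

#' Elastic (gradient) free-energy density
#'
#' `(K_n/2)|grad Q^n|^2 + (K_m/2)|grad Q^m|^2`, with
#' `|grad Q|^2 = 2(|grad Qxx|^2 + |grad Qxy|^2)` for the two-component
#' representation. Discretized with compact one-sided differences on the
#' periodic grid so that the 5-point Laplacian used in the molecular field is
#' the exact discrete functional derivative of this energy (see the methods
#' vignette).
#'
#' @inheritParams bulk_energy_density
#' @return matrix of energy densities.
#' @export
elastic_energy_density <- function(Qn, Qm, params) {
  gsq <- function(m) {
    (shift_mat(m, 1, 0) - m)^2 + (shift_mat(m, 0, 1) - m)^2
  }
  params$K_n * (gsq(Qn$xx) + gsq(Qn$xy)) +
    params$K_m * (gsq(Qm$xx) + gsq(Qm$xy))
}

#' Exterior bulk energy density for island geometries
#'
#' Outside the circular island the bulk energy is
#' `(C'/2)(Qn:Qn)^2 + (C'/2)(Qm:Qm)^2`, minimized by zero order, so
#' relaxation melts the nematic outside the tissue.
#'
#' @inheritParams bulk_energy_density
#' @param C_prime exterior bulk energy scale.
#' @param exterior logical matrix marking exterior sites; `NULL` means all.
#' @return matrix of energy densities (zero at interior sites).
#' @export
exterior_bulk_energy_density <- function(Qn, Qm, C_prime, exterior = NULL) {
  if (is.null(C_prime) || is.na(C_prime)) stop("C_prime (and island radius R) required")
  qqn <- q_contract(Qn, Qn)
  qqm <- q_contract(Qm, Qm)
  e <- (C_prime / 2) * (qqn^2 + qqm^2)
  if (!is.null(exterior)) e[!exterior] <- 0
  e
}

#' Molecular fields of the free energy
#'
#' `H^x = -(df/dQ^x - (I/2) Tr df/dQ^x)`: the traceless negative functional
#' derivative driving relaxation `dQ/dt = gamma H` downhill in free energy.
#' In the interior,
#' `H^n = 6C(1-3Qn:Qn)Qn + K_n lap Qn + 3J(1-3Qn:Qm)Qm` (and symmetrically
#' for `m`); at exterior sites the `C` and `J` terms are replaced by
#' `-2C'(Q:Q)Q`. These expressions were validated against a numerical
#' functional derivative of the discrete free energy (see tests).
#'
#' @inheritParams bulk_energy_density
#' @param which `"n"`, `"m"` or `"both"`.
#' @param interior optional logical matrix; `NULL` = all interior.
#' @return a [qtensor_field()], or a list `(Hn, Hm)` for `"both"`.
#' @export
molecular_field <- function(which = c("both", "n", "m"), Qn, Qm, params,
                            interior = NULL) {
  which <- match.arg(which)
  int_m <- if (is.null(interior)) NULL else
    matrix(as.integer(interior), nrow(Qn$xx), ncol(Qn$xx))
  cp <- if (is.na(params$C_prime %||% NA_real_)) 0 else params$C_prime
  h <- .mol_field_cpp(Qn$xx, Qn$xy, Qm$xx, Qm$xy,
                      params$C, params$K_n, params$K_m, params$J, int_m, cp,
                      coupling_code(params))
  Hn <- qtensor_field(h$Hnxx, h$Hnxy, periodic = Qn$periodic)
  Hm <- qtensor_field(h$Hmxx, h$Hmxy, periodic = Qm$periodic)
  switch(which, n = Hn, m = Hm, both = list(Hn = Hn, Hm = Hm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total free energy of a state
#'
#' Sum of bulk and elastic densities over the grid (unit cell area), with the
#' exterior bulk term substituted outside the island when an interior mask is
#' given. Non-increasing along pure relaxational dynamics.
#'
#' @inheritParams molecular_field
#' @return scalar free energy (LB units).
#' @export
total_free_energy <- function(Qn, Qm, params, interior = NULL) {
  el <- elastic_energy_density(Qn, Qm, params)
  if (is.null(interior)) {
    sum(bulk_energy_density(Qn, Qm, params)) + sum(el)
  } else {
    bulk <- bulk_energy_density(Qn, Qm, params)
    ext <- exterior_bulk_energy_density(Qn, Qm, params$C_prime)
    sum(ifelse(interior, bulk, ext)) + sum(el)
  }
}
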