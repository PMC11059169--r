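#' Model parameters for the two-field active nematic
#'
#' Defaults are the reference parameter sets of the model, in lattice-Boltzmann units. The
#' `"mdck"` set drives active turbulence (`gamma = 0.4, K_m = 0.005,
#' C = 1e-3/3, zeta = -0.03, K_n = 0.065, J = 0.0008, rho = 40, eta = 20/3`);
#' the `"lp9"` set is the passive island variant, identical except
#' `K_m = 0.02, K_n = 0.01, zeta = 0` plus the exterior bulk scale
#' `C_prime = 0.003` and island radius `R = 80`.
#'
#' The shape-stress alignment term is quartic by default,
#' `(J/2)(1 - 3 Qn:Qm)^2`, the literal free-energy form; `coupling =
#' "harmonic"` substitutes the harmonic alignment `(J/2)|Qn - Qm|^2`, whose
#' misalignment-relaxation time is simply `1/(2 gamma J)` (~16 min at the
#' defaults under the standard unit calibration). See the methods vignette
#' for why both forms are provided.
#'
#' @param scenario `"mdck"` or `"lp9"`.
#' @param ... named overrides of individual parameters (including
#'   `coupling`).
#' @return a `model_params` list with elements `C`, `K_n`, `K_m`, `J`,
#'   `gamma`, `zeta`, `rho`, `eta`, and for LP-9 also `C_prime` and `R`.
#' @export
model_params <- function(scenario = c("mdck", "lp9"), ...) {
  scenario <- match.arg(scenario)
  p <- list(C = 1e-3 / 3, K_n = 0.065, K_m = 0.005, J = 0.0008,
            gamma = 0.4, zeta = -0.03, rho = 40, eta = 20 / 3,
            C_prime = NA_real_, R = NA_real_, coupling = "quartic",
            scenario = scenario)
  if (scenario == "lp9") {
    p$K_m <- 0.02; p$K_n <- 0.01; p$zeta <- 0
    p$C_prime <- 0.003; p$R <- 80
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown model parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  for (nm in c("C", "K_n", "K_m", "J", "gamma", "rho", "eta")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || is.na(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive number")
  }
  if (!p$coupling %in% c("quartic", "harmonic"))
    stop("coupling must be 'quartic' or 'harmonic'")
  if (p$zeta > 0)
    warning("zeta > 0 is extensile activity; contractile monolayers have zeta <= 0")
  class(p) <- "model_params"
  p
}

#' BGK relaxation time implied by the model viscosity
#'
#' From `nu = eta/rho = c_s^2 (tau - 1/2)` with `c_s^2 = 1/3`; the MDCK set
#' (`eta = 20/3`, `rho = 40`) gives `tau = 1`.
#'
#' @param params a [model_params()].
#' @return scalar relaxation time in LB steps.
#' @export
lb_tau <- function(params) 3 * params$eta / params$rho + 0.5

#' Run configuration for the hybrid solver
#'
#' Defaults reproduce the reference protocol: a 200 x 200 periodic box run
#' for 120,000 lattice-Boltzmann steps with data collected every 300 steps,
#' initial order magnitude `S = 1` with site-wise random director angles.
#' The unit calibration (3 um per lattice unit from 10 LB units ~ 30 um, and
#' 0.1 min per LB step from 100 LB time units ~ 10 min) is stored here, not
#' hard-coded in operations.
#'
#' @param grid integer vector `c(nx, ny)` or a single size.
#' @param steps total LB steps; must be a multiple of `frame_every`.
#' @param frame_every frame recording interval in steps.
#' @param seed integer seed for the random initial directors.
#' @param S0 initial order magnitude for both tensors.
#' @param scenario `"mdck"` (periodic, active) or `"lp9"` (pinned defect).
#' @param um_per_lu,min_per_step physical calibration of the LB units.
#' @param store_flow keep velocity fields in the trajectory.
#' @return a `run_config` list.
#' @export
run_config <- function(grid = c(200, 200), steps = 120000, frame_every = 300,
                       seed = 1, S0 = 1, scenario = c("mdck", "lp9"),
                       um_per_lu = 3, min_per_step = 0.1, store_flow = TRUE) {
  scenario <- match.arg(scenario)
  if (length(grid) == 1) grid <- c(grid, grid)
  if (steps %% frame_every != 0)
    stop("frame_every must divide steps")
  structure(list(grid = as.integer(grid), steps = as.integer(steps),
                 frame_every = as.integer(frame_every), seed = as.integer(seed),
                 S0 = S0, scenario = scenario, um_per_lu = um_per_lu,
                 min_per_step = min_per_step, store_flow = isTRUE(store_flow)),
            class = "run_config")
}
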