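#' Active stress tensor from the contractile order parameter
#'
#' `Pi_act = -zeta * Q^m`; with `zeta < 0` (contractile) the positive
#' principal axis of `Pi_act` lies along the stress director `m`, so cells
#' pull inward along `m`.
#'
#' @param Qm stress-order [qtensor_field()].
#' @param zeta activity; `zeta <= 0` for contractile monolayers.
#' @return a [qtensor_field()] holding the active stress.
#' @export
active_stress <- function(Qm, zeta) {
  qtensor_field(-zeta * Qm$xx, -zeta * Qm$xy, periodic = Qm$periodic)
}

#' Vorticity of a velocity field
#'
#' Returns the independent component `Omega_xy` of the antisymmetric tensor
#' `Omega_ij = (d_i u_j - d_j u_i)/2`, i.e. half the scalar curl
#' `(dx u_y - dy u_x)/2`, via central differences on the periodic grid. A
#' rigid rotation `u = w(-y, x)` gives uniform `Omega_xy = w`, and both
#' directors co-rotate at the local angular velocity `Omega_xy`.
#'
#' @param ux,uy velocity component matrices.
#' @return matrix `Omega_xy`.
#' @export
vorticity <- function(ux, uy) 0.5 * (ddx(uy) - ddy(ux))

#' Advance the coupled Q-tensor fields
#'
#' Explicit Euler steps of the co-rotational dynamics
#' `(dt + u.grad) Q = -Omega.Q + Q.Omega + gamma H` for both tensors, with
#' central-difference advection. The flow-tumbling parameter is zero: only
#' vorticity rotates the directors.
#'
#' @param Qn,Qm [qtensor_field()]s.
#' @param ux,uy velocity matrices (use 0 for pure relaxation).
#' @param params a [model_params()].
#' @param dt time step (LB units); `|u| dt` must stay below half a grid unit.
#' @param steps number of Euler steps to take.
#' @param interior optional logical matrix for island geometries.
#' @param evolve_n set `FALSE` to pin the shape tensor (LP-9 protocol).
#' @return list with updated `Qn` and `Qm`.
#' @export
update_q <- function(Qn, Qm, ux = 0, uy = 0, params, dt = 1, steps = 1,
                     interior = NULL, evolve_n = TRUE) {
  d <- dim(Qn$xx)
  if (length(ux) == 1) ux <- matrix(ux, d[1], d[2])
  if (length(uy) == 1) uy <- matrix(uy, d[1], d[2])
  cfl <- max(sqrt(ux^2 + uy^2)) * dt
  if (cfl > 0.5)
    stop(sprintf("CFL violation: max |u| dt = %.3f grid units (limit 0.5)", cfl))
  int_m <- if (is.null(interior)) NULL else matrix(as.integer(interior), d[1], d[2])
  cp <- if (is.na(params$C_prime %||% NA_real_)) 0 else params$C_prime
  r <- .q_step_cpp(Qn$xx, Qn$xy, Qm$xx, Qm$xy, ux, uy,
                   params$C, params$K_n, params$K_m, params$J, params$gamma,
                   int_m, cp, dt, as.integer(steps), isTRUE(evolve_n),
                   coupling_code(params))
  list(Qn = qtensor_field(r$Qnxx, r$Qnxy, Qn$periodic),
       Qm = qtensor_field(r$Qmxx, r$Qmxy, Qm$periodic))
}

#' Initialize a lattice-Boltzmann flow state at equilibrium
#'
#' D2Q9 populations set to the discrete Maxwellian for the given density and
#' velocity fields.
#'
#' @param rho density (scalar or matrix).
#' @param ux,uy velocity (scalar or matrix).
#' @param dim grid dimension `c(nx, ny)` when arguments are scalar.
#' @param tau BGK relaxation time; `lb_tau` of a [model_params()] gives the
#'   value implied by `eta/rho` through `nu = (tau - 1/2)/3`.
#' @return a `flow_state` object.
#' @export
lb_equilibrium <- function(rho, ux = 0, uy = 0, dim = NULL, tau = 1) {
  if (!is.null(dim)) {
    rho <- matrix(rho, dim[1], dim[2])
  }
  d <- base::dim(rho)
  if (length(ux) == 1) ux <- matrix(ux, d[1], d[2])
  if (length(uy) == 1) uy <- matrix(uy, d[1], d[2])
  f <- .lb_equilibrium_cpp(rho, ux, uy)
  structure(list(f = f, nx = d[1], ny = d[2], tau = tau,
                 rho = rho, ux = ux, uy = uy),
            class = "flow_state")
}

#' One or more lattice-Boltzmann cycles
#'
#' BGK collision with Guo forcing followed by streaming on the periodic
#' D2Q9 lattice. The macroscopic velocity includes the half-force
#' correction; mass is conserved exactly by streaming.
#'
#' @param flow a `flow_state` from [lb_equilibrium()].
#' @param Fx,Fy body-force matrices (e.g. the divergence of the active
#'   stress); scalars are recycled.
#' @param steps number of collision-stream cycles.
#' @return the updated `flow_state` with refreshed `rho`, `ux`, `uy`.
#' @export
lb_step <- function(flow, Fx = 0, Fy = 0, steps = 1) {
  d <- c(flow$nx, flow$ny)
  if (length(Fx) == 1) Fx <- matrix(Fx, d[1], d[2])
  if (length(Fy) == 1) Fy <- matrix(Fy, d[1], d[2])
  if (!all(is.finite(Fx)) || !all(is.finite(Fy)))
    stop("body force must be finite")
  r <- .lb_run_cpp(flow$f, flow$nx, flow$ny, Fx, Fy, flow$tau, as.integer(steps))
  flow$f <- r$f; flow$rho <- r$rho; flow$ux <- r$ux; flow$uy <- r$uy
  flow
}

#' Run the hybrid active-nematic simulation
#'
#' MDCK scenario: both tensors start at the configured order magnitude with
#' site-wise independent random angles and evolve under the full coupled
#' dynamics in a periodic box; frames (including the initial state) are
#' recorded every `frame_every` steps. The LP-9 scenario delegates to
#' [relax_stress()] (pinned shape defect, relaxation-only stress dynamics).
#'
#' @param config a [run_config()].
#' @param params a [model_params()]; defaults to the scenario's set.
#' @param backstress also transmit the elastic (Ericksen plus antisymmetric
#'   director-torque) stress of both tensors to the fluid. The default keeps
#'   the passive stress purely viscous, the minimal closure of the momentum
#'   balance; the back-reaction is available for sensitivity studies.
#' @return an `an_trajectory`: arrays `Qnxx, Qnxy, Qmxx, Qmxy` (and `ux, uy`)
#'   of dimension `nx x ny x nframes`, per-frame `steps`, total `mass` and
#'   `max_speed` diagnostics, plus `config` and `params`.
#' @export
simulate_monolayer <- function(config = run_config(), params = NULL,
                               backstress = FALSE) {
  if (config$scenario == "lp9") {
    cfg <- lp9_config(box = config$grid[1], seed = config$seed)
    return(relax_stress(cfg, params %||% model_params("lp9")))
  }
  params <- params %||% model_params("mdck")
  nx <- config$grid[1]; ny <- config$grid[2]
  set.seed(config$seed)
  psi_n <- matrix(runif(nx * ny, 0, pi), nx, ny)
  psi_m <- matrix(runif(nx * ny, 0, pi), nx, ny)
  Qn <- q_from_director(config$S0, psi_n)
  Qm <- q_from_director(config$S0, psi_m)
  raw <- .run_hybrid_cpp(Qn$xx, Qn$xy, Qm$xx, Qm$xy,
                         params$C, params$K_n, params$K_m, params$J,
                         params$gamma, params$zeta, params$rho, lb_tau(params),
                         config$steps, config$frame_every, config$store_flow,
                         1.0, isTRUE(backstress), coupling_code(params))
  structure(c(raw, list(config = config, params = params)),
            class = "an_trajectory")
}

#' @export
print.an_trajectory <- function(x, ...) {
  nf <- length(x$steps)
  cat(sprintf("<an_trajectory %d x %d, %d frames (every %d steps), seed %d>\n",
              dim(x$Qnxx)[1], dim(x$Qnxx)[2], nf, x$config$frame_every,
              x$config$seed))
  invisible(x)
}

n_frames <- function(traj) length(traj$steps)

#' Extract one frame of a trajectory as a tissue state
#'
#' @param traj an `an_trajectory`.
#' @param k frame index (1-based).
#' @return list with `Qn`, `Qm` ([qtensor_field()]s), `ux`, `uy` (or `NULL`),
#'   and the LB `step` of the frame.
#' @export
get_frame <- function(traj, k) {
  stopifnot(k >= 1, k <= n_frames(traj))
  list(Qn = qtensor_field(traj$Qnxx[, , k], traj$Qnxy[, , k]),
       Qm = qtensor_field(traj$Qmxx[, , k], traj$Qmxy[, , k]),
       ux = if (!is.null(traj$ux)) traj$ux[, , k],
       uy = if (!is.null(traj$uy)) traj$uy[, , k],
       step = traj$steps[k])
}

#' Detect the onset of the statistical steady state
#'
#' Measurements are taken once the mean defect count and the
#' extensile area fraction stop trending. This returns the earliest frame
#' from which neither series has a significant monotone trend over the
#' remaining frames (two-sided Mann-Kendall test at `alpha`), requiring at
#' least `window` remaining frames. If no such frame exists the result is
#' flagged and falls back to the final `measure` frames.
#'
#' @param series a data frame with columns `defect_count` and `ext_frac`
#'   (one row per frame), or an `an_trajectory` (analysed first).
#' @param window minimum tail length for the trend test.
#' @param alpha significance level of the trend test.
#' @param measure fallback measurement window (frames).
#' @return list with `index` (first steady frame, 1-based), `flagged`
#'   (logical: no steady window found) and the `series` used.
#' @export
detect_steady_state <- function(series, window = 50, alpha = 0.05,
                                measure = 150) {
  if (inherits(series, "an_trajectory"))
    series <- analyze_trajectory(series)$series
  n <- nrow(series)
  trendless <- function(y) {
    if (length(y) < 3 || sd(y) == 0) return(TRUE)
    p <- suppressWarnings(
      cor.test(seq_along(y), y, method = "kendall", exact = FALSE)$p.value)
    is.na(p) || p > alpha
  }
  for (s in seq_len(max(1, n - window + 1))) {
    idx <- s:n
    if (trendless(series$defect_count[idx]) && trendless(series$ext_frac[idx]))
      return(list(index = s, flagged = FALSE, series = series))
  }
  list(index = max(1, n - measure + 1), flagged = TRUE, series = series)
}
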