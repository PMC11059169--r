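test_that("active stress is -zeta Q^m with the contractile sign convention", {
  Qm <- qtensor_field(matrix(0.5, 3, 3), matrix(-0.2, 3, 3))
  expect_equal(active_stress(Qm, 0)$xx, matrix(0, 3, 3))
  pi_act <- active_stress(Qm, -0.03)
  # contractile zeta < 0: positive principal stress along m (pulls inward)
  expect_equal(pi_act$xx, matrix(0.015, 3, 3))
  expect_equal(pi_act$xy, matrix(-0.006, 3, 3))
  z <- qtensor_field(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(active_stress(z, -0.03)$xx, matrix(0, 3, 3))
})

test_that("vorticity convention: rigid rotation gives Omega_xy = w,
           shear gives |Omega_xy| = rate/2", {
  n <- 32
  x <- matrix(seq_len(n), n, n); y <- t(x)
  w <- 1e-3
  ux <- -w * (y - n / 2); uy <- w * (x - n / 2)
  om <- vorticity(ux, uy)
  inner <- 3:(n - 2)
  expect_equal(om[inner, inner], matrix(w, length(inner), length(inner)),
               tolerance = 1e-12)
  expect_equal(vorticity(matrix(0.3, n, n), matrix(-0.1, n, n)),
               matrix(0, n, n))
  g <- 2e-3
  om_sh <- vorticity(g * y, matrix(0, n, n))
  expect_equal(abs(om_sh[inner, inner]),
               matrix(g / 2, length(inner), length(inner)), tolerance = 1e-12)
})

test_that("co-rotation rotates both directors together: misalignment is
           invariant under uniform vorticity", {
  # free energy switched off; rigid rotation about the box centre.
  p <- model_params("mdck", C = 1e-300, K_n = 1e-300, K_m = 1e-300,
                    J = 1e-300)
  n <- 33
  x <- matrix(seq_len(n), n, n); y <- t(x)
  w <- 1e-3
  c0 <- (n + 1) / 2
  ux <- -w * (y - c0); uy <- w * (x - c0)
  psi_n0 <- 0.3; psi_m0 <- 1.1
  Qn <- q_from_director(1, matrix(psi_n0, n, n))
  Qm <- q_from_director(1, matrix(psi_m0, n, n))
  st <- update_q(Qn, Qm, ux, uy, p, steps = 1000)
  ctr <- cbind(ceiling(n / 2), ceiling(n / 2))
  an <- director_from_q(st$Qn)$angle[ctr]
  am <- director_from_q(st$Qm)$angle[ctr]
  theta0 <- abs(psi_n0 - psi_m0)
  theta1 <- abs(an - am) %% pi
  expect_equal(min(theta1, pi - theta1), min(theta0, pi - theta0),
               tolerance = 1e-6)
  # and the rotation rate is the angular velocity w (Euler-scheme accuracy)
  expect_equal((an - psi_n0) %% pi, (w * 1000) %% pi, tolerance = 5e-3)
})

test_that("CFL guard triggers on over-fast advection", {
  p <- model_params("mdck")
  Q <- q_from_director(1, matrix(0.1, 8, 8))
  expect_error(update_q(Q, Q, matrix(0.8, 8, 8), 0, p), "CFL")
})

test_that("LB equilibrium at rest is an exact fixed point and tau follows
           from the viscosity", {
  expect_equal(lb_tau(model_params("mdck")), 1) # nu = eta/rho = 1/6
  fl <- lb_equilibrium(40, dim = c(8, 8), tau = 1)
  fl2 <- lb_step(fl, steps = 5)
  expect_equal(fl2$f, fl$f, tolerance = 1e-14)
  expect_equal(fl2$rho, matrix(40, 8, 8), tolerance = 1e-13)
  expect_equal(max(abs(fl2$ux)), 0, tolerance = 1e-15)
  expect_error(lb_step(fl, Fx = matrix(NaN, 8, 8)), "finite")
})

test_that("decaying shear wave recovers the kinematic viscosity within 2%", {
  p <- model_params("mdck")
  n <- 64
  k <- 2 * pi / n
  u0 <- 1e-4
  y <- matrix(rep(seq_len(n) - 1, each = n), n, n)
  fl <- lb_equilibrium(matrix(p$rho, n, n), ux = u0 * sin(k * y),
                       tau = lb_tau(p))
  steps <- 2000
  fl <- lb_step(fl, steps = steps)
  amp <- 2 * mean(fl$ux * sin(k * y)) # Fourier amplitude of the mode
  nu_meas <- -log(amp / u0) / (k^2 * steps)
  expect_equal(nu_meas, p$eta / p$rho, tolerance = 0.02)
})

test_that("forced LB conserves mass and unforced LB conserves momentum", {
  set.seed(4)
  n <- 16
  fl <- lb_equilibrium(matrix(40, n, n),
                       ux = matrix(rnorm(n * n, 0, 1e-3), n, n),
                       uy = matrix(rnorm(n * n, 0, 1e-3), n, n), tau = 1)
  mass0 <- sum(fl$rho)
  mom0 <- c(sum(fl$rho * fl$ux), sum(fl$rho * fl$uy))
  Fx <- matrix(rnorm(n * n, 0, 1e-5), n, n)
  fl_f <- lb_step(fl, Fx = Fx, Fy = -Fx, steps = 200)
  expect_equal(sum(fl_f$rho) / mass0, 1, tolerance = 1e-10)
  fl_0 <- lb_step(fl, steps = 200)
  mom1 <- c(sum(fl_0$rho * fl_0$ux), sum(fl_0$rho * fl_0$uy))
  expect_lt(max(abs(mom1 - mom0)), 1e-8 * 200)
})

test_that("hybrid runs are deterministic given the seed and conserve mass", {
  cfg <- run_config(grid = 32, steps = 600, frame_every = 300, seed = 9)
  tr1 <- simulate_monolayer(cfg)
  tr2 <- simulate_monolayer(cfg)
  expect_identical(tr1$Qnxx, tr2$Qnxx)
  expect_identical(tr1$ux, tr2$ux)
  expect_lt(diff(range(tr1$mass)) / tr1$mass[1], 1e-8)
  # low grid-Reynolds number at the MDCK parameters: advective inertia is
  # subdominant at the lattice scale
  p <- model_params("mdck")
  Re <- max(tr1$max_speed) * 1 * p$rho / p$eta
  expect_lt(Re, 0.5)
})

test_that("steady-state detector: constant, ramp-then-plateau and monotone
           series behave as specified", {
  n <- 300
  const <- data.frame(defect_count = rep(10, n), ext_frac = rep(0.3, n))
  expect_equal(detect_steady_state(const, window = 50)$index, 1)
  set.seed(2)
  ramp <- c(seq(40, 10, length.out = 100), rep(10, n - 100)) +
    rnorm(n, 0, 0.5)
  plateau <- data.frame(defect_count = ramp,
                        ext_frac = 0.3 + rnorm(n, 0, 0.01))
  idx <- detect_steady_state(plateau, window = 50)$index
  expect_gt(idx, 40)
  expect_lt(idx, 160)
  mono <- data.frame(defect_count = seq(100, 10, length.out = n) +
                       rnorm(n, 0, 0.5),
                     ext_frac = seq(0.5, 0.2, length.out = n))
  res <- detect_steady_state(mono, window = 50, measure = 150)
  expect_true(res$flagged)
  expect_equal(res$index, n - 150 + 1)
})
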