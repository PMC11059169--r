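test_that("Q-tensor construction from director follows S(dd - I/2)", {
  one <- matrix(1, 1, 1)
  q0 <- q_from_director(1, 0 * one)
  expect_equal(q0$xx[1], 0.5)
  expect_equal(q0$xy[1], 0)
  q90 <- q_from_director(1, (pi / 2) * one)
  expect_equal(q90$xx[1], -0.5) # nematic symmetry: rotation by 90 deg flips Qxx
  expect_equal(q90$xy[1], 0)
  q45 <- q_from_director(1, (pi / 4) * one)
  expect_equal(q45$xx[1], 0, tolerance = 1e-15)
  expect_equal(q45$xy[1], 0.5)
  expect_error(q_from_director(-0.1, 0 * one), "non-negative")
})

test_that("director extraction inverts construction and flags isotropy", {
  d <- director_from_q(qtensor_field(matrix(0.5), matrix(0)))
  expect_equal(d$S[1], 1)
  expect_equal(d$angle[1], 0)
  d0 <- director_from_q(qtensor_field(matrix(0), matrix(0)))
  expect_equal(d0$S[1], 0)
  expect_true(d0$isotropic[1])
  expect_equal(d0$angle[1], 0)
  # round trip over random fields
  set.seed(7)
  S <- matrix(runif(64, 0, 1.5), 8, 8)
  psi <- matrix(runif(64, 0, pi), 8, 8)
  Q <- q_from_director(S, psi)
  d <- director_from_q(Q)
  expect_equal(d$S, S, tolerance = 1e-12)
  Q2 <- q_from_director(d$S, d$angle)
  expect_equal(Q2$xx, Q$xx, tolerance = 1e-12)
  expect_equal(Q2$xy, Q$xy, tolerance = 1e-12)
})

test_that("bulk energy density matches closed-form special cases", {
  p <- model_params("mdck")
  z <- qtensor_field(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_equal(bulk_energy_density(z, z, p),
               matrix(p$C + p$J / 2, 4, 4))
  # aligned ordered state S = sqrt(2/3): every squared factor vanishes
  Qa <- q_from_director(sqrt(2 / 3), matrix(0.3, 4, 4))
  expect_equal(bulk_energy_density(Qa, Qa, p), matrix(0, 4, 4),
               tolerance = 1e-14)
  # perpendicular directors at S = sqrt(2/3): Qn:Qm = -1/3, J term = 2J
  Qb <- q_from_director(sqrt(2 / 3), matrix(0.3 + pi / 2, 4, 4))
  expect_equal(bulk_energy_density(Qa, Qb, p), matrix(2 * p$J, 4, 4),
               tolerance = 1e-14)
})

test_that("elastic energy: uniform fields cost nothing, K scales linearly,
           plane waves match the discrete closed form", {
  p <- model_params("mdck")
  u <- q_from_director(0.8, matrix(1.1, 6, 6))
  expect_equal(elastic_energy_density(u, u, p), matrix(0, 6, 6),
               tolerance = 1e-14)
  W <- 16; eps <- 0.01
  x <- matrix(seq_len(W) - 1, W, W)
  Q <- qtensor_field(eps * cos(2 * pi * x / W), matrix(0, W, W))
  z <- qtensor_field(matrix(0, W, W), matrix(0, W, W))
  e1 <- elastic_energy_density(Q, z, p)
  # forward-difference plane wave: mean (K/2)|grad Q|^2 = 2 K eps^2 sin^2(pi/W)
  expect_equal(mean(e1), 2 * p$K_n * eps^2 * sin(pi / W)^2,
               tolerance = 1e-12)
  p2 <- model_params("mdck", K_n = 2 * p$K_n)
  expect_equal(elastic_energy_density(Q, z, p2), 2 * e1, tolerance = 1e-14)
})

test_that("molecular field: stationary at the aligned minimum and equal to
           the closed form for a uniform overshoot", {
  p <- model_params("mdck")
  Qa <- q_from_director(sqrt(2 / 3), matrix(0.4, 8, 8))
  H <- molecular_field("both", Qa, Qa, p)
  expect_lt(max(abs(H$Hn$xx), abs(H$Hn$xy), abs(H$Hm$xx), abs(H$Hm$xy)),
            1e-10)
  # uniform S = 1 with Qm = 0: H^n = 6C(1 - 3/2) Q^n = -3C Q^n
  Q1 <- q_from_director(1, matrix(0.7, 8, 8))
  z <- qtensor_field(matrix(0, 8, 8), matrix(0, 8, 8))
  Hn <- molecular_field("n", Q1, z, p)
  expect_equal(Hn$xx, -3 * p$C * Q1$xx, tolerance = 1e-12)
  expect_equal(Hn$xy, -3 * p$C * Q1$xy, tolerance = 1e-12)
})

test_that("molecular field equals the numerical functional derivative of the
           free energy on random states", {
  p <- model_params("mdck")
  st <- random_state(8, 42)
  H <- molecular_field("both", st$Qn, st$Qm, p)
  for (which in c("n", "m")) {
    Hnum <- numerical_molecular_field(st$Qn, st$Qm, p, which)
    Ha <- if (which == "n") H$Hn else H$Hm
    scale <- max(abs(Ha$xx), abs(Ha$xy))
    expect_lt(max(abs(Hnum$xx - Ha$xx), abs(Hnum$xy - Ha$xy)) / scale, 1e-5)
  }
})

test_that("exterior quartic energy penalizes order and its molecular field
           melts it under relaxation", {
  p <- model_params("lp9")
  n <- 12
  z <- qtensor_field(matrix(0, n, n), matrix(0, n, n))
  expect_equal(exterior_bulk_energy_density(z, z, p$C_prime),
               matrix(0, n, n))
  Q1 <- q_from_director(1, matrix(0.2, n, n))
  expect_equal(exterior_bulk_energy_density(Q1, Q1, p$C_prime),
               matrix(p$C_prime / 4, n, n), tolerance = 1e-14)
  expect_error(exterior_bulk_energy_density(Q1, Q1, NA), "C_prime")
  # all-exterior patch: gradient descent drives S -> 0
  # (the quartic exterior potential gives algebraic, not exponential, decay)
  st <- random_state(n, 5)
  interior <- matrix(FALSE, n, n)
  cur <- st
  s_trace <- mean(director_from_q(st$Qm)$S)
  for (i in 1:40) {
    cur <- update_q(cur$Qn, cur$Qm, 0, 0, p, steps = 50, interior = interior)
    s_trace <- c(s_trace, mean(director_from_q(cur$Qm)$S))
  }
  expect_true(all(diff(s_trace) < 0))
  expect_lt(tail(s_trace, 1), 0.1)
  # exterior H matches its numerical derivative too
  H <- molecular_field("m", st$Qn, st$Qm, p, interior = interior)
  Hnum <- numerical_molecular_field(st$Qn, st$Qm, p, "m", interior = interior)
  expect_lt(max(abs(Hnum$xx - H$xx), abs(Hnum$xy - H$xy)) /
              max(abs(H$xx), abs(H$xy)), 1e-5)
})

test_that("free energy descends monotonically under pure relaxation", {
  p <- model_params("mdck")
  st <- random_state(16, 3)
  energies <- numeric(21)
  energies[1] <- total_free_energy(st$Qn, st$Qm, p)
  cur <- st
  for (i in 1:20) {
    cur <- update_q(cur$Qn, cur$Qm, 0, 0, p, steps = 50)
    energies[i + 1] <- total_free_energy(cur$Qn, cur$Qm, p)
  }
  expect_true(all(diff(energies) < 1e-12))
  # uniform fields: total energy equals the bulk-only value
  Qu <- q_from_director(0.9, matrix(0.5, 8, 8))
  expect_equal(total_free_energy(Qu, Qu, p),
               sum(bulk_energy_density(Qu, Qu, p)), tolerance = 1e-14)
  z8 <- qtensor_field(matrix(0, 8, 8), matrix(0, 8, 8))
  pj <- model_params("mdck", J = 1e-300)
  expect_equal(total_free_energy(z8, z8, pj), pj$C * 64, tolerance = 1e-10)
})

test_that("the homogeneous aligned state is a stable fixed point", {
  p <- model_params("mdck")
  n <- 16
  Qa <- q_from_director(sqrt(2 / 3), matrix(0.9, n, n))
  set.seed(1)
  pert <- function(Q) qtensor_field(Q$xx + matrix(rnorm(n * n, 0, 1e-3), n, n),
                                    Q$xy + matrix(rnorm(n * n, 0, 1e-3), n, n))
  Qn <- pert(Qa); Qm <- pert(Qa)
  dev <- function(Qn, Qm) sqrt(sum((Qn$xx - Qa$xx)^2 + (Qn$xy - Qa$xy)^2 +
                                     (Qm$xx - Qa$xx)^2 + (Qm$xy - Qa$xy)^2))
  norms <- numeric(11)
  norms[1] <- dev(Qn, Qm)
  for (i in 1:10) {
    st <- update_q(Qn, Qm, 0, 0, p, steps = 200)
    Qn <- st$Qn; Qm <- st$Qm
    norms[i + 1] <- dev(Qn, Qm)
  }
  expect_true(all(diff(norms) < 0))
})
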