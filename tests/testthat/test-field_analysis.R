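test_that("cells map to the dl = L/sqrt(N) lattice with deterministic
           collision resolution", {
  # 4 cells at the corners of a 2x2 arrangement: one site each
  cells <- cell_table(x = c(2.5, 7.5, 2.5, 7.5), y = c(2.5, 2.5, 7.5, 7.5),
                      angle_deg = c(10, 20, 30, 40))
  g <- cells_to_grid(cells, L = 10)
  expect_equal(dim(g$angle), c(2, 2))
  expect_equal(g$dl, 5)
  expect_equal(rad2deg(g$angle), matrix(c(10, 20, 30, 40), 2, 2))
  # N = 100 uniform cells in L = 10 -> 10 x 10 grid with dl = 1
  set.seed(1)
  c100 <- cell_table(runif(100, 0, 10), runif(100, 0, 10),
                     runif(100, 0, 180))
  g100 <- cells_to_grid(c100, L = 10)
  expect_equal(dim(g100$angle), c(10, 10))
  expect_equal(g100$dl, 1)
  # two cells nearest to one site: the closer wins; exact tie -> lower index
  duo <- cell_table(x = c(6, 5.4, 1, 9, 1, 9, 1, 9, 5),
                    y = c(5, 5, 1, 1, 9, 9, 5, 5, 1),
                    angle_deg = c(45, 90, rep(0, 7)))
  gd <- cells_to_grid(duo, L = 10) # 3x3, dl = 10/3; site centre (5, 5)
  expect_equal(rad2deg(gd$angle[2, 2]), 90) # cell 2 is closer
  tie <- cell_table(x = c(4, 6, 1, 9, 1, 9, 1, 9, 5),
                    y = c(5, 5, 1, 1, 9, 9, 5.1, 5.1, 9),
                    angle_deg = c(45, 90, rep(0, 7)))
  gt <- cells_to_grid(tie, L = 10)
  expect_equal(rad2deg(gt$angle[2, 2]), 45) # equidistant: input order wins
})

test_that("grid refinement interpolates nematically, not on raw angles", {
  u <- director_grid(matrix(0.7, 5, 5))
  r <- refine_grid(u, 3)
  expect_equal(r$angle, matrix(0.7, nrow(r$angle), ncol(r$angle)),
               tolerance = 1e-12)
  expect_identical(refine_grid(u, 1), u)
  # midpoint of 10 and 170 degrees is 0 degrees (nematic average), never 90
  two <- director_grid(matrix(deg2rad(c(10, 170)), 2, 1), periodic = FALSE)
  r2 <- refine_grid(two, 2)
  expect_equal(rad2deg(r2$angle[2, 1]), 0, tolerance = 1e-10)
})

test_that("winding-number defect finder: imprinted charges, empty fields,
           and charge neutrality on periodic random fields", {
  # +1/2 imprint psi = phi/2 (the pinned-defect construction)
  n <- 41; ctr <- c(21, 21)
  x <- matrix(seq_len(n), n, n); y <- t(x)
  psi <- atan2(y - ctr[2] - 0.25, x - ctr[1] - 0.25) / 2
  d <- find_defects(psi, periodic = FALSE)
  expect_equal(nrow(d), 1)
  expect_equal(d$charge, 0.5)
  expect_lt(max(abs(c(d$x, d$y) - ctr)), 1.01)
  # -1/2 imprint
  dm <- find_defects(-psi, periodic = FALSE)
  expect_equal(dm$charge, -0.5)
  # uniform field: no defects
  expect_equal(nrow(find_defects(matrix(1, 20, 20), periodic = TRUE)), 0)
  # topological constraint: net charge zero on periodic smooth fields
  for (seed in 1:5) {
    f <- smooth_nematic_field(64, 6, seed = seed)
    ds <- find_defects(f, periodic = TRUE)
    expect_equal(attr(ds, "total_charge"), 0)
    expect_true(all(abs(ds$charge) == 0.5))
  }
})

test_that("principal stress axis matches an eigen-decomposition oracle and
           is rotation-equivariant", {
  r <- principal_stress_axis(2, 0, 1)
  expect_equal(r$angle, 0)
  expect_equal(r$magnitude, 0.5)
  r2 <- principal_stress_axis(0, 1, 0)
  expect_equal(rad2deg(r2$angle), 45)
  expect_equal(r2$magnitude, 1)
  set.seed(8)
  for (i in 1:20) {
    s <- matrix(rnorm(3), 1)
    r <- principal_stress_axis(s[1], s[2], s[3])
    # oracle: eigen-decomposition of the traceless tensor
    cc <- -(s[1] + s[3]) / 2
    ev <- eigen(matrix(c(s[1] + cc, s[2], s[2], s[3] + cc), 2, 2))
    expect_equal(r$magnitude, max(ev$values), tolerance = 1e-12)
    vec <- ev$vectors[, which.max(ev$values)]
    ang_oracle <- atan2(vec[2], vec[1]) %% pi
    expect_equal(r$angle, ang_oracle, tolerance = 1e-10)
    # equivariance: rotating the tensor rotates the axis, magnitude fixed
    al <- runif(1, 0, pi)
    R <- matrix(c(cos(al), sin(al), -sin(al), cos(al)), 2, 2)
    S2 <- R %*% matrix(c(s[1], s[2], s[2], s[3]), 2, 2) %*% t(R)
    rr <- principal_stress_axis(S2[1, 1], S2[1, 2], S2[2, 2])
    expect_equal(rr$magnitude, r$magnitude, tolerance = 1e-12)
    expect_equal(sin(rr$angle - r$angle - al), 0, tolerance = 1e-10)
  }
  # inverse round trip: rebuild sigma from angle + magnitude + trace
  ang <- 0.9; mag <- 1.7; iso <- -3
  sxx <- mag * cos(2 * ang) + iso; sxy <- mag * sin(2 * ang)
  syy <- -mag * cos(2 * ang) + iso
  rb <- principal_stress_axis(sxx, sxy, syy)
  expect_equal(rb$angle, ang, tolerance = 1e-12)
  expect_equal(rb$magnitude, mag, tolerance = 1e-12)
  # isotropic tensor: flagged, angle undefined
  ri <- principal_stress_axis(5, 0, 5)
  expect_true(ri$isotropic)
  expect_true(is.na(ri$angle))
})

test_that("misalignment angle: perpendicular, nematic wrap and the
           random-director null", {
  g <- function(deg) director_grid(matrix(deg2rad(deg), 2, 2))
  expect_equal(misalignment(g(0), g(90))$theta, matrix(90, 2, 2))
  expect_equal(misalignment(g(10), g(170))$theta, matrix(20, 2, 2),
               tolerance = 1e-12)
  set.seed(12)
  n <- 200
  a <- director_grid(matrix(runif(n * n, 0, pi), n, n))
  b <- director_grid(matrix(runif(n * n, 0, pi), n, n))
  mm <- misalignment(a, b)
  expect_lt(abs(mean(mm$theta) - 45), 0.5)
  expect_lt(abs(mean(mm$extensile) - 0.5), 0.02)
  # theta = 45 exactly is contractile (strict inequality for extensile)
  m45 <- misalignment(g(0), g(45))
  expect_false(any(m45$extensile))
})

test_that("interface domains form a band along class boundaries and the
           three fractions partition the tissue", {
  n <- 40
  half <- matrix(rep(c(TRUE, FALSE), each = n * n / 2), n, n) # split along y
  r1 <- interface_domains(half, r_max = 1, periodic = FALSE)
  expect_equal(sum(r1$interface), 2 * n) # two one-site bands
  expect_equal(sum(r1$fractions), 1)
  expect_equal(r1$fractions[["interface"]], 2 / n)
  runi <- interface_domains(matrix(TRUE, n, n), r_max = 1, periodic = FALSE)
  expect_equal(runi$fractions[["interface"]], 0)
  # periodic wrap doubles the boundary count
  r2 <- interface_domains(half, r_max = 1, periodic = TRUE)
  expect_equal(sum(r2$interface), 4 * n)
})

test_that("defect-interface colocalization handles full, empty and
           undefined cases", {
  mask <- matrix(FALSE, 10, 10); mask[4:6, ] <- TRUE
  d <- data.frame(x = c(4.5, 5.5), y = c(2.5, 7.5),
                  charge = c(0.5, -0.5), orientation = 0)
  expect_equal(defect_interface_colocalization(d, mask), 1)
  expect_equal(defect_interface_colocalization(d, mask & FALSE), 0)
  none <- d[0, ]
  expect_true(is.na(defect_interface_colocalization(none, mask)))
})

test_that("orientation correlation: constant fields, independent-angle null
           and generator round trip", {
  const <- matrix(0.8, 32, 32)
  cc <- orientation_correlation(const)
  expect_true(all(abs(cc$C - 1) < 1e-12))
  set.seed(3)
  iid <- matrix(runif(64 * 64, 0, pi), 64, 64)
  ci <- orientation_correlation(iid)
  far <- ci$r > 0
  expect_lt(max(abs(ci$C[far])), 3 / sqrt(min(ci$npairs[far])))
  # round trip: field built with correlation length ell recovers it
  f <- smooth_nematic_field(128, 16, seed = 5)
  cr <- orientation_correlation(f)
  ell <- correlation_length(cr)
  expect_equal(ell, 16, tolerance = 0.2)
})

test_that("orientation correlation is invariant under the nematic symmetry
           psi -> psi + pi on arbitrary subsets", {
  set.seed(6)
  f <- smooth_nematic_field(48, 8, seed = 6)
  flip <- matrix(runif(48 * 48) < 0.5, 48, 48)
  f2 <- f + flip * pi
  c1 <- orientation_correlation(f)
  c2 <- orientation_correlation(f2)
  expect_equal(c1$C, c2$C, tolerance = 1e-10)
  d1 <- find_defects(f, periodic = TRUE)
  d2 <- find_defects(wrap_pi(f2), periodic = TRUE)
  expect_equal(d1$charge, d2$charge)
  expect_equal(d1$x, d2$x, tolerance = 1e-9)
})

test_that("temporal orientation correlation decays with frame shuffling
           symmetry", {
  set.seed(9)
  base <- smooth_nematic_field(32, 6, seed = 9)
  frames <- list(base, wrap_pi(base + 0.1), wrap_pi(base + 0.2))
  ct <- orientation_correlation(frames, mode = "temporal", frame_interval = 15)
  expect_equal(ct$C[1], 1)
  expect_equal(ct$t, c(0, 15, 30))
  expect_equal(ct$C[2], cos(0.2), tolerance = 1e-10)
  expect_equal(ct$C[3], cos(0.4), tolerance = 1e-10)
})

test_that("velocity correlation: uniform flow, white noise and the
           zero-flow flag", {
  u1 <- matrix(0.3, 32, 32)
  cv <- velocity_correlation(u1, u1)
  expect_true(all(abs(cv$C - 1) < 1e-12))
  set.seed(10)
  wn <- function() matrix(rnorm(64 * 64), 64, 64)
  cw <- velocity_correlation(wn(), wn())
  expect_lt(max(abs(cw$C[cw$r > 0])), 0.1)
  z <- matrix(0, 8, 8)
  cz <- velocity_correlation(z, z)
  expect_true(is.na(cz$C[1]))
  expect_match(attr(cz, "flagged"), "zero velocity")
})

test_that("stress-vs-misalignment binning: flat null, monotone recovery and
           scale invariance", {
  set.seed(11)
  th <- runif(5000, 0, 90)
  flat <- stress_vs_misalignment(rep(1, 5000) + rnorm(5000, 0, 0.01), th)
  expect_lt(diff(range(flat$mean)), 0.05)
  dec <- stress_vs_misalignment(cos(deg2rad(th)) + 0.01, th)
  expect_true(all(diff(dec$mean) < 0))
  s1 <- stress_vs_misalignment(list(cos(deg2rad(th))), list(th))
  s2 <- stress_vs_misalignment(list(1000 * cos(deg2rad(th))), list(th))
  expect_equal(s1$mean, s2$mean, tolerance = 1e-12)
})

test_that("misalignment histogram: point mass, uniform density and the
           extensile fraction", {
  h0 <- misalignment_histogram(rep(0, 100))
  expect_equal(attr(h0, "extensile_fraction"), 0)
  expect_equal(sum(h0$count > 0), 1)
  set.seed(13)
  hu <- misalignment_histogram(runif(20000, 0, 90))
  expect_equal(attr(hu, "extensile_fraction"), 0.5, tolerance = 0.02)
  expect_lt(diff(range(hu$density)) / mean(hu$density), 0.25)
})
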