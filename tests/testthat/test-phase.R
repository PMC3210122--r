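test_that("direct PRC on a planar normal-form oscillator matches theory", {
  # integrate the Stuart-Landau fixture with deSolve, apply impulses in
  # the real direction, and compare the measured sensitivity with the
  # fixture's closed-form Z (independent of the package's DDE machinery)
  fx <- make_fixture("stuart_landau_ode",
                     list(mu = 0.5, omega = 2 * pi, c_re = -1, c_im = 0.4))
  R <- fx$R_inf; Om <- fx$Omega
  rhs <- function(t, y, parms) {
    z <- y[1] + 1i * y[2]
    dz <- (fx$params$mu + 1i * fx$params$omega) * z +
      (fx$params$c_re + 1i * fx$params$c_im) * z * Mod(z)^2
    list(c(Re(dz), Im(dz)))
  }
  measure <- function(theta, imp) {
    z0 <- R * exp(1i * theta)
    y0 <- c(Re(z0) + imp, Im(z0))
    out <- deSolve::ode(y0, seq(0, 20, by = 0.002), rhs, NULL,
                        method = "rk4")
    zT <- out[nrow(out), 2] + 1i * out[nrow(out), 3]
    ref <- theta + Om * 20
    delta <- Arg(zT * exp(-1i * ref))
    delta / imp
  }
  thetas <- seq(0, 2 * pi, length.out = 9L)[1:8]
  Zmeas <- vapply(thetas, measure, 0, imp = 1e-4)
  Zref <- fx$Z(thetas, direction = 1)
  expect_equal(Zmeas, Zref, tolerance = 0.02 * max(abs(Zref)))
})

test_that("the DDE PRC is in the linear-response regime", {
  cyc <- cycle_A()
  p <- param_A()
  base <- prc_A()
  half <- prc_direct(p, cyc, impulse = base$impulse / 2, n_phase = 8L,
                     relax_periods = 40L)
  keep <- seq(1, 64, by = 8)
  expect_lt(max(abs(half$Z - base$Z[keep])) / max(abs(base$Z)), 0.02)
})

test_that("the PRC is insensitive to the relaxation window", {
  cyc <- cycle_A()
  longer <- prc_direct(param_A(), cyc, n_phase = 8L, relax_periods = 80L)
  keep <- seq(1, 64, by = 8)
  expect_lt(max(abs(longer$Z - prc_A()$Z[keep])) / max(abs(prc_A()$Z)),
            0.01)
})

test_that("convolution coupling functions satisfy their structural identities", {
  G <- gamma_A_u()
  # diffusive signal at zero lag: Gamma(0) = 0, gamma_a(0) = 0 exactly
  expect_identical(G$gamma[1], 0)
  expect_identical(G$gamma_a[1], 0)
  # gamma_a odd on the grid by construction
  n <- length(G$phi)
  expect_equal(G$gamma_a, -G$gamma_a[c(1L, n:2L)], tolerance = 1e-12)
  # trapezoid result vs refined quadrature on an upsampled spline
  Zf <- stats::splinefun(c(prc_A()$theta, 2 * pi),
                         c(prc_A()$Z, prc_A()$Z[1]), method = "periodic")
  uf <- stats::splinefun(c(cycle_A()$samples$theta, 2 * pi),
                         c(cycle_A()$samples$u, cycle_A()$samples$u[1]),
                         method = "periodic")
  g2 <- param_A()$damping^2
  th_fine <- seq(0, 2 * pi, length.out = 8192L + 1L)[1:8192]
  for (k in c(5L, 20L, 40L)) {
    phi <- G$phi[k]
    ref <- g2 * mean(Zf(th_fine) * (uf((th_fine + phi) %% (2 * pi)) -
                                      uf(th_fine)))
    expect_equal(G$gamma[k], ref, tolerance = 1e-4 * max(abs(G$gamma)))
  }
})

test_that("the convolution demands the forcing-direction sensitivity", {
  pu <- prc_direct(param_A(), cycle_A(), n_phase = 8L,
                   relax_periods = 30L, component = "u")
  expect_error(gamma_convolution(pu, cycle_A(), "u"), "impulse")
})

test_that("locking analysis solves the textbook case", {
  ga <- function(phi) -sin(phi)
  ld <- locking_analysis(ga, 0, 0.5)
  expect_identical(nrow(ld$fixed_points), 2L)
  stable <- ld$fixed_points[ld$fixed_points$stable, ]
  expect_equal(stable$phi, 0, tolerance = 1e-9)
  unst <- ld$fixed_points[!ld$fixed_points$stable, ]
  expect_equal(unst$phi, pi, tolerance = 1e-9)
  # detuned: stable point at asin(delta/eps)
  ld2 <- locking_analysis(ga, 0.25, 0.5)
  st2 <- ld2$fixed_points$phi[ld2$fixed_points$stable]
  expect_equal(st2, asin(0.5), tolerance = 1e-9)
  # drift regime
  ld3 <- locking_analysis(ga, 0.6, 0.5)
  expect_true(ld3$drifting)
})

test_that("stable and unstable points alternate and bound the basins", {
  ld <- locking_analysis(gamma_C_v(), 0, 0.02)
  fp <- ld$fixed_points
  expect_identical(sum(fp$stable), 5L)
  expect_true(all(abs(diff(fp$stable)) == 1))  # alternation
  # 1-D flow oracle: forward-integrate the phase ODE from 100 starts
  gaf <- stats::splinefun(c(gamma_C_v()$phi, 2 * pi),
                          c(gamma_C_v()$gamma_a, gamma_C_v()$gamma_a[1]),
                          method = "periodic")
  flow_to <- function(phi0) {
    x <- phi0
    for (i in 1:40000) x <- x + 0.02 * 0.02 * gaf(x %% (2 * pi))
    x %% (2 * pi)
  }
  stable_phi <- fp$phi[fp$stable]
  starts <- seq(0.001, 2 * pi - 0.001, length.out = 100L)
  pred <- ld$basin_of(starts)
  for (i in seq(1, 100, by = 7)) {
    final <- flow_to(starts[i])
    d <- abs(final - stable_phi); d <- pmin(d, 2 * pi - d)
    expect_identical(which.min(d), pred[i])
  }
})

test_that("critical coupling is linear in the mismatch and handles edges", {
  G <- gamma_A_u()
  expect_identical(critical_coupling(G, 0), 0)
  e1 <- critical_coupling(G, 0.05)
  e2 <- critical_coupling(G, 0.10)
  expect_equal(e2 / e1, 2, tolerance = 1e-9)
  expect_equal(critical_coupling(G, -0.05), e1, tolerance = 1e-9)
  expect_error(critical_coupling(function(phi) 0 * phi, 0.1),
               "no-locking-channel")
})

test_that("fixed points appear exactly at the critical coupling", {
  G <- gamma_A_u()
  dw <- 0.05
  ec <- critical_coupling(G, dw)
  expect_true(locking_analysis(G, dw, 0.98 * ec)$drifting)
  expect_false(locking_analysis(G, dw, 1.02 * ec)$drifting)
})

test_that("gamma_a at A is first-harmonic dominated; at C it is not", {
  power <- function(G) {
    A <- vapply(1:8, function(k) mean(G$gamma_a * sin(k * G$phi)) * 2, 0)
    A^2 / sum(A^2)
  }
  expect_gt(power(gamma_A_u())[1], 0.95)
  expect_lt(power(gamma_C_v())[1], 0.5)
  expect_gt(power(gamma_C_v())[5], 0.5)
})
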