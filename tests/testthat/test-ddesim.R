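test_that("the rest state is preserved exactly by the integrator", {
  traj <- dde_integrate(param_A(), history = 0, t_end = 2)
  expect_true(all(traj$u == 0) && all(traj$v == 0))
})

test_that("the delay-free damped oscillator matches its closed form", {
  # b = 0, no nonlinearity: u'' + 2 g u' + g^2 (1 - a) u = 0
  g <- 10; a <- 0.75
  p <- model_params(0.5, g, a, 0, nl2 = 0, nl3 = 0)
  # u(0) = u0 (constant history), v(0) = 0: closed form from the two
  # characteristic roots of the quadratic
  disc <- sqrt(as.complex(4 * g^2 - 4 * g^2 * (1 - a)))
  r1 <- (-2 * g + disc) / 2; r2 <- (-2 * g - disc) / 2
  u0 <- 0.01
  c2 <- u0 * r1 / (r1 - r2); c1 <- u0 - c2
  uref <- function(t) Re(c1 * exp(r1 * t) + c2 * exp(r2 * t))
  traj <- dde_integrate(p, history = u0, t_end = 10, dt = 0.5 / 50)
  at10 <- traj_at(traj, 10)$u
  expect_equal(at10, uref(10), tolerance = 1e-8)
})

test_that("the linear DDE fixture reproduces the symbolic method of steps", {
  fx <- make_fixture("linear_dde", list(k = 5L))
  sim <- fx$integrate(t_end = 3, m = 40L)
  for (tt in c(0.5, 1, 1.5, 2.2, 3)) {
    i <- which.min(abs(sim$times - tt))
    expect_equal(sim$u[i], fx$reference(sim$times[i]), tolerance = 1e-8)
  }
})

test_that("the stepping scheme shows 4th-order convergence", {
  # measure at t = 5 where the exact solution is a degree-5 polynomial
  # (below degree 4 the scheme is exact and the ratio is indeterminate)
  fx <- make_fixture("linear_dde", list(k = 5L))
  err <- vapply(c(20L, 40L, 80L), function(m) {
    sim <- fx$integrate(t_end = 5, m = m)
    abs(sim$u[length(sim$u)] - fx$reference(5))
  }, 0)
  ord <- log2(err[-length(err)] / err[-1])
  expect_true(all(ord > 3.5 & ord < 4.5))
})

test_that("the network integrator self-converges at 4th order", {
  p <- param_C()  # strongly nonlinear exercise
  run <- function(m) {
    traj <- dde_integrate(p, history = 0.01, t_end = 6, dt = 0.3 / m)
    traj$u[nrow(traj$u), 1]
  }
  u1 <- run(20L); u2 <- run(40L); u3 <- run(80L); u4 <- run(160L)
  ord <- log2(abs(u1 - u2) / abs(u2 - u3))
  ord2 <- log2(abs(u2 - u3) / abs(u3 - u4))
  expect_gt(min(ord, ord2), 3.5)
  expect_lt(max(ord, ord2), 4.6)
})

test_that("the integrator agrees with an independent DDE solver", {
  p <- param_A()
  g <- p$damping
  f <- function(t, y, parms) {
    ul <- if (t <= p$delay) 0.01 else deSolve::lagvalue(t - p$delay, 1)
    list(c(y[2],
           -2 * g * y[2] - g^2 * (1 - p$gain_a) * y[1] +
             g^2 * (p$gain_b * ul + p$nl3 * y[1]^3)))
  }
  out <- deSolve::dede(c(0.01, 0), seq(0, 10, by = 0.01), f, NULL,
                       atol = 1e-10, rtol = 1e-10)
  traj <- dde_integrate(p, history = 0.01, t_end = 10, dt = p$delay / 60)
  mine <- traj_at(traj, 10)$u
  expect_equal(mine, unname(out[nrow(out), 2]), tolerance = 1e-6)
})

test_that("step-size and overflow guards trigger", {
  p <- param_A()
  expect_error(dde_integrate(p, history = 0.01, t_end = 1, dt = 0.3 / 7),
               "m >= 20")
  expect_error(dde_integrate(p, history = 0.01, t_end = 1, dt = 0.07),
               "m >= 20")
  punst <- model_params(0.3, 10, 0.6, -2, nl2 = 0, nl3 = 1)  # antisaturating
  expect_error(dde_integrate(punst, history = 0.5, t_end = 50),
               "divergence")
})

test_that("dense output interpolates the stored grid exactly", {
  traj <- dde_integrate(param_A(), t_end = 5)
  idx <- c(5L, 100L, 333L)
  at <- traj_at(traj, traj$times[idx])
  expect_equal(at$u, traj$u[idx, 1])
  expect_equal(at$v, traj$v[idx, 1])
  expect_error(traj_at(traj, 5.5), "outside")
})

test_that("period estimation on a pure sinusoid is exact to 1e-6", {
  fx <- make_fixture("sine_signal", list(period = 0.731, t_end = 15))
  # wrap the sampled sine as a trajectory-like object
  n <- length(fx$times)
  traj <- structure(list(times = fx$times, u = matrix(fx$u, n, 1),
                         v = matrix(fx$v, n, 1), dt = fx$params$dt,
                         m = 1L, params = list(param_A()), coupling = NULL,
                         meta = list()), class = "dde_trajectory")
  cyc <- find_limit_cycle(traj, transient = 1, n_phase = 32L)
  expect_false(cyc$quiescent)
  expect_equal(cyc$period, 0.731, tolerance = 1e-6 * 0.731)
  expect_equal(cyc$amplitude, 1, tolerance = 1e-5)
})

test_that("quiescent runs are flagged, not errors", {
  p <- params_at_offset(hopf_A(), -0.2)   # below onset: decays to rest
  traj <- dde_integrate(p, history = 0.01, t_end = 60)
  cyc <- find_limit_cycle(traj, transient = 50)
  expect_true(cyc$quiescent)
  expect_lt(cyc$amplitude, 1e-6)
})

test_that("near-onset cycles are sinusoidal, far-from-onset ones are not", {
  hA <- cycle_harmonics(cycle_A(), 5L)
  hC <- cycle_harmonics(cycle_C(), 5L)
  # odd symmetry: even harmonics vanish in both regimes
  expect_lt(hA[2] / hA[1], 1e-3)
  expect_lt(hC[2] / hC[1], 1e-3)
  # the first overtone (3rd harmonic) separates the two regimes
  expect_lt(hA[3] / hA[1], 0.05)
  expect_gt(hC[3] / hC[1], 0.05)
})

test_that("amplitude scales as sqrt(mu) near onset", {
  hp <- hopf_A()
  mus <- c(0.01, 0.018, 0.032, 0.056, 0.1)
  amps <- vapply(mus, function(mu) {
    p <- params_at_offset(hp, mu)
    settle_cycle(p, t_end = 700, transient = 500)$amplitude
  }, 0)
  fit <- stats::lm.fit(cbind(1, log(mus)), log(amps))
  expect_gt(fit$coefficients[2], 0.45)
  expect_lt(fit$coefficients[2], 0.55)
})

test_that("period tends to 2 pi / omega_c at onset", {
  p <- params_at_offset(hopf_A(), 0.004)
  cyc <- settle_cycle(p, t_end = 1500, transient = 1200)
  expect_equal(cyc$period, 2 * pi / hopf_A()$omega_c,
               tolerance = 0.01)
})

test_that("perturbed orbits relax at the CGL rate", {
  cyc <- cycle_A()
  p <- param_A()
  h <- cycle_history(cyc, 0)
  h$u <- h$u * 1.10; h$v <- h$v * 1.10    # radial kick off the attractor
  traj <- dde_integrate(p, history = h, t_end = 60)
  # envelope decay of the amplitude excess
  peaks <- vapply(seq(5, 50, by = 5), function(t0) {
    max(abs(traj$u[traj$times >= t0 & traj$times < t0 + 5, 1]))
  }, 0)
  excess <- peaks - cyc$amplitude
  sel <- excess > 1e-5
  fit <- stats::lm.fit(cbind(1, seq(5, 50, by = 5)[sel] + 2.5),
                       log(excess[sel]))
  rate <- -fit$coefficients[2]
  pred <- 2 * cgl_A()$mu[1]   # radial Floquet rate of the normal form
  expect_lt(abs(rate - pred) / pred, 0.10)
})
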