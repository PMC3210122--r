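test_that("characteristic function reduces to the quadratic when b = 0", {
  g <- 10; a <- 0.4
  p <- model_params(0.3, g, a, 0)
  # closed-form roots of lam^2 + 2 g lam + g^2 (1 - a)
  disc <- sqrt(as.complex(4 * g^2 - 4 * g^2 * (1 - a)))
  roots <- c((-2 * g + disc) / 2, (-2 * g - disc) / 2)
  for (r in roots)
    expect_lt(Mod(char_residual(r, p)), 1e-9)
})

test_that("characteristic function has real-coefficient conjugate symmetry", {
  p <- param_A()
  for (lam in c(0.3 + 2i, -1 - 7i, 5i, 2 + 0i))
    expect_equal(char_residual(Conj(lam), p),
                 Conj(char_residual(lam, p)))
})

test_that("the Hopf point is a root and matches a brute-force grid scan", {
  hp <- hopf_A()
  expect_lt(hp$residual, 1e-10)
  expect_lt(Mod(char_residual(1i * hp$omega_c, hp$params)), 1e-10)
  expect_gt(hp$omega_c, 0)

  # 2-D scan of |Delta(i w)| over (w, b): minimum within one cell
  p0 <- param_A()
  ws <- seq(4, 7, length.out = 121)
  bs <- seq(-1.4, -0.9, length.out = 121)
  best <- c(Inf, NA, NA)
  for (b in bs) {
    pb <- model_params(p0$delay, p0$damping, p0$gain_a, b)
    r <- Mod(char_residual(1i * ws, pb))
    i <- which.min(r)
    if (r[i] < best[1]) best <- c(r[i], ws[i], b)
  }
  expect_lt(abs(best[2] - hp$omega_c), diff(ws[1:2]) * 1.5)
  expect_lt(abs(best[3] - hp$gain_critical), diff(bs[1:2]) * 1.5)
})

test_that("continuation along the Hopf curve matches independent solves", {
  av <- seq(-0.5, 0.8, length.out = 14)
  cv <- hopf_curve(av, param_A())
  expect_identical(nrow(cv), length(av))
  expect_true(all(cv$residual < 1e-10))
  # branch continuity
  expect_true(all(abs(diff(cv$omega_c)) < 0.5))
  # fresh per-point solves agree to 1e-8
  for (i in c(1, 7, 14)) {
    hp <- find_hopf(model_params(0.3, 10, av[i], 0))
    expect_equal(cv$gain_critical[i], hp$gain_critical, tolerance = 1e-8)
    expect_equal(cv$omega_c[i], hp$omega_c, tolerance = 1e-8)
  }
})

test_that("points A, B, C lie on the unstable side of the curve", {
  for (p in load_param_sets()) {
    hp <- find_hopf(p)
    expect_gt(hp$direction * (p$gain_b - hp$gain_critical), 0)
  }
})

test_that("spectrum classification flips across the critical gain", {
  hp <- hopf_A()
  sub <- leading_roots(params_at_offset(hp, -0.1), real_floor = -20)
  expect_true(sub$stable)
  sup <- leading_roots(params_at_offset(hp, 0.1), real_floor = -20)
  expect_false(sup$stable)
  # at criticality the leading pair sits on the axis at +- omega_c
  crit <- leading_roots(params_at_offset(hp, 0), real_floor = -20)
  lead <- crit$roots[1]
  expect_lt(abs(Re(lead)), 1e-6)
  expect_equal(abs(Im(lead)), hp$omega_c, tolerance = 1e-6)
  # conjugate pairing
  for (r in crit$roots[Im(crit$roots) > 1e-8])
    expect_true(any(Mod(crit$roots - Conj(r)) < 1e-8))
})

test_that("root finder agrees with an argument-principle contour count", {
  p <- params_at_offset(hopf_A(), 0.1)
  # rectangle Re in [-6, 2], Im in [0.5, 12] (avoids the real axis)
  corners <- c(-6 + 0.5i, 2 + 0.5i, 2 + 12i, -6 + 12i, -6 + 0.5i)
  wrap <- function(x) atan2(sin(x), cos(x))
  winding <- 0
  for (k in 1:4) {
    z <- seq(0, 1, length.out = 4000)
    path <- corners[k] + z * (corners[k + 1] - corners[k])
    f <- char_residual(path, p)
    winding <- winding + sum(wrap(diff(Arg(f))))
  }
  n_contour <- round(winding / (2 * pi))
  found <- leading_roots(p, real_floor = -6)$roots
  inside <- sum(Re(found) > -6 & Re(found) < 2 &
                  Im(found) > 0.5 & Im(found) < 12)
  expect_identical(inside, as.integer(n_contour))
})

test_that("leading root grows linearly with the offset at the CGL rate", {
  hp <- hopf_A()
  slopes <- vapply(c(0.01, 0.02), function(mu) {
    p <- params_at_offset(hp, mu)
    Re(leading_roots(p, real_floor = -5, n_max = 4L)$roots[1]) / mu
  }, 0)
  pred <- Re(hp$dlam_dmu)
  expect_lt(abs(slopes[1] - pred) / pred, 0.05)
  expect_lt(abs(slopes[2] - pred) / pred, 0.05)
})

test_that("hopf solver reports failure modes", {
  expect_error(find_hopf(param_A(), c(0.1, 1)), "root-not-found")
  expect_error(hopf_curve(0.5, param_A()), "at least 2")
})
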