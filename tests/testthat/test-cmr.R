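test_that("center basis and dual basis pair to the identity", {
  hp <- hopf_A()
  cb <- build_center_basis(hp, param_A())
  # closed-form normalization against high-resolution quadrature
  pc <- hp$params
  N <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    psi_i <- function(s) cb$psi(s)[i, ]
    phi_j <- function(th) cb$phi(th)[, j]
    N[i, j] <- Re(hale_pairing(psi_i, phi_j, pc, n = 20000L))
  }
  expect_equal(N, diag(2), tolerance = 1e-8)
  # complex pair: <psi, phi> = D and <psi, conj(phi)> = 0
  w <- hp$omega_c
  psi_c <- function(s) cb$p * exp(-1i * w * s)
  phi_c <- function(th) cb$q * exp(1i * w * th)
  phi_cc <- function(th) Conj(cb$q) * exp(-1i * w * th)
  expect_equal(hale_pairing(psi_c, phi_c, pc, n = 20000L), cb$D,
               tolerance = 1e-8)
  expect_lt(Mod(hale_pairing(psi_c, phi_cc, pc, n = 20000L)),
            1e-7 * Mod(cb$D))
})

test_that("the basis at theta = 0 is the eigenvector of the linearization", {
  hp <- hopf_A()
  cb <- build_center_basis(hp, param_A())
  g <- param_A()$damping
  A <- matrix(c(0, 1, -g^2 * (1 - param_A()$gain_a), -2 * g), 2, 2,
              byrow = TRUE)
  B <- matrix(c(0, 0, g^2 * hp$gain_critical, 0), 2, 2, byrow = TRUE)
  M <- A + B * exp(-1i * hp$omega_c * hp$params$delay)
  expect_lt(max(Mod(M %*% cb$q - 1i * hp$omega_c * cb$q)), 1e-8)
})

test_that("the analytic reduction refuses a quadratic nonlinearity", {
  p <- model_params(0.3, 10, 0.6, -1.2, nl2 = 0.3, nl3 = -1)
  expect_error(amplitude_equation(p), "nl2")
})

test_that("reduction coefficients: criticality, supercriticality", {
  hp <- hopf_A()
  p0 <- params_at_offset(hp, 0)
  amp0 <- amplitude_equation(p0, hopf_list = list(hp))
  expect_equal(amp0$red[[1]]$growth, 0, tolerance = 1e-10)
  # supercritical cubic throughout the explored gain range
  for (a in c(-1.4, 0, 0.6, 0.9)) {
    hp_a <- find_hopf(model_params(0.3, 10, a, 0, nl3 = -1))
    r <- amplitude_equation(params_at_offset(hp_a, 0.05),
                            hopf_list = list(hp_a))$red[[1]]
    expect_lt(Re(r$c), 0)
  }
})

test_that("reduced and full models agree on the cycle amplitude", {
  cgl <- cgl_A()
  expect_equal(2 * cgl$R_inf[1], cycle_A()$amplitude, tolerance = 0.1)
  # and on the orbital frequency
  Om <- cgl$omega[1] + Im(cgl$c[1]) * cgl$R_inf[1]^2
  expect_equal(2 * pi / Om, cycle_A()$period, tolerance = 0.01)
})

test_that("Stuart-Landau closed form is recovered by the averaged system", {
  cgl <- cgl_A()
  amp <- amplitude_equation(param_A(), hopf_list = list(hopf_A()))
  sim <- simulate_amplitude(amp, 0.01 + 0i, t_end = 200, dt = 0.01,
                            averaged = TRUE)
  r_end <- unname(Mod(sim$z[nrow(sim$z), 1]))
  expect_equal(r_end, cgl$R_inf[1], tolerance = 1e-4)
})

test_that("unaveraged and averaged amplitude equations agree on envelopes", {
  amp <- amplitude_equation(param_A(), hopf_list = list(hopf_A()))
  T0 <- 2 * pi / hopf_A()$omega_c
  horizon <- 50 * T0
  full <- simulate_amplitude(amp, 0.02 + 0i, t_end = horizon, dt = 0.002,
                             averaged = FALSE)
  avg <- simulate_amplitude(amp, 0.02 + 0i, t_end = horizon, dt = 0.002,
                            averaged = TRUE)
  # compare amplitude envelopes on a coarse grid (the full solution's
  # modulus carries a small counter-rotating ripple)
  idx <- round(seq(1, nrow(full$z), length.out = 40L))
  env_full <- Mod(full$z[idx, 1])
  env_avg <- Mod(avg$z[idx, 1])
  expect_lt(max(abs(env_full - env_avg) / pmax(env_avg, 1e-4)), 0.05)
})

test_that("the synchronized manifold is invariant for identical pairs", {
  p <- param_A()
  cm <- coupling_matrix(2, eps_u = 0.05, eps_v = 0.02)
  amp <- amplitude_equation(list(p, p), cm,
                            hopf_list = list(hopf_A(), hopf_A()))
  sim <- simulate_amplitude(amp, c(0.03 + 0.01i, 0.03 + 0.01i),
                            t_end = 30, dt = 0.005)
  expect_lt(max(Mod(sim$z[, 1] - sim$z[, 2])), 1e-10)
})

test_that("analytic phase sensitivity is a pure sinusoid scaling as 1/sqrt(mu)", {
  Z <- analytic_Z(cgl_A(), "v", n_phase = 128L)
  sp <- Mod(stats::fft(Z$Z))^2
  expect_lt(sp[3] / sp[2], 1e-10)          # 2nd harmonic / 1st
  hp <- hopf_A()
  amp4 <- amplitude_equation(params_at_offset(hp, 4 * 0.03),
                             hopf_list = list(hp))
  Z4 <- analytic_Z(cgl_reduce(amp4), "v", n_phase = 128L)
  expect_equal(max(abs(Z4$Z)) / max(abs(Z$Z)), 0.5, tolerance = 0.01)
  expect_error(analytic_Z(cgl_reduce(
    amplitude_equation(params_at_offset(hp, -0.01),
                       hopf_list = list(hp))), "v"), "no-cycle")
})

test_that("analytic Z and Gamma match the direct numerical measurements", {
  Zan <- analytic_Z(cgl_A(), "v", n_phase = 64L)
  expect_lt(nrms(prc_A()$Z, Zan$Z), 0.10)
  Gan <- analytic_gamma(cgl_A(), "u", n_phase = 64L)
  expect_lt(nrms(gamma_A_u()$gamma, Gan$gamma), 0.10)
  # v channel too: the closed form tracks the convolution
  Gv <- gamma_convolution(prc_A(), cycle_A(), "v")
  Gvan <- analytic_gamma(cgl_A(), "v", n_phase = 64L)
  expect_lt(nrms(Gv$gamma, Gvan$gamma), 0.10)
})

test_that("analytic Gamma evaluated by quadrature matches its mean form", {
  # Gamma(0) is the mean of the diffusive integrand at zero lag: zero
  Gan <- analytic_gamma(cgl_A(), "u", n_phase = 64L)
  expect_equal(Gan$gamma[1], 0, tolerance = 1e-12)
  expect_equal(Gan$gamma_a + rev(c(Gan$gamma_a[-1], Gan$gamma_a[1])),
               rep(0, 64), tolerance = 1e-12)
})

test_that("death eigenvalues reduce to the uncoupled growth rates", {
  sets <- load_param_sets()
  amp <- amplitude_equation(list(sets$A, sets$B))
  de <- death_eigenvalues(amp, 0, "u")
  g <- sort(rep(vapply(amp$red, `[[`, 0, "growth"), 2))
  expect_equal(sort(Re(de$lambdas)), g, tolerance = 1e-10)
})

test_that("perturbative and exact death eigenvalues agree for small mismatch", {
  hp <- hopf_A()
  pr <- match_pair(hp, 0.1, mu = 0.03)
  amp <- amplitude_equation(pr$params, hopf_list = pr$hopf)
  for (e in c(0.05, 0.1)) {
    de <- death_eigenvalues(amp, e, "u")
    ex <- sort(Re(de$lambdas), decreasing = TRUE)[c(1, 3)]
    pe <- sort(Re(de$lambdas_perturbative), decreasing = TRUE)
    expect_lt(max(abs(ex - pe)), 0.05 * max(abs(ex)))
  }
})

test_that("the death region is a single interval over coupling strength", {
  sets <- load_param_sets()
  amp <- amplitude_equation(list(sets$A, sets$B))
  es <- seq(0, 1.5, length.out = 60L)
  mr <- vapply(es, function(e) death_eigenvalues(amp, e, "u")$max_re, 0)
  dead <- mr < 0
  runs <- rle(dead)
  expect_lte(sum(runs$values), 1L)   # at most one dead interval
  expect_true(any(dead))
})
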