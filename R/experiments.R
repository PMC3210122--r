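#' Construct an equal-amplitude pair with a prescribed frequency mismatch
#'
#' Inverts the Hopf relations of the characteristic equation: the partner
#' oscillator keeps the same bifurcation offset \eqn{\mu} (hence the same
#' amplitude, to leading order) while its cortico-cortical gain \eqn{a} is
#' solved for so that its critical frequency is
#' \eqn{\omega_c + \Delta\omega}. Because the critical frequency decreases
#' with \eqn{a}, positive mismatches move the partner to smaller \eqn{a}.
#'
#' @param ref_hopf the reference oscillator's `hopf_point`.
#' @param delta_omega required frequency mismatch (rad/s).
#' @param mu shared bifurcation offset.
#' @param a_bracket search interval for the partner's gain \eqn{a}.
#' @return A list with `params` (list of two [model_params()]), `hopf`
#'   (list of two `hopf_point`s) and `delta_omega`.
#' @export
match_pair <- function(ref_hopf, delta_omega, mu = 0.03,
                       a_bracket = c(-1.5, 0.95)) {
  stopifnot(inherits(ref_hopf, "hopf_point"))
  p0 <- ref_hopf$params
  target <- ref_hopf$omega_c + delta_omega
  f <- function(a) {
    find_hopf(model_params(p0$delay, p0$damping, a, 0, p0$nl2,
                           p0$nl3))$omega_c - target
  }
  a2 <- if (abs(delta_omega) < 1e-14) ref_hopf$second_gain else
    stats::uniroot(f, a_bracket, tol = 1e-12)$root
  hp2 <- find_hopf(model_params(p0$delay, p0$damping, a2, 0, p0$nl2,
                                p0$nl3))
  list(params = list(params_at_offset(ref_hopf, mu),
                     params_at_offset(hp2, mu)),
       hopf = list(ref_hopf, hp2), delta_omega = delta_omega, mu = mu)
}

# unwrapped phase difference (osc 1 minus osc 2) from crossing times
phase_difference_series <- function(traj, after, period) {
  c1 <- upward_crossings(traj, 1L, after = after)
  c2 <- upward_crossings(traj, 2L, after = after)
  if (length(c1) < 3L || length(c2) < 3L) return(NULL)
  # phase of oscillator 2 at the crossing times of oscillator 1
  ph2 <- stats::approx(c2, 2 * pi * seq_along(c2), xout = c1,
                       rule = 1)$y
  ph1 <- 2 * pi * seq_along(c1)
  ok <- !is.na(ph2)
  if (sum(ok) < 3L) return(NULL)
  list(times = c1[ok], dphi = ph1[ok] - ph2[ok])
}

# drift-rate lock test: locked iff the mean phase-difference drift over
# the measurement window stays below tol_rate (rad per rotation)
is_locked <- function(traj, t_measure, period, tol_rate = 2 * pi * 1e-3) {
  pd <- phase_difference_series(traj, after = t_measure, period)
  if (is.null(pd) || length(pd$times) < 10L) return(NA)
  fit <- stats::lm.fit(cbind(1, pd$times), pd$dphi)
  abs(fit$coefficients[2]) * period < tol_rate
}

#' Critical coupling strength by three levels of description
#'
#' For each frequency mismatch the critical coupling for phase locking of
#' an equal-amplitude pair (u-channel, diffusive) is computed three ways:
#' \describe{
#'   \item{`eps_dde`}{bisection over full delay-differential simulations
#'     with a crossing-time drift criterion;}
#'   \item{`eps_amplitude`}{the same bisection over simulations of the
#'     unaveraged amplitude equations;}
#'   \item{`eps_phase`}{the closed formula
#'     \eqn{|\Delta\omega|/\max(\mp\Gamma_a)} from the measured phase
#'     coupling function at the reference point, evaluated at the pair's
#'     measured (uncoupled) orbital frequency mismatch \eqn{\Delta\Omega}
#'     -- the inverse construction from the critical frequencies leaves a
#'     small systematic offset in the realized mismatch, and the phase
#'     description is a statement about the realized frequencies.}
#' }
#'
#' @param delta_omegas numeric vector of frequency mismatches (rad/s).
#' @param ref a [model_params()] for the reference working point (default
#'   packaged point A).
#' @param mu shared bifurcation offset.
#' @param gamma_a a `coupling_function` for the u channel at the reference
#'   point; computed from a direct PRC when `NULL`.
#' @param t_sim,t_transient simulation horizon and transient (s) for the
#'   lock tests.
#' @param rel_tol relative bisection tolerance on the critical coupling.
#' @param methods subset of `c("dde", "amplitude", "phase")`.
#' @return A data.frame with one row per mismatch and one column per
#'   method (`NA` where bisection failed, with a warning).
#' @export
exp_critical_coupling <- function(delta_omegas, ref = NULL, mu = 0.03,
                                  gamma_a = NULL,
                                  t_sim = 400, t_transient = 150,
                                  rel_tol = 0.05,
                                  methods = c("dde", "amplitude",
                                              "phase")) {
  if (is.null(ref)) ref <- load_param_sets()[["A"]]
  hp <- find_hopf(ref)
  ref_mu <- params_at_offset(hp, mu)
  if (is.null(gamma_a) && "phase" %in% methods) {
    cyc <- settle_cycle(ref_mu, t_end = 250, transient = 200,
                        n_phase = 64L)
    prc <- prc_direct(ref_mu, cyc, n_phase = 64L, relax_periods = 40L)
    gamma_a <- gamma_convolution(prc, cyc, "u")
  }
  lock_dde <- function(pair, eps, t_sim) {
    cm <- coupling_matrix(2, eps_u = eps)
    traj <- dde_integrate(pair$params, cm, history = function(s) c(0.01, 0.012),
                          t_end = t_sim)
    T0 <- 2 * pi / mean(vapply(pair$hopf, `[[`, 0, "omega_c"))
    is_locked(traj, t_transient, T0)
  }
  lock_amp <- function(pair, eps, t_sim) {
    cm <- coupling_matrix(2, eps_u = eps)
    amp <- amplitude_equation(pair$params, cm, pair$hopf)
    sim <- simulate_amplitude(amp, c(0.01 + 0i, 0.012 + 0i), t_end = t_sim,
                              dt = 0.01)
    sel <- sim$times >= t_transient
    dphi <- Arg(sim$z[sel, 1]) - Arg(sim$z[sel, 2])
    dphi <- cumsum(c(dphi[1], atan2(sin(diff(dphi)), cos(diff(dphi)))))
    T0 <- 2 * pi / mean(vapply(pair$hopf, `[[`, 0, "omega_c"))
    fit <- stats::lm.fit(cbind(1, sim$times[sel]), dphi)
    abs(fit$coefficients[2]) * T0 < 2 * pi * 1e-3
  }
  bisect_eps <- function(locked_at, eps_hint) {
    hi <- max(eps_hint, 1e-4)
    for (i in 1:10) {
      lk <- locked_at(hi)
      if (is.na(lk)) return(NA_real_)
      if (lk) break
      hi <- hi * 2
    }
    if (!lk) return(NA_real_)
    lo <- 0
    while ((hi - lo) > rel_tol * hi) {
      mid <- (hi + lo) / 2
      lk <- locked_at(mid)
      if (is.na(lk)) return(NA_real_)
      if (lk) hi <- mid else lo <- mid
    }
    (hi + lo) / 2
  }
  out <- data.frame(delta_omega = delta_omegas,
                    delta_omega_measured = NA_real_)
  for (m in methods)
    out[[paste0("eps_", if (m == "amplitude") "amplitude" else m)]] <-
      NA_real_
  for (i in seq_along(delta_omegas)) {
    dw <- delta_omegas[i]
    if (dw == 0) {
      out$delta_omega_measured[i] <- 0
      if ("phase" %in% methods) out$eps_phase[i] <- 0
      if ("dde" %in% methods) out$eps_dde[i] <- 0
      if ("amplitude" %in% methods) out$eps_amplitude[i] <- 0
      next
    }
    pair <- match_pair(hp, dw, mu)
    # realized mismatch of the uncoupled pair (shifted by the offset- and
    # amplitude-induced frequency corrections)
    Om <- vapply(pair$params, function(p) {
      cy <- settle_cycle(p, t_end = 200, transient = 150)
      2 * pi / cy$period
    }, 0)
    dw_meas <- Om[2] - Om[1]
    out$delta_omega_measured[i] <- dw_meas
    ep <- if (!is.null(gamma_a)) critical_coupling(gamma_a, dw_meas) else NA
    if ("phase" %in% methods) out$eps_phase[i] <- ep
    # window long enough to resolve slow beating near threshold
    t_run <- max(t_sim, min(25 / max(abs(dw_meas), 1e-3), 1200))
    hint <- if (is.finite(ep) && ep > 0) ep else 0.01
    if ("dde" %in% methods) {
      v <- tryCatch(bisect_eps(function(e) lock_dde(pair, e, t_run), hint),
                    error = function(e) NA_real_)
      if (is.na(v)) warning("DDE bisection failed at delta_omega = ", dw)
      out$eps_dde[i] <- v
    }
    if ("amplitude" %in% methods) {
      v <- tryCatch(bisect_eps(function(e) lock_amp(pair, e, t_run), hint),
                    error = function(e) NA_real_)
      if (is.na(v)) warning("amplitude bisection failed at delta_omega = ",
                            dw)
      out$eps_amplitude[i] <- v
    }
  }
  out
}

#' Amplitude death sweep for the A-B pair
#'
#' Couples the two standard working points A and B (equal offsets, ~45%
#' frequency mismatch) through the u channel and sweeps the coupling
#' strength. For each strength the pair is integrated from small initial
#' data and the asymptotic amplitudes are measured; an oscillator is dead
#' when its amplitude falls below `1e-6` times its uncoupled amplitude.
#' The eigenvalue-based prediction from the reduced amplitude equations is
#' attached (`threshold_pred`). If `find_onset` is set the simulated onset
#' is located by bisection on the asymptotic decay/growth rate of the
#' amplitude envelope (the sign of the leading Floquet/eigenvalue rate),
#' which is insensitive to the finite observation window.
#'
#' @param eps_values coupling strengths to sweep.
#' @param params_list two [model_params()]; default packaged A and B.
#' @param t_end,transient integration horizon and discarded transient.
#' @param find_onset logical: also bisect the simulated death onset.
#' @return A data.frame (eps, amp1, amp2, dead) with attributes
#'   `threshold_pred` and (optionally) `threshold_sim`.
#' @export
exp_amplitude_death <- function(eps_values = seq(0, 0.5, by = 0.05),
                                params_list = NULL,
                                t_end = 120, transient = 80,
                                find_onset = FALSE) {
  if (is.null(params_list)) {
    sets <- load_param_sets()
    params_list <- list(sets$A, sets$B)
  }
  amp0 <- vapply(params_list, function(p) {
    cy <- settle_cycle(p, t_end = t_end, transient = transient)
    cy$amplitude
  }, 0)
  run <- function(eps) {
    cm <- coupling_matrix(2, eps_u = eps)
    traj <- dde_integrate(params_list, cm,
                          history = function(s) c(0.01, 0.012),
                          t_end = t_end)
    vapply(1:2, function(j)
      find_limit_cycle(traj, transient, osc = j)$amplitude, 0)
  }
  res <- t(vapply(eps_values, run, numeric(2)))
  dead <- res[, 1] < 1e-6 * amp0[1] & res[, 2] < 1e-6 * amp0[2]
  out <- data.frame(eps = eps_values, amp1 = res[, 1], amp2 = res[, 2],
                    dead = dead)
  amp <- amplitude_equation(params_list,
                            coupling_matrix(2, eps_u = 1))
  de <- death_eigenvalues(amp, eps = 0.1, channel = "u",
                          find_threshold = TRUE, eps_max = 2)
  attr(out, "threshold_pred") <- de$threshold_eps
  if (find_onset) {
    t_run <- 400
    decaying_at <- function(e) {
      cm <- coupling_matrix(2, eps_u = e)
      traj <- dde_integrate(params_list, cm,
                            history = function(s) c(0.01, 0.012),
                            t_end = t_run)
      early <- max(abs(traj$u[traj$times >= 150 & traj$times <= 200, ]))
      late <- max(abs(traj$u[traj$times >= t_run - 50, ]))
      late < 0.7 * early
    }
    thr0 <- attr(out, "threshold_pred")
    hi <- if (is.finite(thr0) && !is.na(thr0)) 2 * thr0 else 1
    for (i in 1:6) {
      if (decaying_at(hi)) break
      hi <- hi * 1.5
    }
    if (!decaying_at(hi)) {
      warning("no simulated death onset found")
      attr(out, "threshold_sim") <- NA_real_
    } else {
      lo <- 0
      while ((hi - lo) > 0.02 * hi) {
        mid <- (hi + lo) / 2
        if (decaying_at(mid)) hi <- mid else lo <- mid
      }
      attr(out, "threshold_sim") <- (hi + lo) / 2
    }
  }
  out
}

#' Multimodal phase locking of an identical pair
#'
#' Two identical oscillators at the strongly anharmonic working point are
#' coupled weakly and diffusively through the chosen channel and released
#' from a uniform grid of initial phase differences (time-shifted history
#' segments of the same converged cycle). Each run is integrated until the
#' phase difference settles; the distinct final values are clustered and
#' compared against the basins predicted by the reduced phase-difference
#' equation.
#'
#' @param params a [model_params()]; default packaged point C.
#' @param channel coupling channel (`"v"` is the one that supports
#'   five-fold locking at the packaged C).
#' @param eps coupling strength.
#' @param n_init number of initial phase differences.
#' @param t_end integration horizon (s).
#' @param diagram optional precomputed `locking_diagram` for the same
#'   channel; computed from a direct PRC when `NULL`.
#' @param n_phase,relax_periods PRC settings when the diagram is computed
#'   internally.
#' @return A list with `table` (data.frame `phi_initial`, `phi_final`,
#'   `settled`, `attractor_sim`, `attractor_pred`), `diagram`, `n_distinct`
#'   (clusters among settled runs), `agreement` (fraction of settled runs
#'   landing in the predicted basin's attractor).
#' @export
exp_multimodal <- function(params = NULL, channel = "v", eps = 0.02,
                           n_init = 20L, t_end = 500,
                           diagram = NULL, n_phase = 128L,
                           relax_periods = 30L) {
  if (is.null(params)) params <- load_param_sets()[["C"]]
  cyc <- settle_cycle(params, t_end = 250, transient = 200,
                      n_phase = n_phase)
  if (is.null(diagram)) {
    prc <- prc_direct(params, cyc, n_phase = n_phase,
                      relax_periods = relax_periods)
    gma <- gamma_convolution(prc, cyc, channel)
    diagram <- locking_analysis(gma, 0, eps)
  }
  stable_phi <- diagram$fixed_points$phi[diagram$fixed_points$stable]
  T0 <- cyc$period
  phi0 <- seq(0, 2 * pi, length.out = n_init + 1L)[seq_len(n_init)]
  cm <- coupling_matrix(2,
                        eps_u = if (channel == "u") eps else 0,
                        eps_v = if (channel == "v") eps else 0)
  res <- lapply(phi0, function(ph) {
    h1 <- cycle_history(cyc, 0)
    h2 <- cycle_history(cyc, ph)
    hist <- list(u = cbind(h1$u, h2$u), v = cbind(h1$v, h2$v))
    traj <- dde_integrate(rep(list(params), 2), cm, history = hist,
                          t_end = t_end)
    pd <- phase_difference_series(traj, after = t_end * 0.05, T0)
    if (is.null(pd)) return(list(final = NA_real_, settled = FALSE))
    nwin <- min(50L, floor(length(pd$dphi) / 4))
    tail_d <- utils::tail(pd$dphi, nwin)
    settled <- (max(tail_d) - min(tail_d)) < 1e-2
    list(final = mean(tail_d) %% (2 * pi), settled = settled)
  })
  phif <- vapply(res, `[[`, 0, "final")
  settled <- vapply(res, `[[`, TRUE, "settled")
  # cluster the settled finals against the predicted stable points
  nearest_stable <- function(x) {
    if (length(stable_phi) == 0L) return(NA_integer_)
    d <- abs(outer(x, stable_phi, "-"))
    d <- pmin(d, 2 * pi - d)
    apply(d, 1L, which.min)
  }
  att_sim <- rep(NA_integer_, n_init)
  att_sim[settled] <- nearest_stable(phif[settled])
  att_pred <- if (!diagram$drifting)
    diagram$basin_of(-phi0) else rep(NA_integer_, n_init)
  # distinct clusters among settled finals (circular gap clustering)
  n_distinct <- if (any(settled)) {
    v <- sort(phif[settled])
    gaps <- diff(c(v, v[1] + 2 * pi))
    sum(gaps > 0.3)
  } else 0L
  # runs seeded exactly on an unstable point have no predicted basin
  cmp <- settled & !is.na(att_pred)
  agreement <- if (any(cmp)) mean(att_sim[cmp] == att_pred[cmp])
               else NA_real_
  list(table = data.frame(phi_initial = phi0, phi_final = phif,
                          settled = settled, attractor_sim = att_sim,
                          attractor_pred = att_pred),
       diagram = diagram, n_distinct = n_distinct,
       agreement = agreement, period = T0)
}

#' Kuramoto order parameter of a phase ensemble
#'
#' \eqn{R(t) = |n^{-1}\sum_j e^{i\theta_j(t)}|}: 0 for incoherence, 1 for
#' full synchrony.
#'
#' @param phases numeric matrix (time x oscillator) of phases in radians.
#' @return Numeric vector `R(t)`.
#' @export
kuramoto_order_parameter <- function(phases) {
  if (length(phases) == 0L) stop("empty phase input")
  if (!is.matrix(phases)) phases <- matrix(phases, nrow = 1L)
  Mod(rowMeans(exp(1i * phases)))
}

# crossing-based phases on a common time grid for every oscillator
crossing_phases <- function(traj, tgrid) {
  n <- ncol(traj$u)
  ph <- matrix(NA_real_, length(tgrid), n)
  for (j in seq_len(n)) {
    cr <- upward_crossings(traj, j, after = tgrid[1] - 5)
    if (length(cr) < 3L) next
    ph[, j] <- stats::approx(cr, 2 * pi * seq_along(cr), xout = tgrid,
                             rule = 2)$y
  }
  ph
}

#' Population synchronization transition
#'
#' Simulates an all-to-all, u-channel diffusively coupled ensemble of
#' delay-induced oscillators with heterogeneous gains drawn around working
#' point A (coupling normalized by the ensemble size), sweeps the coupling
#' strength, and reports the time-averaged Kuramoto order parameter from
#' crossing-time phases. Optionally co-simulates the reduced phase model
#' (same frequencies, the measured phase coupling function of the
#' reference oscillator) on the same ensemble.
#'
#' @param eps_values coupling strengths to sweep.
#' @param n ensemble size.
#' @param seed integer seed for the parameter draw.
#' @param a_spread,mu_spread half-widths of the uniform gain and offset
#'   distributions around point A.
#' @param t_end,transient horizon and discarded transient (s).
#' @param phase_model logical: also run the reduced phase-model sweep.
#' @param gamma_fun optional `coupling_function` (u channel) for the phase
#'   model; measured at A when `NULL`.
#' @return A data.frame (eps, R_dde, and R_phase when requested) with
#'   attribute `"ensemble"` (the drawn parameters and uncoupled
#'   frequencies).
#' @export
exp_population <- function(eps_values = c(0, 0.015, 0.04, 0.1),
                           n = 50L, seed = 1L,
                           a_spread = 0.05, mu_spread = 0.01,
                           t_end = 120, transient = 60,
                           phase_model = TRUE, gamma_fun = NULL) {
  if (n < 10L) warning("order parameter is noisy for n < 10")
  sets <- load_param_sets()
  pA <- sets$A
  mu_A <- find_hopf(pA)$gain_critical - pA$gain_b
  fx <- make_fixture("population_sample",
                     list(n = n, a_center = pA$gain_a,
                          a_spread = a_spread, mu_center = mu_A,
                          mu_spread = mu_spread),
                     seed = seed)
  params <- vector("list", n)
  omega0 <- numeric(n)
  for (j in seq_len(n)) {
    hp <- find_hopf(model_params(pA$delay, pA$damping, fx$a[j], 0,
                                 pA$nl2, pA$nl3))
    params[[j]] <- params_at_offset(hp, fx$mu[j])
    omega0[j] <- hp$omega_c
  }
  # deterministic, seed-reproducible initial history offsets
  set.seed(split_seed(seed, 1L))
  h0 <- stats::runif(n, 0.005, 0.02)
  tgrid <- seq(transient, t_end, by = 0.05)
  run_dde <- function(eps) {
    cm <- coupling_matrix(n, eps_u = eps / n)
    traj <- dde_integrate(params, cm, history = function(s) h0,
                          t_end = t_end)
    ph <- crossing_phases(traj, tgrid)
    ok <- colSums(is.na(ph)) == 0L
    mean(kuramoto_order_parameter(ph[, ok, drop = FALSE]))
  }
  out <- data.frame(eps = eps_values,
                    R_dde = vapply(eps_values, run_dde, 0))
  # uncoupled frequencies for the phase model (measured once)
  traj0 <- dde_integrate(params, NULL, history = function(s) h0,
                         t_end = t_end)
  Omega <- vapply(seq_len(n), function(j) {
    cy <- find_limit_cycle(traj0, transient, osc = j)
    if (cy$quiescent) NA_real_ else 2 * pi / cy$period
  }, 0)
  attr(out, "ensemble") <- list(a = fx$a, mu = fx$mu, omega_c = omega0,
                                Omega = Omega)
  if (phase_model) {
    ok <- !is.na(Omega)
    if (any(!ok))
      warning(sum(!ok), " quiescent ensemble members excluded from the ",
              "phase model")
    Omega_ph <- Omega[ok]
    n_ph <- sum(ok)
    if (is.null(gamma_fun)) {
      cyc <- settle_cycle(pA, t_end = 150, transient = 100,
                          n_phase = 64L)
      prc <- prc_direct(pA, cyc, n_phase = 64L, relax_periods = 25L)
      gamma_fun <- gamma_convolution(prc, cyc, "u")
    }
    # Fourier form of Gamma for O(n K) mean-field evaluation
    K <- 8L
    gv <- gamma_fun$gamma
    np <- length(gv)
    ck <- stats::fft(gv) / np
    run_phase <- function(eps) {
      th <- 2 * pi * (seq_len(n_ph) - 1) / n_ph  # uniform start
      dt <- 0.02
      steps <- as.integer(t_end / dt)
      keep <- numeric(0)
      drift <- function(th) {
        s <- vapply(0:K, function(m) mean(exp(1i * m * th)), complex(1))
        # sum_k Gamma(th_k - th_j)/n = sum_m c_m conj(e^{im th_j}) S_m
        acc <- Re(ck[1]) + 0 * th
        for (m in 1:K)
          acc <- acc + 2 * Re(ck[m + 1] * s[m + 1] * exp(-1i * m * th))
        Omega_ph + eps * acc
      }
      for (s_ in seq_len(steps)) {
        k1 <- drift(th); k2 <- drift(th + dt / 2 * k1)
        k3 <- drift(th + dt / 2 * k2); k4 <- drift(th + dt * k3)
        th <- th + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        if (s_ * dt >= transient && s_ %% 5L == 0L)
          keep <- c(keep, kuramoto_order_parameter(th))
      }
      mean(keep)
    }
    out$R_phase <- vapply(eps_values, run_phase, 0)
  }
  out
}

#' Fraction of quiescent oscillators vs coupling (population death)
#'
#' Variant of the population sweep with a broad frequency spread: strong
#' all-to-all coupling between detuned delay-induced oscillators quenches
#' the whole ensemble.
#'
#' @inheritParams exp_population
#' @return A data.frame (eps, dead_fraction, mean_amplitude).
#' @export
exp_population_death <- function(eps_values = c(0, 0.5, 1, 2),
                                 n = 20L, seed = 1L,
                                 a_spread = 0.45, mu_spread = 0.03,
                                 t_end = 120, transient = 80) {
  sets <- load_param_sets()
  pA <- sets$A
  fx <- make_fixture("population_sample",
                     list(n = n, a_center = 0.45, a_spread = a_spread,
                          mu_spread = mu_spread), seed = seed)
  params <- vector("list", n)
  for (j in seq_len(n)) {
    hp <- find_hopf(model_params(pA$delay, pA$damping, fx$a[j], 0,
                                 pA$nl2, pA$nl3))
    params[[j]] <- params_at_offset(hp, fx$mu[j])
  }
  set.seed(split_seed(seed, 2L))
  h0 <- stats::runif(n, 0.005, 0.02)
  amp0 <- local({
    traj <- dde_integrate(params, NULL, history = function(s) h0,
                          t_end = t_end)
    vapply(seq_len(n), function(j)
      find_limit_cycle(traj, transient, osc = j)$amplitude, 0)
  })
  run <- function(eps) {
    cm <- coupling_matrix(n, eps_u = eps / n)
    traj <- dde_integrate(params, cm, history = function(s) h0,
                          t_end = t_end)
    amp <- vapply(seq_len(n), function(j)
      find_limit_cycle(traj, transient, osc = j)$amplitude, 0)
    c(mean(amp < 1e-3 * amp0), mean(amp))
  }
  res <- t(vapply(eps_values, run, numeric(2)))
  data.frame(eps = eps_values, dead_fraction = res[, 1],
             mean_amplitude = res[, 2])
}
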