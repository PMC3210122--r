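#' Phase response curve by the direct (impulse) method
#'
#' Measures the phase sensitivity function \eqn{Z(\theta)} of a converged
#' limit cycle by applying a small impulse to the current value of one state
#' component (the history segment is left untouched), integrating until the
#' orbit has relaxed back to the cycle, and reading the asymptotic phase
#' shift off the displacement of the upward \eqn{u = 0} crossing times
#' relative to an identically seeded unperturbed run. A positive `Z` is a
#' phase advance. `Z = shift / impulse`, i.e. the result is normalized per
#' unit impulse and valid in the linear-response regime (halving the
#' impulse should leave it unchanged).
#'
#' Note on components: an impulse in `v` is what a delta force in the
#' second-order equation produces, so `component = "v"` is the sensitivity
#' relevant to the diffusive coupling used in this package (the coupling
#' drive enters \eqn{\ddot u}).
#'
#' @param params the oscillator's [model_params()].
#' @param cycle its converged `limit_cycle` (from [settle_cycle()] or
#'   [find_limit_cycle()]); must not be quiescent.
#' @param impulse impulse amplitude; default `1e-3` times the cycle
#'   amplitude (scaled by the angular frequency for `component = "v"`).
#' @param n_phase number of phases probed.
#' @param component `"u"` or `"v"`.
#' @param relax_periods number of periods allowed for relaxation before the
#'   asymptotic shift is read (over the final 5 crossings).
#' @param dt optional integrator step.
#' @return An object of class `prc`: `theta`, `Z`, `component`, `impulse`,
#'   `relax_periods`, `meta`.
#' @export
prc_direct <- function(params, cycle, impulse = NULL, n_phase = 64L,
                       component = c("v", "u"), relax_periods = 30L,
                       dt = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(cycle, "limit_cycle"))
  if (cycle$quiescent) stop("cycle is quiescent; no PRC is defined")
  component <- match.arg(component)
  T0 <- cycle$period
  if (is.null(impulse))
    impulse <- 1e-3 * cycle$amplitude *
      (if (component == "v") 2 * pi / T0 else 1)
  t_run <- (relax_periods + 6) * T0
  comp_row <- if (component == "u") "u" else "v"
  if (is.null(dt)) dt <- cycle$traj$dt
  m_run <- as.integer(round(params$delay / dt))
  th <- seq(0, 2 * pi, length.out = n_phase + 1L)[seq_len(n_phase)]
  Z <- numeric(n_phase)
  for (k in seq_len(n_phase)) {
    h0 <- cycle_history(cycle, th[k], m = m_run)
    hp <- h0
    last <- nrow(hp[[comp_row]])
    hp[[comp_row]][last, 1] <- hp[[comp_row]][last, 1] + impulse
    tr0 <- dde_integrate(params, history = h0, t_end = t_run, dt = dt)
    tr1 <- dde_integrate(params, history = hp, t_end = t_run, dt = dt)
    c0 <- upward_crossings(tr0, after = t_run - 6.5 * T0)
    c1 <- upward_crossings(tr1, after = t_run - 6.5 * T0)
    if (length(c1) < 3L)
      stop("basin-escape: perturbed orbit stopped crossing the phase ",
           "origin at theta = ", signif(th[k], 4))
    nc <- min(length(c0), length(c1), 5L)
    d <- utils::tail(c0, nc) - utils::tail(c1, nc)
    Z[k] <- 2 * pi * mean(d) / T0 / impulse
  }
  structure(list(theta = th, Z = Z, component = component,
                 impulse = impulse, relax_periods = relax_periods,
                 meta = list(method = "direct impulse", period = T0,
                             n_phase = n_phase)),
            class = "prc")
}

#' @export
print.prc <- function(x, ...) {
  cat(sprintf("<prc> component %s, %d phases, max |Z| = %.4g (%s)\n",
              x$component, length(x$theta), max(abs(x$Z)),
              x$meta$method))
  invisible(x)
}

# periodic cubic interpolant on a uniform [0, 2pi) grid
periodic_fun <- function(x, y) {
  stats::splinefun(c(x, 2 * pi), c(y, y[1]), method = "periodic")
}

#' Phase coupling function by convolution
#'
#' Computes the phase coupling function of the diffusive coupling channel
#' from a measured phase sensitivity and the cycle waveform,
#' \deqn{\Gamma(\varphi) = \frac{1}{2\pi}\int_0^{2\pi} Z(\theta)\,
#'   \left[s(\theta + \varphi) - s(\theta)\right] d\theta,}
#' per unit coupling intensity, where \eqn{s} is the coupled signal:
#' \eqn{\gamma^2 u(\theta)} for the `u` channel and
#' \eqn{\gamma\, v(\theta)} for the `v` channel (matching how the coupling
#' drive enters \eqn{\ddot u}). `prc` must therefore hold the sensitivity
#' to `v`-impulses. The integral is evaluated by the trapezoidal rule on
#' the common uniform grid (spectrally accurate for smooth periodic
#' integrands); the cycle samples are resampled onto the PRC grid with a
#' periodic spline when the grids differ (with a warning).
#'
#' The antisymmetric part is returned with the orientation used by
#' [locking_analysis()]: \eqn{\Gamma_a(\varphi) = \Gamma(-\varphi) -
#' \Gamma(\varphi)}, so that the phase difference
#' \eqn{\varphi = \theta_{\rm partner} - \theta_{\rm self}} obeys
#' \eqn{\dot\varphi = \Delta\omega + \epsilon\,\Gamma_a(\varphi)} for a
#' symmetrically coupled pair.
#'
#' @param prc a `prc` with `component = "v"`.
#' @param cycle the matching `limit_cycle`.
#' @param channel `"u"` or `"v"`.
#' @param gamma_rate damping rate used for the channel scaling; defaults
#'   to the one stored in the cycle's trajectory.
#' @return An object of class `coupling_function`: `phi`, `gamma`,
#'   `gamma_a`, `channel`, `meta`.
#' @export
gamma_convolution <- function(prc, cycle, channel = c("u", "v"),
                              gamma_rate = NULL) {
  stopifnot(inherits(prc, "prc"), inherits(cycle, "limit_cycle"))
  channel <- match.arg(channel)
  if (prc$component != "v")
    stop("the convolution needs the sensitivity to 'v' impulses ",
         "(the coupling drive enters the second-order equation); ",
         "got a '", prc$component, "'-component PRC")
  if (is.null(gamma_rate)) gamma_rate <- cycle$traj$params[[1]]$damping
  th <- prc$theta; n <- length(th)
  sig_raw <- if (channel == "u") cycle$samples$u else cycle$samples$v
  scale <- if (channel == "u") gamma_rate^2 else gamma_rate
  if (nrow(cycle$samples) != n ||
      max(abs(cycle$samples$theta - th)) > 1e-9) {
    warning("PRC and cycle grids differ; resampling the waveform")
    f <- periodic_fun(cycle$samples$theta, sig_raw)
    sig <- f(th)
  } else sig <- sig_raw
  sig <- scale * sig
  # Gamma(phi_k) = mean_j Z_j (sig_{j+k} - sig_j) on the circular grid
  gam <- vapply(seq_len(n) - 1L, function(k) {
    mean(prc$Z * (sig[((seq_len(n) - 1L + k) %% n) + 1L] - sig))
  }, 0)
  gam_m <- gam[c(1L, n:2L)]          # Gamma(-phi) by index reversal
  structure(list(phi = th, gamma = gam, gamma_a = gam_m - gam,
                 channel = channel,
                 meta = list(method = "trapezoid convolution",
                             gamma_rate = gamma_rate,
                             prc_meta = prc$meta)),
            class = "coupling_function")
}

#' @export
print.coupling_function <- function(x, ...) {
  cat(sprintf("<coupling_function> channel %s, %d phases, max |Gamma_a| = %.4g\n",
              x$channel, length(x$phi), max(abs(x$gamma_a))))
  invisible(x)
}

#' Fixed points and basins of the phase-difference equation
#'
#' Analyzes the one-dimensional flow of the phase difference
#' \eqn{\dot\varphi = \Delta\omega + \epsilon\,\Gamma_a(\varphi)} for a
#' symmetrically coupled pair. Roots are bracketed by sign changes of a
#' periodic spline of the right-hand side on a fine grid and polished by
#' bisection; a root is stable iff the slope of the flow is negative
#' there. Stable and unstable points alternate around the circle, and the
#' unstable points are exactly the basin boundaries of the stable ones.
#'
#' @param gma a `coupling_function` (its `gamma_a` is used), or a function
#'   of \eqn{\varphi}.
#' @param delta_omega frequency mismatch \eqn{\Delta\omega} (rad/s).
#' @param eps coupling strength (> 0).
#' @param n_grid scan resolution.
#' @return An object of class `locking_diagram`: `fixed_points`
#'   (data.frame `phi`, `stable`), `drifting` flag, `basin_of(phi)`
#'   (function mapping initial phase differences to the index of the
#'   attracting stable point in `fixed_points`), `delta_omega`, `eps`.
#' @export
locking_analysis <- function(gma, delta_omega, eps, n_grid = 4096L) {
  stopifnot(eps > 0)
  ga <- if (is.function(gma)) gma else periodic_fun(gma$phi, gma$gamma_a)
  f <- function(phi) delta_omega + eps * ga(phi %% (2 * pi))
  xg <- seq(0, 2 * pi, length.out = n_grid + 1L)
  fv <- f(xg)
  sc <- which(fv[-1] * fv[-length(fv)] < 0)
  roots <- vapply(sc, function(i)
    stats::uniroot(f, c(xg[i], xg[i + 1L]), tol = 1e-12)$root, 0)
  roots <- c(roots, xg[which(fv == 0)])    # exact grid hits (rare)
  roots <- sort(unique(roots %% (2 * pi)))
  if (length(roots) == 0L) {
    return(structure(list(fixed_points = data.frame(phi = numeric(0),
                                                    stable = logical(0)),
                          drifting = TRUE, basin_of = NULL,
                          delta_omega = delta_omega, eps = eps),
                     class = "locking_diagram"))
  }
  h <- 1e-6
  stable <- vapply(roots, function(r) (f(r + h) - f(r - h)) < 0, TRUE)
  fp <- data.frame(phi = roots, stable = stable)
  stable_idx <- which(fp$stable)
  basin_of <- function(phi0) {
    vapply(phi0 %% (2 * pi), function(x) {
      for (iter in 1:200) {
        d <- fp$phi - x
        if (any(abs(d) < 1e-9 | abs(abs(d) - 2 * pi) < 1e-9)) {
          j <- which.min(pmin(abs(d), abs(abs(d) - 2 * pi)))
          if (fp$stable[j]) return(match(j, stable_idx))
          # sitting on an unstable point: undefined, return NA
          return(NA_integer_)
        }
        # follow the flow to the next fixed point in the flow direction
        dir <- sign(f(x))
        cand <- if (dir > 0) fp$phi[fp$phi > x + 1e-12] else
          rev(fp$phi[fp$phi < x - 1e-12])
        nxt <- if (length(cand)) cand[1] else
          if (dir > 0) fp$phi[1] + 2 * pi else fp$phi[nrow(fp)] - 2 * pi
        x <- nxt %% (2 * pi)
      }
      NA_integer_
    }, 0L)
  }
  structure(list(fixed_points = fp, drifting = FALSE, basin_of = basin_of,
                 delta_omega = delta_omega, eps = eps),
            class = "locking_diagram")
}

#' @export
print.locking_diagram <- function(x, ...) {
  if (x$drifting) {
    cat("<locking_diagram> drifting (no fixed points) at eps =", x$eps, "\n")
  } else {
    ns <- sum(x$fixed_points$stable)
    cat(sprintf("<locking_diagram> %d fixed points (%d stable) at eps = %g, delta_omega = %g\n",
                nrow(x$fixed_points), ns, x$eps, x$delta_omega))
  }
  invisible(x)
}

#' Critical coupling strength for phase locking
#'
#' For the phase-difference flow \eqn{\dot\varphi = \Delta\omega +
#' \epsilon\,\Gamma_a(\varphi)}, locking first becomes possible when
#' \eqn{\epsilon\,\max_\varphi(\mp\Gamma_a)} reaches \eqn{|\Delta\omega|},
#' so the critical coupling is linear in the mismatch:
#' \eqn{\epsilon_c = |\Delta\omega| / \max_\varphi(\mp\Gamma_a)} with the
#' sign chosen so that a root exists for \eqn{\epsilon \ge \epsilon_c}.
#'
#' @param gma a `coupling_function` or a function of \eqn{\varphi}.
#' @param delta_omega frequency mismatch (rad/s).
#' @param n_grid evaluation grid.
#' @return `eps_c` (0 when `delta_omega` is 0).
#' @export
critical_coupling <- function(gma, delta_omega, n_grid = 4096L) {
  ga <- if (is.function(gma)) gma else periodic_fun(gma$phi, gma$gamma_a)
  xg <- seq(0, 2 * pi, length.out = n_grid + 1L)
  gv <- ga(xg)
  if (max(abs(gv)) < 1e-14)
    stop("no-locking-channel: the antisymmetric coupling function vanishes")
  if (delta_omega == 0) return(0)
  rng <- if (delta_omega > 0) -min(gv) else max(gv)
  if (rng <= 0) return(Inf)
  abs(delta_omega) / rng
}
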