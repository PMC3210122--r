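#' Integrate a delayed oscillator network by the method of steps
#'
#' Fixed-step classical Runge--Kutta (RK4) integration of the coupled
#' second-order delay model (see [model_params()] and [coupling_matrix()]),
#' with the delayed values taken from the stored dense solution. The step
#' size must divide the delay exactly (`dt = delay / m`, integer
#' `m >= 20`), so that the derivative discontinuities that propagate from
#' the start of the integration always fall on grid points; delayed values
#' needed at half steps are evaluated by cubic Hermite interpolation of an
#' already completed step. The scheme is deterministic and shows 4th-order
#' convergence on smooth segments.
#'
#' @param params a [model_params()] or list of them (one per oscillator).
#' @param coupling a [coupling_matrix()] or `NULL`; its dimension sets the
#'   number of oscillators when `params` has length 1.
#' @param history initial history for \eqn{u} on \eqn{[-\tau, 0]}: a scalar
#'   constant (default `0.01`), a function `h(s)` returning per-oscillator
#'   values for `s` in \eqn{[-\tau, 0]}, or a list with matrices `u` and `v`
#'   of dimension `(m + 1) x n` sampled on the uniform history grid (exact
#'   seeding, e.g. from [cycle_history()]).
#' @param t_end end time (s); the trajectory covers \eqn{[-\tau, t_{end}]}.
#' @param dt step size; must equal `delay / m` for integer `m >= 20`.
#'   Default `delay / 40`.
#' @param guard overflow guard: integration aborts with an error when
#'   \eqn{|u|} exceeds this bound.
#' @return A `dde_trajectory` object: list with `times` (length `N`),
#'   matrices `u`, `v` (`N x n`), `dt`, `m`, `params`, `coupling`, `meta`.
#' @examples
#' p <- load_param_sets()[["A"]]
#' traj <- dde_integrate(p, t_end = 2)
#' @export
dde_integrate <- function(params, coupling = NULL, history = 0.01,
                          t_end, dt = NULL, guard = 1e6) {
  n <- if (!is.null(coupling)) coupling$n
       else if (inherits(params, "model_params")) 1L else length(params)
  params <- as_param_list(params, n)
  tau <- params[[1]]$delay; g <- params[[1]]$damping
  if (is.null(dt)) dt <- tau / 40
  m <- tau / dt
  if (abs(m - round(m)) > 1e-8 || round(m) < 20)
    stop("'dt' must equal delay / m for integer m >= 20")
  m <- as.integer(round(m))
  dt <- tau / m
  nsteps <- as.integer(ceiling(t_end / dt - 1e-9))
  if (nsteps < 1L) stop("'t_end' must exceed one step")

  sgrid <- seq(-tau, 0, length.out = m + 1L)
  if (is.list(history)) {
    hu <- history$u; hv <- history$v
    if (!is.matrix(hu)) hu <- matrix(hu, ncol = n)
    if (!is.matrix(hv)) hv <- matrix(hv, ncol = n)
    if (nrow(hu) != m + 1L || nrow(hv) != m + 1L || ncol(hu) != n)
      stop("list history must supply (m + 1) x n matrices 'u' and 'v'")
  } else if (is.function(history)) {
    hu <- t(vapply(sgrid, function(s) rep_len(history(s), n), numeric(n)))
    # v = du/dt on the history by centered differences (one-sided at ends)
    hv <- apply(hu, 2, function(col) {
      d <- numeric(m + 1L)
      d[2:m] <- (col[3:(m + 1L)] - col[1:(m - 1L)]) / (2 * dt)
      d[1] <- (col[2] - col[1]) / dt
      d[m + 1L] <- (col[m + 1L] - col[m]) / dt
      d
    })
    hv <- matrix(hv, ncol = n)
  } else {
    hu <- matrix(as.numeric(history), m + 1L, n)
    hv <- matrix(0, m + 1L, n)
  }

  a <- vapply(params, `[[`, 0, "gain_a")
  b <- vapply(params, `[[`, 0, "gain_b")
  p2 <- vapply(params, `[[`, 0, "nl2")
  p3 <- vapply(params, `[[`, 0, "nl3")
  eu <- if (!is.null(coupling)) coupling$eps_u else NULL
  ev <- if (!is.null(coupling)) coupling$eps_v else NULL
  res <- .dde_steps(hu, hv, g, tau, a, b, p2, p3, eu, ev,
                    m, nsteps, guard)
  if (res$blow_step > 0)
    stop(sprintf("divergence: |u| exceeded %g at t = %g", guard,
                 res$blow_step * dt))
  times <- seq(-tau, by = dt, length.out = m + 1L + nsteps)
  structure(list(times = times, u = res$u, v = res$v, dt = dt, m = m,
                 params = params, coupling = coupling,
                 meta = list(solver = "RK4 method of steps",
                             interpolant = "cubic Hermite",
                             dt = dt, m = m, n = n, guard = guard)),
            class = "dde_trajectory")
}

#' @export
print.dde_trajectory <- function(x, ...) {
  cat("<dde_trajectory>", ncol(x$u), "oscillator(s), t in [",
      x$times[1], ",", x$times[length(x$times)], "], dt =", x$dt, "\n")
  invisible(x)
}

#' Evaluate a trajectory between grid points
#'
#' Dense output by cubic Hermite interpolation on each step, using the
#' stored derivative `v` for `u` (exact at grid points) and linear
#' interpolation of `v` within a step for the derivative component.
#'
#' @param traj a `dde_trajectory`.
#' @param t times inside the stored range.
#' @param osc oscillator index.
#' @return A list with vectors `u` and `v` at the requested times.
#' @export
traj_at <- function(traj, t, osc = 1L) {
  tms <- traj$times
  if (any(t < tms[1] - 1e-12 | t > tms[length(tms)] + 1e-12))
    stop("interpolation outside the stored range")
  dt <- traj$dt
  k <- pmin(pmax(floor((t - tms[1]) / dt) + 1L, 1L), length(tms) - 1L)
  s <- (t - tms[k]) / dt
  u0 <- traj$u[k, osc]; u1 <- traj$u[k + 1L, osc]
  v0 <- traj$v[k, osc]; v1 <- traj$v[k + 1L, osc]
  h00 <- (1 + 2 * s) * (1 - s)^2; h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s); h11 <- s^2 * (s - 1)
  list(u = h00 * u0 + h10 * dt * v0 + h01 * u1 + h11 * dt * v1,
       v = (1 - s) * v0 + s * v1)
}

# refined upward zero-crossing times of u for one oscillator
upward_crossings <- function(traj, osc = 1L, after = -Inf) {
  tms <- traj$times; u <- traj$u[, osc]
  idx <- which(u[-length(u)] <= 0 & u[-1] > 0)
  idx <- idx[tms[idx] >= after]
  vapply(idx, function(k) {
    f <- function(t) traj_at(traj, t, osc)$u
    lo <- tms[k]; hi <- tms[k + 1L]
    if (f(lo) == 0) return(lo)
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }, 0)
}

#' Extract the limit cycle from a settled trajectory
#'
#' Discards the transient, locates the upward zero crossings of \eqn{u}
#' (the phase origin: \eqn{u = 0} with \eqn{\dot u > 0}), and summarizes
#' the attractor. The period is the mean interval between successive
#' crossings; the amplitude is \eqn{\max |u|} after the transient. A run
#' with fewer than 3 crossings or amplitude below `1e-9` is returned as a
#' quiescent result (amplitude death), not an error.
#'
#' @param traj a `dde_trajectory`.
#' @param transient time (s) to discard.
#' @param osc oscillator index.
#' @param n_phase number of uniform phase samples of the cycle to store.
#' @return An object of class `limit_cycle`: `period`, `amplitude`,
#'   `quiescent`, `crossing_times`, `period_cv` (coefficient of variation
#'   of the crossing intervals), `samples` (data.frame `theta`, `u`, `v`),
#'   plus the underlying trajectory window needed to reseed simulations.
#' @export
find_limit_cycle <- function(traj, transient, osc = 1L, n_phase = 128L) {
  tmax <- traj$times[length(traj$times)]
  if (transient >= tmax) stop("'transient' exceeds the trajectory range")
  cross <- upward_crossings(traj, osc, after = transient)
  sel <- traj$times >= transient
  amp <- max(abs(traj$u[sel, osc]))
  if (length(cross) < 3L || amp < 1e-9) {
    return(structure(list(period = NA_real_, amplitude = amp,
                          quiescent = TRUE, crossing_times = cross,
                          period_cv = NA_real_, samples = NULL,
                          traj = traj, osc = osc),
                     class = "limit_cycle"))
  }
  iv <- diff(cross)
  period <- mean(iv)
  cv <- stats::sd(iv) / period
  t0 <- cross[length(cross) - 1L]
  th <- seq(0, 2 * pi, length.out = n_phase + 1L)[seq_len(n_phase)]
  st <- traj_at(traj, t0 + th / (2 * pi) * period, osc)
  structure(list(period = period, amplitude = amp, quiescent = FALSE,
                 crossing_times = cross, period_cv = cv,
                 samples = data.frame(theta = th, u = st$u, v = st$v),
                 t_origin = t0, traj = traj, osc = osc),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  if (x$quiescent)
    cat("<limit_cycle> quiescent (amplitude", format(x$amplitude), ")\n")
  else
    cat(sprintf("<limit_cycle> T = %.6f s (%.3f Hz), amplitude %.5f, period CV %.2e\n",
                x$period, 1 / x$period, x$amplitude, x$period_cv))
  invisible(x)
}

#' Fourier harmonic amplitudes of the cycle waveform
#'
#' Amplitudes \eqn{|c_k|} of the first `k_max` Fourier harmonics of the
#' stored \eqn{u(\theta)} samples; the ratio of the 2nd to the 1st harmonic
#' is the package's measure of waveform anharmonicity (near-sinusoidal
#' cycles near onset have a small ratio, mixed-mode waveforms far from
#' onset a large one).
#'
#' @param cycle a `limit_cycle`.
#' @param k_max number of harmonics.
#' @return Numeric vector of harmonic amplitudes `1..k_max`.
#' @export
cycle_harmonics <- function(cycle, k_max = 5L) {
  if (cycle$quiescent) stop("quiescent result has no waveform")
  u <- cycle$samples$u
  co <- stats::fft(u) / length(u)
  Mod(co[2:(k_max + 1L)]) * 2
}

#' History segment of a converged cycle at a given phase
#'
#' Returns an exact-seeding history (`list(u, v)` matrices on the uniform
#' history grid) describing the oscillator sitting on its limit cycle with
#' phase `theta` at the initial instant. Used to start perturbation
#' experiments on the attractor and to prepare pairs of oscillators with a
#' prescribed initial phase difference.
#'
#' @param cycle a non-quiescent `limit_cycle`.
#' @param theta phase in \eqn{[0, 2\pi)}; `0` is the upward \eqn{u = 0}
#'   crossing.
#' @param m history grid refinement (steps per delay); defaults to the
#'   cycle's own.
#' @return A list with `u`, `v` matrices of dimension `(m + 1) x 1`.
#' @export
cycle_history <- function(cycle, theta = 0, m = NULL) {
  if (cycle$quiescent) stop("cannot seed from a quiescent result")
  traj <- cycle$traj
  tau <- traj$params[[1]]$delay
  if (is.null(m)) m <- traj$m
  t1 <- cycle$t_origin + (theta %% (2 * pi)) / (2 * pi) * cycle$period
  # shift back whole periods until the history window fits the stored data
  while (t1 - tau < traj$times[1] && t1 + cycle$period <= cycle$t_origin)
    t1 <- t1 + cycle$period
  if (t1 - tau < traj$times[1])
    stop("trajectory window too short to extract a history segment")
  s <- seq(t1 - tau, t1, length.out = m + 1L)
  st <- traj_at(traj, s, cycle$osc)
  list(u = matrix(st$u, ncol = 1), v = matrix(st$v, ncol = 1))
}

#' Simulate one oscillator and return its settled cycle
#'
#' Convenience wrapper: integrates a single uncoupled oscillator from the
#' default constant history and extracts the limit cycle.
#'
#' @param params a [model_params()].
#' @param t_end,transient integration horizon and discarded transient (s).
#' @param dt optional step size.
#' @param n_phase phase samples stored on the cycle.
#' @return A `limit_cycle`.
#' @export
settle_cycle <- function(params, t_end = 60, transient = t_end / 2,
                         dt = NULL, n_phase = 128L) {
  traj <- dde_integrate(params, t_end = t_end, dt = dt)
  find_limit_cycle(traj, transient, n_phase = n_phase)
}
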