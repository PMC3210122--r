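#' Characteristic function of the linearized oscillator
#'
#' Linearizing the single-oscillator model about its rest state with the
#' exponential ansatz \eqn{u \propto e^{\lambda t}} gives the transcendental
#' characteristic function
#' \deqn{\Delta(\lambda) = \lambda^2 + 2\gamma\lambda + \gamma^2(1 - a)
#'       - \gamma^2 b\, e^{-\lambda\tau},}
#' whose zeros are the characteristic roots of the delay equation. The delay
#' enters only through the delayed feedback term \eqn{b u(t-\tau)}.
#'
#' @param lam complex (or numeric) value(s) at which to evaluate.
#' @param params a [model_params()] object.
#' @return Complex value(s) of \eqn{\Delta(\lambda)}; zero iff `lam` is a
#'   characteristic root.
#' @export
char_residual <- function(lam, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(!is.finite(Re(lam))) || any(!is.finite(Im(lam))))
    stop("non-finite 'lam'")
  g <- params$damping
  lam^2 + 2 * g * lam + g^2 * (1 - params$gain_a) -
    g^2 * params$gain_b * exp(-lam * params$delay)
}

# derivative of the characteristic function in lambda
char_dlam <- function(lam, params) {
  g <- params$damping
  2 * lam + 2 * g + g^2 * params$gain_b * params$delay *
    exp(-lam * params$delay)
}

#' Locate the Hopf bifurcation of the delayed feedback loop
#'
#' Solves the two real equations \eqn{\mathrm{Re}\,\Delta(i\omega) =
#' \mathrm{Im}\,\Delta(i\omega) = 0} simultaneously for the Hopf frequency
#' \eqn{\omega_c > 0} and the critical feedback gain \eqn{b_c}, holding the
#' second gain \eqn{a} fixed at its value in `params_template`. On the
#' traced (lowest-frequency) branch \eqn{b_c < 0}: the rest state loses
#' stability as the delayed feedback gain \eqn{b} decreases through
#' \eqn{b_c}, i.e. as the negative feedback strengthens. The bifurcation
#' offset used throughout the package is \eqn{\mu = b_c - b \ge 0} on the
#' oscillatory side.
#'
#' The imaginary part of \eqn{\Delta(i\omega) = 0} fixes
#' \eqn{b = -2\omega/(\gamma \sin\omega\tau)}; substituting into the real
#' part leaves a scalar equation in \eqn{\omega} which is bracketed on the
#' first branch \eqn{\omega\tau \in (0, \pi)} and polished by Newton
#' iteration on the full two-variable system to residual `1e-12`.
#' Transversality (\eqn{d\,\mathrm{Re}\lambda / d\mu > 0}) is verified from
#' \eqn{d\lambda/db = \gamma^2 e^{-i\omega\tau} / \Delta'(i\omega)}.
#'
#' @param params_template a [model_params()] object supplying \eqn{\gamma},
#'   \eqn{\tau} and the second gain \eqn{a}; its `gain_b` is ignored.
#' @param omega_bracket optional numeric length-2 interval (rad/s) known to
#'   contain exactly one branch crossing; defaults to the first branch
#'   \eqn{(0, \pi/\tau)}.
#' @return An object of class `hopf_point` with fields `gain_critical`
#'   (\eqn{b_c}), `omega_c`, `residual`, `second_gain` (\eqn{a}),
#'   `dlam_dgain` (complex \eqn{d\lambda/db} at criticality),
#'   `direction` (destabilizing direction of the gain) and
#'   `dlam_dmu = direction * dlam_dgain`.
#' @examples
#' p <- model_params(0.1, 10, gain_a = 0.6, gain_b = 0)
#' hp <- find_hopf(p)
#' Mod(char_residual(1i * hp$omega_c,
#'                   model_params(0.1, 10, 0.6, hp$gain_critical)))
#' @export
find_hopf <- function(params_template, omega_bracket = NULL) {
  p <- params_template
  stopifnot(inherits(p, "model_params"))
  g <- p$damping; tau <- p$delay; a <- p$gain_a
  if (is.null(omega_bracket))
    omega_bracket <- c(1e-8, pi / tau - 1e-8)
  # real part after eliminating b: -w^2 + g^2(1-a) + 2 g w cot(w tau)
  fre <- function(w) -w^2 + g^2 * (1 - a) + 2 * g * w / tan(w * tau)
  ws <- seq(omega_bracket[1], omega_bracket[2], length.out = 512L)
  fv <- fre(ws)
  # ignore sign changes across cot() poles (w tau = k pi): finite jumps only
  ok <- which(diff(sign(fv)) != 0 &
                abs(diff(ws)) * pmax(abs(fv[-1]), abs(fv[-length(fv)])) <
                  1e3 * max(g^2, 1))
  if (length(ok) == 0L)
    stop("root-not-found: no Hopf crossing in the omega bracket [",
         omega_bracket[1], ", ", omega_bracket[2], "]")
  i <- ok[1]
  w <- stats::uniroot(fre, c(ws[i], ws[i + 1]), tol = 1e-14)$root
  b <- -2 * w / (g * sin(w * tau))
  # Newton polish of (w, b) on Re/Im of Delta(i w) = 0
  for (k in 1:8) {
    pk <- model_params(tau, g, a, b, p$nl2, p$nl3)
    f <- char_residual(1i * w, pk)
    J <- matrix(c(Re(1i * char_dlam(1i * w, pk)), Re(-g^2 * exp(-1i * w * tau)),
                  Im(1i * char_dlam(1i * w, pk)), Im(-g^2 * exp(-1i * w * tau))),
                2, 2, byrow = TRUE)
    step <- solve(J, c(Re(f), Im(f)))
    w <- w - step[1]; b <- b - step[2]
    if (max(abs(step)) < 1e-13) break
  }
  pk <- model_params(tau, g, a, b, p$nl2, p$nl3)
  res <- Mod(char_residual(1i * w, pk))
  if (res > 1e-10) stop("root-not-found: Newton polish did not converge")
  dlam_db <- g^2 * exp(-1i * w * tau) / char_dlam(1i * w, pk)
  if (abs(Re(dlam_db)) < 1e-12)
    stop("degenerate-bifurcation: leading root does not cross transversally")
  # destabilizing direction of the control gain: +1 when increasing b
  # destabilizes (positive-feedback branch), -1 otherwise
  direction <- sign(Re(dlam_db))
  structure(list(gain_critical = b, omega_c = w, residual = res,
                 second_gain = a, dlam_dgain = dlam_db,
                 direction = direction,
                 dlam_dmu = direction * dlam_db, params = pk),
            class = "hopf_point")
}

#' @export
print.hopf_point <- function(x, ...) {
  cat(sprintf("<hopf_point> a = %g: b_c = %.6f, omega_c = %.6f rad/s (%.3f Hz), residual %.2e\n",
              x$second_gain, x$gain_critical, x$omega_c,
              x$omega_c / (2 * pi), x$residual))
  invisible(x)
}

#' Trace the Hopf bifurcation curve over the second gain
#'
#' Continues the Hopf point of [find_hopf()] along a sorted grid of values
#' of the cortico-cortical gain \eqn{a}, using each solution's frequency to
#' bracket the next. If continuation fails partway, the points found so far
#' are returned with a warning naming the last good index.
#'
#' @param second_gain_values sorted numeric vector of \eqn{a} values
#'   (length at least 2).
#' @param params_template a [model_params()] supplying \eqn{\gamma,\tau}.
#' @return A `data.frame` with columns `second_gain`, `gain_critical`,
#'   `omega_c`, `residual`, in input order.
#' @export
hopf_curve <- function(second_gain_values, params_template) {
  av <- second_gain_values
  if (length(av) < 2L) stop("need at least 2 second-gain values")
  if (is.unsorted(av) && is.unsorted(rev(av))) stop("values must be sorted")
  p <- params_template
  out <- vector("list", length(av))
  bracket <- NULL
  for (i in seq_along(av)) {
    pi_ <- model_params(p$delay, p$damping, av[i], 0, p$nl2, p$nl3)
    hp <- tryCatch(find_hopf(pi_, bracket), error = function(e) e)
    if (inherits(hp, "error")) {
      warning("continuation lost the branch at index ", i,
              "; returning ", i - 1L, " points (", conditionMessage(hp), ")")
      out <- out[seq_len(i - 1L)]
      break
    }
    out[[i]] <- data.frame(second_gain = av[i],
                           gain_critical = hp$gain_critical,
                           omega_c = hp$omega_c, residual = hp$residual)
    dw <- 0.35 * pi / p$delay
    bracket <- c(max(1e-8, hp$omega_c - dw),
                 min(pi / p$delay - 1e-8, hp$omega_c + dw))
  }
  do.call(rbind, out)
}

#' Leading characteristic roots of the linearized oscillator
#'
#' Finds all characteristic roots with real part above `real_floor` by
#' Newton refinement from a grid of complex seed points covering
#' \eqn{\mathrm{Re}\,\lambda \in [\mathtt{real\_floor}, \gamma]} and
#' \eqn{\mathrm{Im}\,\lambda \in [0, 3\pi/\tau]} (roots come in conjugate
#' pairs, so only the upper half plane is seeded; real roots are kept once).
#' Converged roots are deduplicated to within `1e-8` and sorted by
#' descending real part.
#'
#' @param params a [model_params()] object (with its actual `gain_b`).
#' @param real_floor negative lower bound on the real part of reported
#'   roots.
#' @param n_max maximum number of distinct roots to report.
#' @return An object of class `spectrum_report`: list with `roots` (complex
#'   vector, conjugates included) and `stable` (TRUE iff all found roots
#'   have negative real part).
#' @export
leading_roots <- function(params, real_floor = -50, n_max = 20L) {
  stopifnot(inherits(params, "model_params"), real_floor < 0)
  g <- params$damping; tau <- params$delay
  res <- seq(real_floor, g, length.out = 40L)
  ims <- seq(0, 3 * pi / tau, length.out = 40L)
  found <- complex(0)
  for (re0 in res) for (im0 in ims) {
    lam <- complex(real = re0, imaginary = im0)
    conv <- FALSE
    for (k in 1:60) {
      f <- char_residual(lam, params)
      d <- char_dlam(lam, params)
      if (Mod(d) < 1e-14) break
      step <- f / d
      lam <- lam - step
      if (!is.finite(Re(lam)) || !is.finite(Im(lam))) break
      if (Mod(step) < 1e-13) { conv <- TRUE; break }
    }
    if (!conv || !is.finite(Re(lam))) next
    if (Mod(char_residual(lam, params)) > 1e-10) next
    if (Re(lam) < real_floor - 1e-9) next
    if (Im(lam) < -1e-8) lam <- Conj(lam)
    if (abs(Im(lam)) < 1e-8) lam <- complex(real = Re(lam), imaginary = 0)
    if (!any(Mod(found - lam) < 1e-7)) found <- c(found, lam)
  }
  found <- found[order(-Re(found))]
  if (length(found) > n_max) found <- found[seq_len(n_max)]
  roots <- complex(0)
  for (lam in found)
    roots <- c(roots, if (Im(lam) > 0) c(lam, Conj(lam)) else lam)
  roots <- roots[order(-Re(roots))]
  structure(list(roots = roots, stable = all(Re(roots) < 0)),
            class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat("<spectrum_report>", length(x$roots), "roots;",
      if (x$stable) "stable" else "unstable", "\n")
  if (length(x$roots)) print(utils::head(x$roots, 6))
  invisible(x)
}

#' Place an oscillator at a given offset above the Hopf curve
#'
#' Convenience constructor: returns the parameter set with
#' `gain_b = gain_critical - mu`, i.e. at bifurcation offset \eqn{\mu}
#' beyond the stability boundary (positive \eqn{\mu} is the oscillatory
#' side).
#'
#' @param hopf a `hopf_point` from [find_hopf()].
#' @param mu bifurcation offset \eqn{\mu} along the destabilizing direction
#'   of the control gain (\eqn{b = b_c - \mu} on the negative-feedback
#'   branch, \eqn{b = b_c + \mu} on the positive-feedback branch).
#' @return A [model_params()] object.
#' @export
params_at_offset <- function(hopf, mu) {
  stopifnot(inherits(hopf, "hopf_point"))
  p <- hopf$params
  model_params(p$delay, p$damping, p$gain_a,
               hopf$gain_critical + hopf$direction * mu,
               p$nl2, p$nl3)
}
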