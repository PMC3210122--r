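#' Physical parameters of one delay-induced oscillator
#'
#' One local cortical area is modelled by a second-order delay differential
#' equation for the deviation \eqn{u(t)} of its mean firing rate from rest:
#' \deqn{\ddot u = -2\gamma\dot u - \gamma^2(1 - a)\,u
#'       + \gamma^2\left[b\,u_\tau + p_2 u^2 + p_3 u^3\right],
#'       \qquad u_\tau = u(t-\tau),}
#' where \eqn{\tau} is the cortico-thalamic transmission delay, \eqn{\gamma}
#' the damping rate, \eqn{a} the (instantaneous) cortico-cortical gain, and
#' \eqn{b} the delayed cortico-thalamic feedback gain, which acts as the
#' Hopf control parameter: the rest state \eqn{u \equiv 0} destabilizes when
#' the feedback becomes sufficiently strong (here, when \eqn{b} drops below a
#' negative critical value \eqn{b_c}). The quadratic and cubic coefficients
#' \eqn{p_2, p_3} summarize the curvature of the neuronal firing-rate
#' nonlinearity around the operating point.
#'
#' @param delay transmission delay \eqn{\tau} in seconds; must be positive.
#' @param damping damping rate \eqn{\gamma} in 1/s; must be positive.
#' @param gain_a dimensionless cortico-cortical gain \eqn{a}.
#' @param gain_b dimensionless delayed feedback gain \eqn{b} (control
#'   parameter).
#' @param nl2 coefficient \eqn{p_2} of the quadratic nonlinearity. The
#'   analytic reduction path requires `nl2 = 0`.
#' @param nl3 coefficient \eqn{p_3} of the cubic nonlinearity.
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(delay = 0.1, damping = 10, gain_a = 0.6, gain_b = -2.65)
#' @export
model_params <- function(delay, damping, gain_a, gain_b, nl2 = 0, nl3 = 1) {
  vals <- c(delay = delay, damping = damping, gain_a = gain_a,
            gain_b = gain_b, nl2 = nl2, nl3 = nl3)
  if (any(!is.finite(vals)))
    stop("all model parameters must be finite numbers")
  if (delay <= 0) stop("'delay' must be > 0")
  if (damping <= 0) stop("'damping' must be > 0")
  structure(list(delay = delay, damping = damping, gain_a = gain_a,
                 gain_b = gain_b, nl2 = nl2, nl3 = nl3),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>  tau =", x$delay, "s, gamma =", x$damping, "/s\n")
  cat("  gains: a =", x$gain_a, ", b =", x$gain_b,
      " nonlinearity: p2 =", x$nl2, ", p3 =", x$nl3, "\n")
  invisible(x)
}

as_param_list <- function(params, n = NULL) {
  if (inherits(params, "model_params")) params <- list(params)
  if (!all(vapply(params, inherits, TRUE, "model_params")))
    stop("'params' must be a model_params object or a list of them")
  if (!is.null(n) && length(params) == 1L && n > 1L)
    params <- rep(params, n)
  if (!is.null(n) && length(params) != n)
    stop("need one parameter set per oscillator (", n, "), got ",
         length(params))
  d <- vapply(params, `[[`, 0, "delay")
  g <- vapply(params, `[[`, 0, "damping")
  if (diff(range(d)) > 1e-12 || diff(range(g)) > 1e-12)
    stop("all oscillators must share the same delay and damping rate")
  params
}

#' Diffusive coupling matrices for an oscillator network
#'
#' Oscillators interact pairwise and diffusively: the coupling drive on
#' oscillator \eqn{i} is
#' \deqn{\gamma^2 \sum_j \epsilon^u_{ij}(u_j - u_i)
#'       + \gamma \sum_j \epsilon^v_{ij}(v_j - v_i),}
#' added to the \eqn{\ddot u_i} equation, with \eqn{v = \dot u}. The
#' \eqn{\gamma}-powers make both intensity matrices dimensionless. A
#' diffusive drive vanishes identically on the synchronized manifold.
#'
#' @param n number of oscillators.
#' @param eps_u,eps_v either a scalar (uniform all-to-all intensity placed on
#'   every off-diagonal entry), or an `n` by `n` symmetric nonnegative matrix
#'   with zero diagonal.
#' @return An object of class `coupling_matrix` with fields `n`, `eps_u`,
#'   `eps_v`.
#' @examples
#' coupling_matrix(2, eps_u = 0.05)          # a u-coupled pair
#' coupling_matrix(3, eps_u = 0, eps_v = 0.1)
#' @export
coupling_matrix <- function(n, eps_u = 0, eps_v = 0) {
  expand <- function(e, what) {
    if (is.matrix(e)) {
      if (!all(dim(e) == c(n, n))) stop(what, " must be ", n, " x ", n)
    } else {
      if (length(e) != 1L) stop(what, " must be a scalar or a matrix")
      e <- matrix(e, n, n)
    }
    diag(e) <- 0
    if (any(e < 0)) stop(what, " intensities must be nonnegative")
    if (max(abs(e - t(e))) > 1e-12) stop(what, " must be symmetric")
    e
  }
  structure(list(n = as.integer(n),
                 eps_u = expand(eps_u, "eps_u"),
                 eps_v = expand(eps_v, "eps_v")),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat("<coupling_matrix> n =", x$n,
      " max eps_u =", max(x$eps_u), " max eps_v =", max(x$eps_v), "\n")
  invisible(x)
}

#' Network right-hand side of the delayed oscillator model
#'
#' Evaluates the second derivatives \eqn{\ddot u_i} for every oscillator
#' given the instantaneous states, the delayed values \eqn{u_i(t-\tau)}, and
#' the coupling matrices. This is the reference (R-level) implementation of
#' the vector field that the compiled integrator steps; it is exposed for
#' testing and for building custom integration schemes.
#'
#' @param u,v numeric vectors of current values \eqn{u_i} and
#'   \eqn{v_i = \dot u_i}.
#' @param u_lag numeric vector of delayed values \eqn{u_i(t - \tau)}.
#' @param params a `model_params` object (recycled) or list of them, one per
#'   oscillator.
#' @param coupling a [coupling_matrix()] or `NULL` for uncoupled dynamics.
#' @return Numeric vector of \eqn{\ddot u_i}.
#' @export
network_rhs <- function(u, v, u_lag, params, coupling = NULL) {
  n <- length(u)
  if (length(v) != n || length(u_lag) != n)
    stop("'u', 'v' and 'u_lag' must have equal length")
  if (any(!is.finite(c(u, v, u_lag))))
    stop("non-finite state values")
  params <- as_param_list(params, n)
  g <- params[[1]]$damping
  a <- vapply(params, `[[`, 0, "gain_a")
  b <- vapply(params, `[[`, 0, "gain_b")
  p2 <- vapply(params, `[[`, 0, "nl2")
  p3 <- vapply(params, `[[`, 0, "nl3")
  acc <- -2 * g * v - g^2 * (1 - a) * u +
    g^2 * (b * u_lag + p2 * u^2 + p3 * u^3)
  if (!is.null(coupling)) {
    if (!inherits(coupling, "coupling_matrix")) stop("bad 'coupling'")
    if (coupling$n != n) stop("coupling matrix is for ", coupling$n,
                              " oscillators, state has ", n)
    acc <- acc + g^2 * as.vector(coupling$eps_u %*% u - rowSums(coupling$eps_u) * u) +
      g * as.vector(coupling$eps_v %*% v - rowSums(coupling$eps_v) * v)
  }
  acc
}

#' Load named oscillator parameter sets from a config file
#'
#' Reads a YAML file describing the shared model constants (delay, damping,
#' nonlinearity) and a list of named working points in the \eqn{(a, b)} gain
#' plane. The packaged defaults file defines the three standard working
#' points used throughout the package:
#' \describe{
#'   \item{A}{just above the Hopf curve: small, nearly sinusoidal
#'     oscillations (the reference point for the reduction theories);}
#'   \item{B}{the same distance above the curve as A but at a higher
#'     oscillation frequency (partner of A for amplitude-death studies);}
#'   \item{C}{far above the curve: strongly anharmonic mixed-mode
#'     oscillations (the working point for multimodal phase locking).}
#' }
#'
#' @param path path to a YAML parameter file; defaults to the packaged file.
#' @return Named list of `model_params`, one per labelled set.
#' @examples
#' sets <- load_param_sets()
#' names(sets)
#' @export
load_param_sets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "param_sets.yaml", package = "delayosc",
                        mustWork = TRUE)
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (f in c("delay", "damping", "sets"))
    if (is.null(cfg[[f]])) stop("config error: missing required field '", f, "'")
  nl2 <- if (is.null(cfg$nl2)) 0 else cfg$nl2
  nl3 <- if (is.null(cfg$nl3)) 1 else cfg$nl3
  out <- list()
  for (s in cfg$sets) {
    for (f in c("label", "gain_a", "gain_b"))
      if (is.null(s[[f]])) stop("config error: missing required field '", f,
                                "' in a parameter set")
    out[[s$label]] <- model_params(delay = cfg$delay, damping = cfg$damping,
                                   gain_a = s$gain_a, gain_b = s$gain_b,
                                   nl2 = nl2, nl3 = nl3)
  }
  out
}

#' Write parameter sets to a config file
#'
#' Inverse of [load_param_sets()]; round-trips all values losslessly (YAML
#' scalars are written with full double precision).
#'
#' @param sets named list of `model_params`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_param_sets <- function(sets, path) {
  sets <- as_param_list(sets, length(sets))
  cfg <- list(delay = sets[[1]]$delay, damping = sets[[1]]$damping,
              nl2 = sets[[1]]$nl2, nl3 = sets[[1]]$nl3,
              sets = unname(Map(function(lab, p)
                list(label = lab, gain_a = p$gain_a, gain_b = p$gain_b),
                names(sets), sets)))
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}
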