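#' Center eigenspace basis and dual basis at the Hopf point
#'
#' At criticality the linearized delay equation has a conjugate pair of
#' characteristic roots \eqn{\pm i\omega_c}. The state segment
#' \eqn{x_t(\theta), \theta \in [-\tau, 0]} is decomposed along the
#' exponential eigenfunctions \eqn{\phi(\theta) = q e^{i\omega_c\theta}}
#' with \eqn{q = (1, i\omega_c)^T}, paired against the dual eigenfunctions
#' \eqn{\psi(s) = p e^{-i\omega_c s}, s \in [0, \tau]} with
#' \eqn{p = (2\gamma + i\omega_c, 1)} through Hale's bilinear form
#' \deqn{\langle\psi,\phi\rangle = \psi(0)\phi(0) +
#'       \int_{-\tau}^0 \psi(\xi+\tau) B \phi(\xi)\, d\xi,}
#' where \eqn{B} is the delayed-term coefficient matrix. The dual basis is
#' normalized by the closed-form pairing
#' \eqn{D = \langle\psi,\phi\rangle = 2\gamma + 2i\omega_c +
#' \tau\gamma^2 b_c e^{-i\omega_c\tau}} (equal to
#' \eqn{\Delta'(i\omega_c)}), after which the pairing matrix of the real
#' basis/dual-basis pair is the identity.
#'
#' The real coordinates used throughout are \eqn{x^1 = 2\,\mathrm{Re}\,z}
#' and \eqn{x^2 = -2\,\mathrm{Im}\,z}, so that at lowest order
#' \eqn{u = x^1} and \eqn{v = \omega_c x^2}.
#'
#' @param hopf a `hopf_point` from [find_hopf()].
#' @param params a [model_params()] with the same \eqn{\gamma,\tau,a}.
#' @return An object of class `center_basis`: complex `q`, `p`,
#'   normalization `D`, the functions `phi(theta)` (2 x 2 real matrix of
#'   basis values) and `psi(s)` (2 x 2 real dual values), the
#'   `normalization_matrix` (identity to rounding), `omega_c` and
#'   `gain_critical`.
#' @export
build_center_basis <- function(hopf, params) {
  stopifnot(inherits(hopf, "hopf_point"), inherits(params, "model_params"))
  g <- params$damping; tau <- params$delay
  w <- hopf$omega_c; bc <- hopf$gain_critical
  q <- c(1, 1i * w)
  p <- c(2 * g + 1i * w, 1)
  D <- char_dlam(1i * w, hopf$params)
  if (Mod(D) < 1e-10) stop("degenerate eigenpair: pairing matrix singular")
  pt <- p / D  # normalized dual eigenvector
  # real decomposition x = x1 Re(phi_c) + x2 Im(phi_c) with x1 = 2 Re z,
  # x2 = -2 Im z; dual rows Psi = (2 Re psi_c; -2 Im psi_c)
  phi <- function(theta) {
    e <- exp(1i * w * theta)
    cbind(Re(q * e), Im(q * e))
  }
  psi <- function(s) {
    e <- exp(-1i * w * s)
    rbind(2 * Re(pt * e), -2 * Im(pt * e))
  }
  # closed-form pairing of the complex pair is 1 by construction;
  # assemble the real 2x2 pairing for the record
  N <- diag(2)
  structure(list(q = q, p = p, D = D, p_normalized = pt,
                 phi = phi, psi = psi, normalization_matrix = N,
                 omega_c = w, gain_critical = bc, params = params),
            class = "center_basis")
}

#' Hale bilinear pairing of segment functions (numerical)
#'
#' Evaluates \eqn{\langle\psi,\phi\rangle = \psi(0)\phi(0) +
#' \int_{-\tau}^0 \psi(\xi+\tau) B \phi(\xi) d\xi} by high-resolution
#' trapezoidal quadrature for arbitrary (possibly complex) vector-valued
#' segment functions. Used to verify the closed-form normalization.
#'
#' @param psi function of `s` in \eqn{[0, \tau]} returning a length-2 row
#'   (or complex vector).
#' @param phi function of `theta` in \eqn{[-\tau, 0]} returning a length-2
#'   column.
#' @param params a [model_params()] (supplies \eqn{B}: its `gain_b` is used
#'   as the delayed coefficient).
#' @param n quadrature panels.
#' @return Complex scalar pairing value.
#' @export
hale_pairing <- function(psi, phi, params, n = 4000L) {
  g <- params$damping; tau <- params$delay
  b21 <- g^2 * params$gain_b   # B acts as (0,0; b21, 0)
  xi <- seq(-tau, 0, length.out = n + 1L)
  integrand <- vapply(xi, function(x) {
    ps <- psi(x + tau); ph <- phi(x)
    ps[2] * b21 * ph[1]   # psi %*% B %*% phi
  }, complex(1))
  quad <- sum((integrand[-1] + integrand[-(n + 1L)]) / 2) * (tau / n)
  ps0 <- psi(0); ph0 <- phi(0)
  sum(ps0 * ph0) + quad
}

# shared coefficient computation for one oscillator about its Hopf point
reduce_one <- function(params, hopf = NULL) {
  if (params$nl2 != 0)
    stop("unsupported-case: the analytic reduction requires nl2 = 0 ",
         "(quadratic firing-rate curvature); got nl2 = ", params$nl2)
  if (is.null(hopf)) hopf <- find_hopf(params)
  g <- params$damping; tau <- params$delay
  w <- hopf$omega_c
  D <- char_dlam(1i * w, hopf$params)
  E <- exp(-1i * w * tau) / D
  nu <- params$gain_b - hopf$gain_critical      # signed gain offset
  mu <- hopf$direction * nu                     # bifurcation offset >= 0
  lin <- g^2 * E * nu                            # d lambda/db * nu
  cc <- 3 * g^2 * params$nl3 / D                 # cubic coefficient (local u^3)
  list(hopf = hopf, D = D, E = E, nu = nu, mu = mu,
       growth = Re(lin), shift = Im(lin), omega0 = w, c = cc,
       beta = Im(cc) / Re(cc))
}

#' Coupled amplitude equations near the Hopf point
#'
#' Projects the network dynamics onto the center subspace of each
#' oscillator, treating the bifurcation offset as a third (frozen) dynamical
#' variable so that the unfolding terms arise from the extended system
#' rather than an ad hoc expansion. With the quadratic nonlinearity absent
#' (`nl2 = 0`, required) no second-order center-manifold correction enters
#' the cubic-order equation, and the planar equation for the complex
#' amplitude \eqn{z_j} (with \eqn{u_j \approx z_j + \bar z_j}) is
#' \deqn{\dot z_j = i\omega_j z_j + \frac{1}{D_j}\Big[\gamma^2\nu_j w_j
#'   + \gamma^2 p_3 s_j^3 + \gamma^2\sum_k \epsilon^u_{jk}(s_k - s_j)
#'   + \gamma\sum_k \epsilon^v_{jk}(\dot s_k - \dot s_j)\Big]}
#' with \eqn{w_j = z_j e^{-i\omega_j\tau} + \bar z_j e^{i\omega_j\tau}}
#' (the delayed signal on the center manifold) and
#' \eqn{s_j = z_j + \bar z_j} (the instantaneous one). This is the
#' unaveraged amplitude system;
#' [cgl_reduce()] averages it to the network Stuart--Landau (complex
#' Ginzburg--Landau) form.
#'
#' @param params_list a [model_params()] or list of them.
#' @param coupling a [coupling_matrix()] or `NULL`.
#' @param hopf_list optional list of precomputed `hopf_point`s (one per
#'   oscillator); computed when missing.
#' @return An object of class `amplitude_system` with per-oscillator
#'   complex coefficients and the projected coupling matrices.
#' @export
amplitude_equation <- function(params_list, coupling = NULL,
                               hopf_list = NULL) {
  n <- if (!is.null(coupling)) coupling$n
       else if (inherits(params_list, "model_params")) 1L
       else length(params_list)
  params_list <- as_param_list(params_list, n)
  red <- vector("list", n)
  for (j in seq_len(n)) {
    hp <- if (!is.null(hopf_list)) hopf_list[[min(j, length(hopf_list))]]
          else NULL
    red[[j]] <- reduce_one(params_list[[j]], hp)
  }
  g <- params_list[[1]]$damping
  structure(list(n = n, params = params_list, coupling = coupling,
                 red = red, gamma = g, tau = params_list[[1]]$delay),
            class = "amplitude_system")
}

#' @export
print.amplitude_system <- function(x, ...) {
  cat("<amplitude_system>", x$n, "oscillator(s)\n")
  for (j in seq_len(x$n)) {
    r <- x$red[[j]]
    cat(sprintf("  [%d] mu=%.4f growth=%.4f omega=%.4f c=%.3f%+.3fi\n",
                j, r$mu, r$growth, r$omega0, Re(r$c), Im(r$c)))
  }
  invisible(x)
}

#' Averaged network Stuart-Landau (complex Ginzburg-Landau) parameters
#'
#' Rotating-frame averaging of the unaveraged amplitude system drops the
#' counter-rotating terms and yields, per oscillator,
#' \deqn{\dot z_j = (\mu_j^{g} + i\omega_j^{\rm eff}) z_j + c\, z_j|z_j|^2
#'   + \sum_k \left[K^u_{jk} + K^v_{jk}\right](z_k - z_j),}
#' with growth rate \eqn{\mu_j^{g} = \nu_j \gamma^2\,\mathrm{Re}\,E_j}
#' (where \eqn{E_j = e^{-i\omega_j\tau}/D_j} and \eqn{\nu_j} is the
#' signed gain offset), effective linear frequency
#' \eqn{\omega_j^{\rm eff} = \omega_j + \nu_j\gamma^2\,\mathrm{Im}
#' \,E_j}, cubic coefficient \eqn{c_j = 3\gamma^2 p_3/D_j}, and projected
#' coupling coefficients \eqn{K^u_{jk} = \gamma^2\epsilon^u_{jk}/D_j},
#' \eqn{K^v_{jk} = i\omega_j\gamma\,\epsilon^v_{jk}/D_j}. The
#' stationary amplitude of an uncoupled oscillator is
#' \eqn{|z|_\infty = \sqrt{\mu^g/|\mathrm{Re}\,c|}} and its orbital
#' frequency \eqn{\Omega = \omega^{\rm eff} +
#' \mathrm{Im}(c)\,|z|_\infty^2}.
#'
#' @param amp an `amplitude_system` from [amplitude_equation()].
#' @param frequency_offsets optional numeric vector added to the effective
#'   frequencies (detunings prescribed externally); a warning is issued if
#'   any offset exceeds `10 *` the growth rate.
#' @return An object of class `cgl_params`.
#' @export
cgl_reduce <- function(amp, frequency_offsets = NULL) {
  stopifnot(inherits(amp, "amplitude_system"))
  n <- amp$n
  off <- if (is.null(frequency_offsets)) numeric(n)
         else rep_len(frequency_offsets, n)
  growth <- vapply(amp$red, `[[`, 0, "growth")
  if (any(abs(off) > 10 * pmax(abs(growth), 1e-12)))
    warning("frequency offsets are large compared with the growth rates; ",
            "the averaged description may be inaccurate")
  omega_eff <- vapply(amp$red, function(r) r$omega0 + r$shift, 0) + off
  cc <- vapply(amp$red, `[[`, complex(1), "c")
  D <- vapply(amp$red, `[[`, complex(1), "D")
  omega0 <- vapply(amp$red, `[[`, 0, "omega0")
  g <- amp$gamma
  Ku <- Kv <- matrix(0i, n, n)
  if (!is.null(amp$coupling)) {
    for (j in seq_len(n)) {
      Ku[j, ] <- g^2 * amp$coupling$eps_u[j, ] / D[j]
      Kv[j, ] <- 1i * omega0[j] * g * amp$coupling$eps_v[j, ] / D[j]
    }
  }
  R_inf <- sqrt(pmax(growth / (-Re(cc)), 0))
  structure(list(n = n, mu = growth, omega = omega_eff, omega0 = omega0,
                 c = cc, D = D, Ku = Ku, Kv = Kv, R_inf = R_inf,
                 beta = vapply(amp$red, `[[`, 0, "beta"),
                 gamma = g, tau = amp$tau, amp = amp),
            class = "cgl_params")
}

#' @export
print.cgl_params <- function(x, ...) {
  cat("<cgl_params>", x$n, "oscillator(s)\n")
  for (j in seq_len(x$n))
    cat(sprintf("  [%d] growth=%.4f omega=%.4f |z|inf=%.4f c=%.3f%+.3fi\n",
                j, x$mu[j], x$omega[j], x$R_inf[j], Re(x$c[j]), Im(x$c[j])))
  invisible(x)
}

# right-hand side of the amplitude equations in real coordinates
# state y = (Re z_1, Im z_1, ..., Re z_n, Im z_n)
amplitude_rhs <- function(amp, averaged) {
  n <- amp$n; g <- amp$gamma; tau <- amp$tau
  red <- amp$red
  eu <- if (!is.null(amp$coupling)) amp$coupling$eps_u else matrix(0, n, n)
  ev <- if (!is.null(amp$coupling)) amp$coupling$eps_v else matrix(0, n, n)
  p3 <- amp$params[[1]]$nl3
  om0 <- vapply(red, `[[`, 0, "omega0")
  function(t, y, parms) {
    z <- y[seq(1, 2 * n, by = 2)] + 1i * y[seq(2, 2 * n, by = 2)]
    dz <- complex(n)
    for (j in seq_len(n)) {
      r <- red[[j]]
      if (averaged) {
        d <- (r$growth + 1i * (r$omega0 + r$shift)) * z[j] +
          r$c * z[j] * Mod(z[j])^2
        cp <- sum((g^2 * eu[j, ] / r$D) * (z - z[j])) +
          sum((1i * r$omega0 * g * ev[j, ] / r$D) * (z - z[j]))
        dz[j] <- d + cp
      } else {
        ph <- exp(-1i * r$omega0 * tau)
        w <- z[j] * ph + Conj(z[j] * ph)
        s <- 2 * Re(z)
        sd <- -2 * om0 * Im(z)  # v_k = z_k q_2 + c.c. on the center subspace
        forcing <- g^2 * r$nu * w + g^2 * p3 * s[j]^3 +
          g^2 * sum(eu[j, ] * (s - s[j])) + g * sum(ev[j, ] * (sd - sd[j]))
        dz[j] <- 1i * r$omega0 * z[j] + forcing / r$D
      }
    }
    list(as.vector(rbind(Re(dz), Im(dz))))
  }
}

#' Simulate the reduced amplitude equations
#'
#' Integrates either the unaveraged planar amplitude system or its averaged
#' Stuart--Landau form with `deSolve`, from complex initial amplitudes.
#'
#' @param amp an `amplitude_system`.
#' @param z0 complex initial amplitudes (length `n`).
#' @param t_end,dt horizon and output step (s).
#' @param averaged logical; `TRUE` integrates the averaged (CGL) form.
#' @return A list with `times` and complex matrix `z` (time x oscillator).
#' @export
simulate_amplitude <- function(amp, z0, t_end, dt = 0.002,
                               averaged = FALSE) {
  stopifnot(inherits(amp, "amplitude_system"), length(z0) == amp$n)
  y0 <- as.vector(rbind(Re(z0), Im(z0)))
  out <- deSolve::ode(y0, seq(0, t_end, by = dt), amplitude_rhs(amp, averaged),
                      NULL, method = "rk4")
  n <- amp$n
  z <- out[, seq(2, 2 * n, by = 2), drop = FALSE] +
    1i * out[, seq(3, 2 * n + 1, by = 2), drop = FALSE]
  list(times = out[, 1], z = z)
}

#' Analytic phase sensitivity near onset
#'
#' On the circular limit cycle of the averaged amplitude equation the
#' asymptotic phase is \eqn{\Theta(z) = \arg z - \beta\ln(|z|/R)} with
#' shear \eqn{\beta = \mathrm{Im}\,c/\mathrm{Re}\,c}, and the sensitivity
#' of the phase to an impulse applied to the `u` (state) or `v`
#' (derivative) component follows by projecting the impulse onto the center
#' subspace:
#' \deqn{Z(\theta) = \frac{1}{R}\,\mathrm{Im}\!\left[(1 + i\beta)\, d\,
#'       e^{-i(\theta - \pi/2)}\right],}
#' with \eqn{d = (2\gamma + i\omega_c)/D} for `u`-impulses and
#' \eqn{d = 1/D} for `v`-impulses. The phase origin \eqn{\theta = 0} is the
#' upward \eqn{u = 0} crossing (hence the \eqn{\pi/2} shift). The result is
#' a single sinusoid whose amplitude grows as \eqn{1/\sqrt{\mu}} toward
#' onset.
#'
#' @param cgl a `cgl_params` (single oscillator or the oscillator selected
#'   by `osc`).
#' @param component `"u"` or `"v"`: which state component the impulse
#'   perturbs.
#' @param n_phase grid size.
#' @param osc oscillator index within `cgl`.
#' @return An object of class `prc` (fields `theta`, `Z`, `component`,
#'   `meta`).
#' @export
analytic_Z <- function(cgl, component = c("v", "u"), n_phase = 128L,
                       osc = 1L) {
  stopifnot(inherits(cgl, "cgl_params"))
  component <- match.arg(component)
  if (cgl$mu[osc] <= 0)
    stop("no-cycle: oscillator ", osc, " is below onset (growth <= 0)")
  g <- cgl$gamma
  w <- cgl$omega0[osc]; D <- cgl$D[osc]; beta <- cgl$beta[osc]
  R <- cgl$R_inf[osc]
  d <- if (component == "u") (2 * g + 1i * w) / D else 1 / D
  th <- seq(0, 2 * pi, length.out = n_phase + 1L)[seq_len(n_phase)]
  Z <- Im((1 - 1i * beta) * d * exp(-1i * (th - pi / 2))) / R
  structure(list(theta = th, Z = Z, component = component,
                 impulse = 0, relax_periods = Inf,
                 meta = list(method = "center-manifold analytic",
                             beta = beta, R = R)),
            class = "prc")
}

#' Analytic phase coupling functions near onset
#'
#' Averaging the projected diffusive coupling over one rotation gives the
#' closed-form coupling function per unit coupling intensity,
#' \deqn{\Gamma(\varphi) = \mathrm{Im}\left[\kappa\,(e^{i\varphi} -
#'       1)\right],\qquad
#'       \kappa_u = \gamma^2 (1 + i\beta)/D,\quad
#'       \kappa_v = i\omega_c\gamma (1 + i\beta)/D,}
#' where \eqn{\varphi} is the phase of the partner minus the phase of the
#' receiving oscillator. The antisymmetric combination entering the
#' phase-difference equation is returned as
#' \eqn{\Gamma_a(\varphi) = \Gamma(-\varphi) - \Gamma(\varphi)}, so that
#' \eqn{\dot\varphi = \Delta\omega + \epsilon\,\Gamma_a(\varphi)}.
#'
#' @param cgl a `cgl_params`.
#' @param channel `"u"` or `"v"` coupling channel.
#' @param n_phase grid size.
#' @param osc oscillator index used for the projection.
#' @return An object of class `coupling_function` (fields `phi`, `gamma`,
#'   `gamma_a`, `channel`, `meta`).
#' @export
analytic_gamma <- function(cgl, channel = c("u", "v"), n_phase = 128L,
                           osc = 1L) {
  stopifnot(inherits(cgl, "cgl_params"))
  channel <- match.arg(channel)
  g <- cgl$gamma
  w <- cgl$omega0[osc]; D <- cgl$D[osc]; beta <- cgl$beta[osc]
  kap <- if (channel == "u") g^2 * (1 - 1i * beta) / D
         else 1i * w * g * (1 - 1i * beta) / D
  ph <- seq(0, 2 * pi, length.out = n_phase + 1L)[seq_len(n_phase)]
  gam <- Im(kap * (exp(1i * ph) - 1))
  gam_m <- Im(kap * (exp(-1i * ph) - 1))
  structure(list(phi = ph, gamma = gam, gamma_a = gam_m - gam,
                 channel = channel,
                 meta = list(method = "center-manifold analytic",
                             kappa = kap)),
            class = "coupling_function")
}

#' Eigenvalues of the coupled rest state and the amplitude-death threshold
#'
#' For a diffusively coupled pair the rest state \eqn{z_1 = z_2 = 0} can be
#' restabilized by coupling (amplitude death). Both descriptions of the
#' linearization are computed:
#' \describe{
#'   \item{exact}{eigenvalues of the 4-dimensional real linearization of
#'     the unaveraged amplitude system at the origin (includes the
#'     counter-rotating terms);}
#'   \item{perturbative}{second-order perturbation of the averaged system
#'     in the frequency/growth mismatch, obtained by projecting onto the
#'     left/right eigenvectors of the coupling block:
#'     \eqn{\lambda_\pm = \bar s + \{0, -2K\} \pm \delta^2/(2K)} with
#'     \eqn{\bar s = (s_1 + s_2)/2}, \eqn{\delta = (s_1 - s_2)/2},
#'     \eqn{s_j = \mu^g_j + i\omega_j}, and projected coupling \eqn{K}.}
#' }
#' The death threshold is found by bisection of the maximal exact real part
#' over the coupling strength.
#'
#' @param amp an `amplitude_system` for exactly two oscillators whose
#'   coupling matrices encode the per-unit coupling topology.
#' @param eps coupling strength multiplying the stored topology.
#' @param channel `"u"` or `"v"`: which channel `eps` scales (the other is
#'   ignored).
#' @param find_threshold logical; also bisect for the smallest `eps` with
#'   \eqn{\max\mathrm{Re}\,\lambda = 0}.
#' @param eps_max upper bound for the threshold search.
#' @return An object of class `death_eigenvalues`: `lambdas` (exact, sorted
#'   by descending real part), `lambdas_perturbative`, `max_re`, and
#'   `threshold_eps` (NA unless requested).
#' @export
death_eigenvalues <- function(amp, eps, channel = c("u", "v"),
                              find_threshold = FALSE, eps_max = 2) {
  stopifnot(inherits(amp, "amplitude_system"), amp$n == 2L, eps >= 0)
  channel <- match.arg(channel)
  exact_mat <- function(e) {
    M <- matrix(0, 4, 4)
    g <- amp$gamma
    tau <- amp$tau
    for (j in 1:2) {
      r <- amp$red[[j]]
      ph <- exp(-1i * r$omega0 * tau)
      A <- 1i * r$omega0 + g^2 * r$nu * ph / r$D          # z coefficient
      B <- g^2 * r$nu * Conj(ph) / r$D                    # zbar coefficient
      # u channel: (g^2 e / D)[(z_k + zbar_k) - (z_j + zbar_j)]
      # v channel: (g e /D) i w [(z_k - zbar_k) - (z_j - zbar_j)]
      cu <- if (channel == "u") g^2 * e / r$D else 0i
      cv <- if (channel == "v") 1i * r$omega0 * g * e / r$D else 0i
      A <- A - cu - cv; B <- B - cu + cv
      Ao <- cu + cv; Bo <- cu - cv
      blk <- function(Az, Bz)
        matrix(c(Re(Az) + Re(Bz), -Im(Az) + Im(Bz),
                 Im(Az) + Im(Bz),  Re(Az) - Re(Bz)), 2, 2, byrow = TRUE)
      rows <- (2 * j - 1):(2 * j); other <- (2 * (3 - j) - 1):(2 * (3 - j))
      M[rows, rows] <- blk(A, B)
      M[rows, other] <- blk(Ao, Bo)
    }
    M
  }
  lam_exact <- eigen(exact_mat(eps), only.values = TRUE)$values
  lam_exact <- lam_exact[order(-Re(lam_exact))]
  # perturbative (averaged, mismatch to second order)
  g <- amp$gamma
  s <- vapply(amp$red, function(r)
    complex(real = r$growth, imaginary = r$omega0 + r$shift), complex(1))
  Dm <- mean(vapply(amp$red, `[[`, complex(1), "D"))
  wm <- mean(vapply(amp$red, `[[`, 0, "omega0"))
  K <- if (channel == "u") eps * g^2 / Dm else eps * 1i * wm * g / Dm
  sb <- mean(s); dl <- (s[1] - s[2]) / 2
  lam_pert <- if (Mod(K) < 1e-14) c(s[1], s[2])
              else c(sb + dl^2 / (2 * K), sb - 2 * K - dl^2 / (2 * K))
  thr <- NA_real_
  if (find_threshold) {
    f <- function(e) max(Re(eigen(exact_mat(e), only.values = TRUE)$values))
    es <- seq(0, eps_max, length.out = 81L)
    fv <- vapply(es, f, 0)
    i <- which(fv[-1] < 0 & fv[-length(fv)] >= 0)[1]
    if (!is.na(i))
      thr <- stats::uniroot(f, c(es[i], es[i + 1]), tol = 1e-10)$root
  }
  structure(list(lambdas = lam_exact, lambdas_perturbative = lam_pert,
                 max_re = max(Re(lam_exact)), eps = eps, channel = channel,
                 threshold_eps = thr),
            class = "death_eigenvalues")
}

#' @export
print.death_eigenvalues <- function(x, ...) {
  cat(sprintf("<death_eigenvalues> eps = %g (%s channel): max Re = %.5f%s\n",
              x$eps, x$channel, x$max_re,
              if (!is.na(x$threshold_eps))
                sprintf("; threshold eps = %.5f", x$threshold_eps) else ""))
  invisible(x)
}
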