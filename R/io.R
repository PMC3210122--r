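#' Write a table with a metadata header
#'
#' Writes a data.frame as tab-separated values preceded by `#`-prefixed
#' `key=value` metadata lines. Numeric columns are written at 17
#' significant digits, so `read_table(write_table(x))` round-trips doubles
#' bit-exactly.
#'
#' @param rows a data.frame.
#' @param path output path.
#' @param metadata named list of scalar metadata values.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, metadata = list()) {
  stopifnot(is.data.frame(rows))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata))
    cat(sprintf("# %s=%s\n", k, format(metadata[[k]], digits = 17)),
        file = con)
  cols <- vapply(rows, function(col)
    if (is.double(col)) format(col, digits = 17, trim = TRUE)
    else as.character(col), character(nrow(rows)))
  if (nrow(rows) == 1L) cols <- matrix(cols, nrow = 1L,
                                       dimnames = list(NULL, names(rows)))
  cat(paste(names(rows), collapse = "\t"), "\n", sep = "", file = con)
  if (nrow(rows) > 0L)
    writeLines(apply(cols, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path input path.
#' @return A data.frame with attribute `"metadata"` (named character list).
#' @export
read_table <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  bad <- which(!is_meta & seq_along(lines) < which(!is_meta)[1])
  meta_lines <- lines[is_meta & cumsum(!is_meta) == 0]
  meta <- list()
  for (i in seq_along(meta_lines)) {
    ln <- sub("^#\\s*", "", meta_lines[i])
    if (!grepl("=", ln))
      stop("malformed metadata header at line ", i, ": ", ln)
    k <- sub("=.*", "", ln); v <- sub("^[^=]*=", "", ln)
    meta[[trimws(k)]] <- trimws(v)
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0L) stop("no table body in ", path)
  df <- utils::read.table(text = paste(body, collapse = "\n"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  attr(df, "metadata") <- meta
  df
}

#' Deterministic seed splitting
#'
#' Derives independent child seeds from one master seed so that every
#' stochastic component of an experiment can be seeded explicitly (no
#' hidden global state). Knuth multiplicative hashing, folded into the
#' positive 31-bit integer range.
#'
#' @param seed master seed (integer).
#' @param k child index (integer, or vector of them).
#' @return Integer seed(s) in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, k) {
  x <- (as.double(seed) * 2654435761 + as.double(k) * 40503) %% (2^31 - 3)
  as.integer(x + 1)
}

#' Write a JSON run manifest next to an experiment output
#'
#' Records the configuration echo, the seed, package version and solver
#' settings of a run; written atomically (temp file + rename).
#'
#' @param path output path (`.json`).
#' @param config named list echoed into the manifest.
#' @param seed integer seed used.
#' @param extra optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  man <- c(list(tool = "delayosc",
                version = as.character(utils::packageVersion("delayosc")),
                seed = seed,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                config = config),
           extra)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Test fixtures with closed-form references
#'
#' Builds the reference problems used to validate the numerical machinery:
#' \describe{
#'   \item{`stuart_landau_ode`}{planar normal form
#'     \eqn{\dot z = (\mu + i\omega) z + (c_r + i c_i) z|z|^2} with
#'     closed-form amplitude \eqn{r(t)} and phase; parameters `mu`,
#'     `omega`, `c_re` (< 0), `c_im`, `r0`, `phi0`. The reference solves
#'     the radial equation exactly and includes the closed-form phase
#'     sensitivity on the limit cycle.}
#'   \item{`linear_dde`}{scalar DDE \eqn{u'(t) = c_0 u + c_1 u(t - \tau)}
#'     with constant history; the reference is the exact piecewise
#'     polynomial/exponential solution built by the method of steps
#'     (parameters `c0`, `c1`, `tau`, `u0`, `k` intervals). A matching
#'     RK4 integrator (`$integrate`) exposes the production stepping
#'     scheme on this fixture.}
#'   \item{`sine_signal`}{pure sinusoid sampled trajectory (parameters
#'     `period`, `amplitude`, `t_end`, `dt`) for crossing/period
#'     estimation tests.}
#'   \item{`population_sample`}{reproducible draw of per-oscillator
#'     parameters around working point A (parameters `n`, `a_spread`,
#'     `mu_spread`; requires `seed`).}
#' }
#'
#' @param kind fixture kind (see above).
#' @param params named list of fixture parameters (defaults filled in).
#' @param seed integer seed for stochastic fixtures.
#' @return A list with the generator output and, where applicable, a
#'   `reference` function.
#' @export
make_fixture <- function(kind, params = list(), seed = NULL) {
  kinds <- c("stuart_landau_ode", "linear_dde", "sine_signal",
             "population_sample")
  if (!kind %in% kinds)
    stop("unknown fixture kind '", kind, "'; valid kinds: ",
         paste(kinds, collapse = ", "))
  p <- params
  switch(kind,
    stuart_landau_ode = {
      d <- list(mu = 0.2, omega = 2 * pi, c_re = -1, c_im = 0.5,
                r0 = 0.05, phi0 = 0)
      p <- utils::modifyList(d, p)
      if (p$c_re >= 0) stop("stuart_landau_ode needs c_re < 0")
      Rinf2 <- if (p$mu > 0) p$mu / (-p$c_re) else NA_real_
      reference <- function(t) {
        # radial: dr/dt = mu r + c_re r^3  (Bernoulli, exact solution)
        r2 <- if (p$mu == 0) 1 / (1 / p$r0^2 - 2 * p$c_re * t) else
          p$mu * p$r0^2 * exp(2 * p$mu * t) /
            (p$mu - p$c_re * p$r0^2 * (exp(2 * p$mu * t) - 1))
        r <- sqrt(r2)
        phi <- p$phi0 + p$omega * t - (p$c_im / (2 * p$c_re)) *
          log(1 + (-p$c_re) * p$r0^2 * (exp(2 * p$mu * t) - 1) / p$mu)
        list(r = r, phi = phi, z = r * exp(1i * phi))
      }
      # closed-form phase sensitivity on the cycle: impulse dz applied at
      # phase theta shifts the asymptotic phase by
      # Im[(1 - i beta) dz e^{-i theta}]/R
      Zfun <- function(theta, direction = 1i) {
        beta <- p$c_im / p$c_re
        Im((1 - 1i * beta) * direction * exp(-1i * theta)) / sqrt(Rinf2)
      }
      list(kind = kind, params = p, reference = reference,
           R_inf = sqrt(Rinf2), Omega = p$omega + p$c_im * Rinf2,
           Z = Zfun)
    },
    linear_dde = {
      d <- list(c0 = 0, c1 = -1, tau = 1, u0 = 1, k = 3L)
      p <- utils::modifyList(d, p)
      if (p$c0 != 0) stop("the symbolic reference assumes c0 = 0")
      # u' = c1 u(t - tau), u = u0 on [-tau, 0]: on interval j the exact
      # solution is a degree-j polynomial built by repeated integration
      reference <- function(t) {
        vapply(t, function(tt) {
          if (tt <= 0) return(p$u0)
          j <- ceiling(tt / p$tau - 1e-12)
          if (j > p$k) stop("reference built for ", p$k, " intervals")
          # u(t) = u0 sum_{m=0}^{j} c1^m (t - (m-1) tau)^m / m!
          m <- 0:j
          p$u0 * sum(p$c1^m * pmax(tt - (m - 1) * p$tau, 0)^m /
                       factorial(m))
        }, 0)
      }
      integrate <- function(t_end, m = 40L) {
        hu <- rep(p$u0, m + 1L)
        hdu <- rep(0, m + 1L)
        nsteps <- as.integer(ceiling(t_end / (p$tau / m) - 1e-9))
        out <- .dde_scalar_steps(hu, hdu, p$c0, p$c1, p$tau, m, nsteps)
        list(times = seq(-p$tau, by = p$tau / m,
                         length.out = m + 1L + nsteps),
             u = out$u)
      }
      list(kind = kind, params = p, reference = reference,
           integrate = integrate)
    },
    sine_signal = {
      d <- list(period = 1, amplitude = 1, t_end = 20, dt = 0.005)
      p <- utils::modifyList(d, p)
      times <- seq(0, p$t_end, by = p$dt)
      w <- 2 * pi / p$period
      list(kind = kind, params = p, times = times,
           u = p$amplitude * sin(w * times),
           v = p$amplitude * w * cos(w * times),
           reference = function(t) p$amplitude * sin(w * t))
    },
    population_sample = {
      if (is.null(seed)) stop("population_sample requires a seed")
      d <- list(n = 50L, a_center = 0.6, a_spread = 0.05,
                mu_center = 0.03, mu_spread = 0.01)
      p <- utils::modifyList(d, p)
      set.seed(seed)
      a <- stats::runif(p$n, p$a_center - p$a_spread,
                        p$a_center + p$a_spread)
      mu <- stats::runif(p$n, p$mu_center - p$mu_spread,
                         p$mu_center + p$mu_spread)
      list(kind = kind, params = p, seed = seed, a = a, mu = mu)
    })
}
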