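# Shared, lazily computed objects for the suite. Everything here is
# deterministic (fixed-step integration, fixed grids), so caching across
# test files changes nothing but the wall clock.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

param_A <- function() load_param_sets()[["A"]]
param_B <- function() load_param_sets()[["B"]]
param_C <- function() load_param_sets()[["C"]]

hopf_A <- function() cached("hopf_A", find_hopf(param_A()))
hopf_B <- function() cached("hopf_B", find_hopf(param_B()))

cgl_A <- function() cached("cgl_A",
  cgl_reduce(amplitude_equation(param_A(), hopf_list = list(hopf_A()))))

cycle_A <- function() cached("cycle_A",
  settle_cycle(param_A(), t_end = 300, transient = 250, n_phase = 64L))

prc_A <- function() cached("prc_A",
  prc_direct(param_A(), cycle_A(), n_phase = 64L, relax_periods = 40L))

gamma_A_u <- function() cached("gamma_A_u",
  gamma_convolution(prc_A(), cycle_A(), "u"))

cycle_C <- function() cached("cycle_C",
  settle_cycle(param_C(), t_end = 250, transient = 200, n_phase = 128L))

prc_C <- function() cached("prc_C",
  prc_direct(param_C(), cycle_C(), n_phase = 128L, relax_periods = 30L))

gamma_C_v <- function() cached("gamma_C_v",
  gamma_convolution(prc_C(), cycle_C(), "v"))

nrms <- function(x, ref) sqrt(mean((x - ref)^2)) / stats::sd(ref)
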