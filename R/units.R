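# Single computational unit: a four-population neural mass (pyramidal,
# excitatory, slow-GABA and fast-GABA interneurons) whose internal coupling
# constants select an intrinsic rhythm. Spike densities are bounded sigmoid
# outputs with ceiling 5 spikes/s. Three presets are provided:
#   gamma - intrinsically silent, oscillates ~35-40 Hz when driven
#           (pyramidal <-> fast-GABA loop)
#   theta - autonomous relaxation oscillator ~4 Hz
#           (pyramidal <-> slow-GABA loop, tonic drive)
#   wm    - gamma unit with a pyramidal self-excitation loop (Cpp) giving
#           cue-triggered persistent activity

.unit_par_names <- c("Cpe", "Cep", "Csp", "Cps", "Cfp", "Cfs", "Cpf", "Cff",
                     "Cpp", "Ge", "we", "Gs", "ws", "Gf", "wf", "r", "v0",
                     "tonic_p", "tonic_f")

# Parameter tables for the three presets. Synaptic kernels are second order,
# h(t) = G * w * t * exp(-w t): G in mV, w (reciprocal time constant) in 1/s.
# Couplings C are dimensionless. The values were calibrated once so that the
# emergent rhythms match their nominal bands (see the methods vignette).
.tg_presets <- function() {
  # gamma: silent at rest, ~35 Hz limit cycle when driven; the rhythm lives
  # in the pyramidal <-> fast-GABA loop, the excitatory interneurons act as
  # a burst amplifier and the slow-GABA loop provides ~50 ms refractoriness.
  gamma <- list(
    Cpe = 40, Cep = 80, Csp = 25, Cps = 60, Cfp = 60, Cfs = 0, Cpf = 300,
    Cff = 0, Cpp = 0,
    Ge = 5.17, we = 110, Gs = 4.45, ws = 20, Gf = 24.5, wf = 360,
    r = 0.56, v0 = 6, tonic_p = 0, tonic_f = 0)
  # theta: autonomous 4.00 Hz relaxation oscillation of the pyramidal /
  # slow-GABA loop under tonic drive; no fast-GABA involvement, so scaling
  # the glutamatergic + slow-GABA time constants rescales the limit cycle
  # in time exactly.
  theta <- list(
    Cpe = 40, Cep = 80, Csp = 25, Cps = 40, Cfp = 0, Cfs = 0, Cpf = 0,
    Cff = 0, Cpp = 0,
    Ge = 6.231, we = 132.57, Gs = 5.363, ws = 19.28, Gf = 30, wf = 440,
    r = 0.56, v0 = 6, tonic_p = 270, tonic_f = 0)
  # wm: gamma unit with a pyramidal self-excitation loop and no slow
  # self-inhibition, so a brief cue ignites activity that persists until the
  # self-loop state is reset by a new input.
  wm <- modifyList(gamma, list(Cpp = 80, Cps = 0, Cpf = 40))
  list(gamma = gamma, theta = theta, wm = wm)
}

#' Unit parameter presets
#'
#' Returns the full parameter tables of the three rhythm presets of the
#' four-population neural-mass unit.
#'
#' @return Named list with elements `gamma`, `theta` and `wm`, each a named
#'   list of unit parameters.
#' @export
unit_presets <- function() .tg_presets()

#' Create the parameter set of one neural-mass unit
#'
#' @param preset One of `"gamma"`, `"theta"`, `"wm"`.
#' @param overrides Named list of parameter overrides; names must be existing
#'   unit parameters.
#' @return An object of class `tg_unit_params`: a named list of unit
#'   parameters with attribute `preset`.
#' @examples
#' u <- make_unit("gamma")
#' u$wf
#' @export
make_unit <- function(preset = c("gamma", "theta", "wm"), overrides = list()) {
  if (length(preset) != 1 || !preset %in% c("gamma", "theta", "wm"))
    stop("unknown unit preset: ", paste(preset, collapse = ", "))
  p <- .tg_presets()[[preset]]
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad))
      stop("unknown unit parameter(s) in overrides: ",
           paste(bad, collapse = ", "))
    p <- modifyList(p, overrides)
  }
  stopifnot(all(vapply(p, is.finite, logical(1))),
            p$we > 0, p$ws > 0, p$wf > 0)
  structure(p, class = "tg_unit_params", preset = preset)
}

#' Population rate sigmoid
#'
#' Static nonlinearity converting a membrane potential (mV) into a population
#' spike density, saturating at 5 spikes/s.
#'
#' @param v Membrane potential (mV), any numeric vector.
#' @param r Sigmoid slope (1/mV).
#' @param v0 Half-activation potential (mV).
#' @return Spike density in `[0, 5]` spikes/s.
#' @export
rate_sigmoid <- function(v, r = 0.56, v0 = 6) {
  pmin(pmax(5 / (1 + exp(-r * (v - v0))), 0), 5)
}

.unitpar_row <- function(params) {
  unlist(params[.unit_par_names])
}

#' Simulate one unit in isolation
#'
#' Advances a single unit with fixed-step Euler integration, optionally with
#' constant external drive and per-step zero-mean Gaussian noise on the
#' pyramidal and fast-interneuron inputs.
#'
#' @param params A `tg_unit_params` object from [make_unit()].
#' @param duration Simulated time (s).
#' @param dt Integration step (s).
#' @param u_p,u_f Constant external drive to the pyramidal / fast-GABA
#'   populations (spikes/s-equivalent).
#' @param noise_sd_p,noise_sd_f Per-step noise standard deviations at the
#'   reference step `dt_ref`.
#' @param dt_ref Reference step at which noise magnitudes are defined; the
#'   per-step noise is rescaled by `sqrt(dt_ref/dt)` so spectra do not depend
#'   on `dt`.
#' @param seed Optional RNG seed.
#' @param state Optional 1 x 12 initial kernel state (default all-zero).
#' @param record_pops If `TRUE`, also record the interneuron spike densities.
#' @return A list with `z_p` (pyramidal spike-density trace), `t` (time
#'   vector), `dt`, the final `state`, and if requested `z_e`, `z_s`, `z_f`.
#' @export
simulate_unit <- function(params, duration, dt = 1e-4, u_p = 0, u_f = 0,
                          noise_sd_p = 0, noise_sd_f = 0, dt_ref = 1e-4,
                          seed = NULL, state = NULL, record_pops = FALSE) {
  stopifnot(inherits(params, "tg_unit_params"), duration > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- round(duration / dt)
  ev <- matrix(0, 0, 5)
  if (u_p != 0) ev <- rbind(ev, c(0, 0, 0, n_steps, u_p))
  if (u_f != 0) ev <- rbind(ev, c(0, 1, 0, n_steps, u_f))
  if (is.null(state)) state <- matrix(0, 1, 12)
  out <- .sim_core(matrix(0, 1, 1), matrix(0, 1, 1), matrix(0, 1, 1),
                   matrix(.unitpar_row(params), 1, 19),
                   ev, noise_sd_p, noise_sd_f, 0, 0,
                   integer(0), integer(0),
                   n_steps, dt, dt_ref, state,
                   0L, 1L, record_pops,
                   FALSE, matrix(0, 4, 4), integer(0), integer(0), 0.02, FALSE)
  res <- list(z_p = drop(out$trace_p), t = (seq_len(n_steps) - 1) * dt,
              dt = dt, state = out$state)
  if (record_pops) {
    res$z_e <- drop(out$trace_e)
    res$z_s <- drop(out$trace_s)
    res$z_f <- drop(out$trace_f)
  }
  res
}

#' Dominant oscillation frequency of a trace
#'
#' Frequency of the largest nonzero-frequency spectral peak of the
#' mean-removed trace.
#'
#' @param trace Numeric time series (spikes/s).
#' @param dt Sampling interval (s).
#' @return Frequency in Hz. For an (effectively) constant trace the value is
#'   0 with attribute `constant = TRUE`.
#' @export
dominant_frequency <- function(trace, dt) {
  stopifnot(length(trace) >= 4, dt > 0)
  x <- trace - mean(trace)
  if (max(abs(x)) < 1e-9) return(structure(0, constant = TRUE))
  n <- length(x)
  nf <- floor(n / 2)
  sp <- Mod(fft(x))[seq_len(nf)]
  freqs <- (seq_len(nf) - 1) / (n * dt)
  k <- which.max(sp[-1]) + 1L
  structure(freqs[k], constant = FALSE)
}
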