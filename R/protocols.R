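# Functioning modes. Retrieval: cue -> WM -> L1 under rhythmic theta
# disinhibition, trained weights untouched. Isolation modes disconnect L1
# from WM and feed a positive uniform noise to the L1 pyramidal inputs:
#   imagination    - positive noise, synapses unchanged
#   dreaming       - higher positive noise, all plastic synapses scaled 1/3
#   dreaming_fast_gamma - dreaming with L1/L2 gamma accelerated to ~45 Hz
#   dreaming_no_theta   - dreaming with the oscillating theta drive replaced
#                         by a constant disinhibition (on-phase mean)
#   schizophrenia  - dreaming-level noise, Af halved, other synapses intact

# Positive-uniform noise ranges for the isolation modes (spikes/s-equivalent
# drive on L1 pyramidal inputs). The imagination range was calibrated once as
# a range that spontaneously recalls stored sequences; dreaming is 50% above
# imagination's maximum (see methods vignette).
.tg_mode_noise <- list(
  imagination = c(100, 300),
  dreaming = c(150, 450))

#' Mode transform descriptor
#'
#' Parameter transform applied to a trained network for each functioning
#' mode.
#'
#' @param mode One of `"retrieval"`, `"imagination"`, `"dreaming"`,
#'   `"dreaming_fast_gamma"`, `"dreaming_no_theta"`, `"schizophrenia"`.
#' @param gamma45_factor Fast-GABA time-constant factor used by the
#'   fast-gamma variant (default [fast_gamma_factor()] for 45 Hz).
#' @return A list with fields `noise_positive_uniform` (min, max),
#'   `synapse_scale`, `af_scale`, `gamma_factor`, `theta_mode`
#'   (`"oscillating"` or `"constant"`), `wm_connected`.
#' @export
mode_transform <- function(mode = c("retrieval", "imagination", "dreaming",
                                    "dreaming_fast_gamma",
                                    "dreaming_no_theta", "schizophrenia"),
                           gamma45_factor = fast_gamma_factor(45)) {
  mode <- match.arg(mode)
  base <- list(mode = mode, noise_positive_uniform = c(0, 0),
               synapse_scale = 1, af_scale = 1, gamma_factor = 1,
               theta_mode = "oscillating", wm_connected = TRUE)
  dream <- .tg_mode_noise$dreaming
  switch(mode,
    retrieval = base,
    imagination = modifyList(base, list(
      noise_positive_uniform = .tg_mode_noise$imagination,
      wm_connected = FALSE)),
    dreaming = modifyList(base, list(
      noise_positive_uniform = dream, synapse_scale = 1 / 3,
      wm_connected = FALSE)),
    dreaming_fast_gamma = modifyList(base, list(
      noise_positive_uniform = dream, synapse_scale = 1 / 3,
      gamma_factor = gamma45_factor, wm_connected = FALSE)),
    dreaming_no_theta = modifyList(base, list(
      noise_positive_uniform = dream, synapse_scale = 1 / 3,
      theta_mode = "constant", wm_connected = FALSE)),
    schizophrenia = modifyList(base, list(
      noise_positive_uniform = dream, af_scale = 1 / 2,
      wm_connected = FALSE)))
}

#' Apply a mode transform to a trained network
#'
#' Scales the plastic weight matrices (always starting from the pristine
#' trained copy, so transforms never compound), sets the L1 noise
#' specification, connects or disconnects the WM layer, applies the
#' fast-GABA time-constant factor, and for the non-theta variant replaces
#' the oscillating theta drive with a constant disinhibition equal to the
#' mean of the theta wave over its on-phase.
#'
#' @param network A trained `tg_network`.
#' @param transform A transform from [mode_transform()].
#' @return The transformed network (with `$mode_transform` recorded).
#' @export
apply_mode <- function(network, transform) {
  stopifnot(inherits(network, "tg_network"))
  if (transform$synapse_scale <= 0 || transform$af_scale <= 0)
    stop("mode scale factors must be positive")
  if (is.null(network$pristine))
    stop("network has no trained pristine weights; train it first")
  snap <- network$pristine
  s <- transform$synapse_scale
  snap <- list(Wp_L1L1 = snap$Wp_L1L1 * s,
               Wf_L1L1 = snap$Wf_L1L1 * s,
               Af_L1L1 = snap$Af_L1L1 * s * transform$af_scale,
               Wp_L1L2 = snap$Wp_L1L2 * s)
  pristine <- network$pristine
  network <- install_weights(network, snap)
  network$pristine <- pristine
  iL1 <- layer_index(network, "L1"); iWM <- layer_index(network, "WM")
  iTH <- layer_index(network, "theta")
  if (!transform$wm_connected)
    network$Wp[cbind(iL1, iWM)] <- 0
  u <- transform$noise_positive_uniform
  network$unif_min[iL1] <- u[1]
  network$unif_max[iL1] <- u[2]
  if (transform$gamma_factor != 1)
    network <- scale_time_constants(network, "L1L2_fastGABA",
                                    transform$gamma_factor)
  if (transform$theta_mode == "constant") {
    mz <- .theta_mean_output(network)
    w <- network$Wp[iL1[1], iTH]
    network$Wp[iL1, iTH] <- 0
    network$unitpar[iL1, "tonic_p"] <-
      network$unitpar[iL1, "tonic_p"] + w * mz
  }
  network$mode_transform <- transform
  network$mode <- transform$mode
  network
}

# mean of the theta generator's pyramidal output over its on-phase: the
# non-oscillating variant holds the disinhibited state constant
.theta_mean_output <- function(network) {
  i <- layer_index(network, "theta")
  pars <- as.list(network$unitpar[i, ])
  u <- structure(pars, class = "tg_unit_params")
  sim <- simulate_unit(u, duration = 3, dt = network$dt)
  z <- sim$z_p[sim$t > 1]
  rng <- range(z)
  mean(z[z > rng[1] + 0.3 * diff(rng)])
}

#' Run the network in retrieval mode
#'
#' Simulates cued retrieval: each cue drives its WM unit for a short window,
#' the WM layer maintains it (and resets on a new cue), L1 is rhythmically
#' disinhibited by the theta generator, and the trained synapses replay the
#' stored sequence within each theta cycle. The simulation includes a
#' settling period before the first cue; scoring utilities use the
#' `cue_onset` attribute to align the analysis window.
#'
#' @param trained_network A trained `tg_network` in retrieval configuration.
#' @param cues Data.frame with columns `feature`, `onset` (s, relative to the
#'   scored window), optional `duration` and `amp`.
#' @param duration Scored window (s).
#' @param seed RNG seed.
#' @param settle Settling time before the scored window (s).
#' @return A `tg_sim` with attribute `cue_onset` (start of the scored
#'   window in trace time).
#' @export
run_retrieval <- function(trained_network, cues, duration = 1.0, seed = 1,
                          settle = 0.5) {
  net <- trained_network
  stopifnot(inherits(net, "tg_network"))
  if (!net$trained)
    warning("network is untrained; retrieval will not recall episodes")
  if (any(cues$feature < 1 | cues$feature > net$n_features))
    stop("cue feature outside 1..", net$n_features)
  cues$onset <- cues$onset + settle
  wd <- wm_drive(cues, n_features = net$n_features)
  total <- settle + duration + 0.45   # margin: last cycle's on-phase
  sim <- simulate_network(net, total, events = wd$events, resets = wd$resets,
                          seed = seed)
  attr(sim, "cue_onset") <- settle
  sim
}

#' Run the network isolated from the environment
#'
#' Applies the mode transform, feeds the positive uniform noise to L1, and
#' runs with no external cue.
#'
#' @param trained_network A trained `tg_network`.
#' @param mode One of `"imagination"`, `"dreaming"`, `"dreaming_fast_gamma"`,
#'   `"dreaming_no_theta"`, `"schizophrenia"`.
#' @param duration Simulated time (s).
#' @param seed RNG seed.
#' @return A `tg_sim`.
#' @export
run_isolation <- function(trained_network, mode, duration = 10, seed = 1) {
  mode <- match.arg(mode, c("imagination", "dreaming", "dreaming_fast_gamma",
                            "dreaming_no_theta", "schizophrenia"))
  net <- apply_mode(trained_network, mode_transform(mode))
  simulate_network(net, duration, seed = seed)
}

#' Fast-GABA time-constant factor for a target gamma frequency
#'
#' The gamma frequency of the L1/L2 units scales approximately as the
#' inverse square root of the fast-GABA time constant; the factor for a
#' target frequency is `(base / target)^2`, with the base taken from the
#' measured intrinsic frequency of the driven gamma preset.
#'
#' @param target_hz Desired gamma frequency (Hz).
#' @param base_hz Basal gamma frequency (Hz).
#' @return Multiplicative factor for [scale_time_constants()].
#' @export
fast_gamma_factor <- function(target_hz, base_hz = gamma_base_hz()) {
  stopifnot(target_hz > 0)
  (base_hz / target_hz)^2
}

#' Intrinsic frequency of the driven gamma preset
#'
#' Measured once from a noise-free simulation of an isolated gamma unit
#' under a constant representative drive, and cached for the session.
#'
#' @return Frequency in Hz.
#' @export
gamma_base_hz <- function() {
  if (!is.null(.tg$gamma_base_hz)) return(.tg$gamma_base_hz)
  u <- make_unit("gamma")
  sim <- simulate_unit(u, duration = 2, dt = 1e-4, u_p = 450)
  f <- as.numeric(dominant_frequency(sim$z_p[sim$t > 0.5], 1e-4))
  .tg$gamma_base_hz <- f
  f
}

#' Theta time-constant factor for a target theta frequency
#'
#' Scaling the theta generator's glutamatergic and slow-GABA time constants
#' by `f` rescales its limit cycle in time exactly, so the factor for a
#' target frequency is `base_hz / target_hz`.
#'
#' @param target_hz Desired theta frequency (Hz).
#' @param base_hz Basal theta frequency of the preset (Hz).
#' @return Multiplicative factor for [scale_time_constants()].
#' @export
theta_factor <- function(target_hz, base_hz = theta_base_hz()) {
  stopifnot(target_hz > 0)
  base_hz / target_hz
}

#' Basal frequency of the theta preset
#'
#' Measured once from a long noise-free simulation of the theta unit and
#' cached for the session.
#'
#' @return Frequency in Hz.
#' @export
theta_base_hz <- function() {
  if (!is.null(.tg$theta_base_hz)) return(.tg$theta_base_hz)
  u <- make_unit("theta")
  sim <- simulate_unit(u, duration = 6, dt = 1e-4)
  z <- sim$z_p[sim$t > 1]
  cyc <- theta_cycles(z, 1e-4)
  f <- 1 / stats::median(diff(cyc$start))
  .tg$theta_base_hz <- f
  f
}
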