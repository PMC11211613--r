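# Full architecture: three layers of gamma-preset units (WM, L1, L2, one
# unit per feature) plus a single theta-generator unit. Fixed wiring:
# feature-preserving diagonal feedforward WM->L1 and L1->L2 (glutamatergic,
# pyramidal targets) and a uniform excitatory synapse from the theta
# generator to every L1 pyramidal population. The plastic synapses are
# exactly Wp(L1,L1), Wf(L1,L1), Af(L1,L1) and Wp(L1,L2), zero before
# training. Matrix orientation everywhere: rows = post-synaptic unit,
# columns = pre-synaptic unit.

# Fixed-wiring and noise defaults (calibrated once; see methods vignette).
.tg_fixed <- list(
  w_ff_wm_l1 = 50,     # WM -> L1 diagonal feedforward weight
  w_ff_l1_l2 = 300,    # L1 -> L2 diagonal feedforward weight (saturating relay)
  w_theta    = 180,    # theta generator -> every L1 unit
  l1_bias    = -680.9,   # tonic inhibitory bias on L1 pyramidal inputs: L1 is
                       # inhibited at rest and disinhibited by the theta drive
  noise_sd_p = 14,     # basal zero-mean noise, pyramidal input, all layers
  noise_sd_f = 14,     # basal zero-mean noise, fast-interneuron input
  cue_amplitude = 500, # retrieval cue drive to WM pyramidal units
  train_amplitude = 700, # training drive to L1/L2 pyramidal populations
  train_amplitude_f = 25 # training co-drive to the fast interneurons
)

#' Layer index helpers
#'
#' Global unit indices of a layer in the assembled network: WM units come
#' first, then L1, then L2, then the single theta generator.
#'
#' @param network A `tg_network`.
#' @param layer One of `"WM"`, `"L1"`, `"L2"`, `"theta"`.
#' @return Integer vector of global unit indices (1-based).
#' @export
layer_index <- function(network, layer = c("WM", "L1", "L2", "theta")) {
  layer <- match.arg(layer)
  n <- network$n_features
  switch(layer,
         WM = seq_len(n), L1 = n + seq_len(n), L2 = 2L * n + seq_len(n),
         theta = 3L * n + 1L)
}

#' Assemble the three-layer theta-gamma network
#'
#' Builds the network with fixed wiring installed and all plastic matrices
#' zero. In `"training"` mode the feedforward (WM->L1, L1->L2) and theta
#' drives are disconnected: during encoding the perception input reaches L1
#' and L2 directly.
#'
#' @param sequences Optional `tg_seqset` carried along as metadata (feature
#'   indices are validated against the layer size).
#' @param mode `"retrieval"` or `"training"`.
#' @param n_features Units per layer (default 75).
#' @param dt Integration step (s).
#' @param unit_overrides Optional named list of per-preset overrides, e.g.
#'   `list(gamma = list(ws = 25))`.
#' @return A `tg_network` object.
#' @export
build_network <- function(sequences = NULL, mode = c("retrieval", "training"),
                          n_features = 75, dt = 1e-4,
                          unit_overrides = list()) {
  mode <- match.arg(mode)
  if (!is.null(sequences)) {
    stopifnot(inherits(sequences, "tg_seqset"))
    if (any(unlist(sequences$episodes) > n_features))
      stop("sequence set references features beyond the layer size")
  }
  gp <- make_unit("gamma", overrides = unit_overrides$gamma %||% list())
  tp <- make_unit("theta", overrides = unit_overrides$theta %||% list())
  wp <- make_unit("wm", overrides = unit_overrides$wm %||% list())
  N <- 3L * n_features + 1L
  unitpar <- matrix(0, N, length(.unit_par_names),
                    dimnames = list(NULL, .unit_par_names))
  net <- structure(list(n_features = n_features, dt = dt, dt_ref = 1e-4,
                        mode = mode, sequences = sequences,
                        fixed = .tg_fixed, trained = FALSE,
                        unit_overrides = unit_overrides,
                        presets = list(gamma = gp, theta = tp, wm = wp)),
                   class = "tg_network")
  iWM <- layer_index(net, "WM"); iL1 <- layer_index(net, "L1")
  iL2 <- layer_index(net, "L2"); iTH <- layer_index(net, "theta")
  unitpar[iWM, ] <- rep(.unitpar_row(wp), each = n_features)
  unitpar[iL1, ] <- rep(.unitpar_row(gp), each = n_features)
  unitpar[iL2, ] <- rep(.unitpar_row(gp), each = n_features)
  unitpar[iTH, ] <- .unitpar_row(tp)
  if (mode == "retrieval")
    unitpar[iL1, "tonic_p"] <- unitpar[iL1, "tonic_p"] + .tg_fixed$l1_bias
  net$unitpar <- unitpar

  Wp <- matrix(0, N, N); Wf <- matrix(0, N, N); Af <- matrix(0, N, N)
  if (mode == "retrieval") {
    Wp[cbind(iL1, iWM)] <- .tg_fixed$w_ff_wm_l1
    Wp[cbind(iL2, iL1)] <- .tg_fixed$w_ff_l1_l2
    Wp[iL1, iTH] <- .tg_fixed$w_theta
  }
  net$Wp <- Wp; net$Wf <- Wf; net$Af <- Af
  net$noise_sd_p <- c(rep(.tg_fixed$noise_sd_p, 3L * n_features), 0)
  net$noise_sd_f <- c(rep(.tg_fixed$noise_sd_f, 3L * n_features), 0)
  net$unif_min <- numeric(N); net$unif_max <- numeric(N)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tg_network <- function(x, ...) {
  cat("tg_network: 3 x", x$n_features, "units + theta generator | mode:",
      x$mode, "| trained:", x$trained, "\n")
  invisible(x)
}

.empty_state <- function(network) matrix(0, nrow(network$unitpar), 12)

.events_matrix <- function(network, events, dt, n_steps) {
  if (is.null(events) || nrow(events) == 0) return(matrix(0, 0, 5))
  idx <- mapply(function(f, l) layer_index(network, l)[f],
                events$feature, events$layer)
  m <- cbind(idx - 1L, ifelse(events$pop == "f", 1, 0),
             round(events$start / dt), round(events$end / dt), events$amp)
  m[m[, 3] < n_steps & m[, 4] > 0, , drop = FALSE]
}

#' Advance the assembled network
#'
#' Runs the fixed-step integrator over the whole network for `duration`
#' seconds. External inputs are rectangular drives (see [make_inputs()]);
#' working-memory resets zero the kernel state of WM units at given times.
#'
#' @param network A `tg_network`.
#' @param duration Simulated time (s).
#' @param events Input schedule data.frame from [make_inputs()] /
#'   [wm_drive()] (columns feature, layer, pop, start, end, amp), or `NULL`.
#' @param resets Optional data.frame with columns `time` (s) and `feature`;
#'   the named WM units' states are zeroed at those times.
#' @param seed Optional RNG seed (set before the run).
#' @param state Optional initial state matrix (units x 12); default all-zero.
#' @param record `"all"` or a character vector of layers to record.
#' @param plastic If `TRUE`, apply the plastic updates of `learn` each step.
#' @param learn Learning parameter object (see [default_learning_params()]).
#' @param suppress_coupling If `TRUE`, inter-unit synapses are removed from
#'   the dynamics (encoding configuration) while plastic accumulation runs.
#' @return A `tg_sim` object: `z` (recorded units x time spike densities),
#'   `record_units`, per-layer accessors via [layer_trace()], `dt`, `seed`,
#'   the final `state`, and (when plastic) updated weight matrices.
#' @export
simulate_network <- function(network, duration, events = NULL, resets = NULL,
                             seed = NULL, state = NULL,
                             record = "all", plastic = FALSE, learn = NULL,
                             suppress_coupling = FALSE) {
  stopifnot(inherits(network, "tg_network"), duration > 0)
  dt <- network$dt
  n_steps <- round(duration / dt)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- .empty_state(network)
  ev <- .events_matrix(network, events, dt, n_steps)
  if (is.null(resets) || nrow(resets) == 0) {
    rs <- integer(0); ru <- integer(0)
  } else {
    iWM <- layer_index(network, "WM")
    rs <- rep(round(resets$time / dt), each = 1)
    ru <- iWM[resets$feature] - 1L
    o <- order(rs); rs <- as.integer(rs[o]); ru <- as.integer(ru[o])
  }
  rec_units <- if (identical(record, "all")) {
    seq_len(nrow(network$unitpar))
  } else {
    sort(unlist(lapply(record, function(l) layer_index(network, l))))
  }
  lp <- if (plastic) {
    .learn_matrix(learn %||% default_learning_params())
  } else matrix(0, 4, 4)
  out <- .sim_core(network$Wp, network$Wf, network$Af,
                   network$unitpar, ev,
                   network$noise_sd_p, network$noise_sd_f,
                   network$unif_min, network$unif_max,
                   rs, ru,
                   n_steps, dt, network$dt_ref, state,
                   as.integer(rec_units - 1L), 1L, FALSE,
                   plastic, lp,
                   as.integer(layer_index(network, "L1") - 1L),
                   as.integer(layer_index(network, "L2") - 1L),
                   if (plastic) (learn %||% default_learning_params())$tau
                   else 0.02, suppress_coupling)
  structure(list(z = out$trace_p, record_units = rec_units,
                 n_features = network$n_features,
                 dt = dt, duration = duration, seed = seed,
                 mode = network$mode, events = events,
                 state = out$state,
                 Wp = if (plastic) out$Wp, Wf = if (plastic) out$Wf,
                 Af = if (plastic) out$Af),
            class = "tg_sim")
}

#' Advance the network by a single integration step
#'
#' One explicit Euler step; a thin wrapper over [simulate_network()] used for
#' step-level tests and state inspection.
#'
#' @inheritParams simulate_network
#' @return A `tg_sim` with one recorded sample and the advanced `state`.
#' @export
step_network <- function(network, state, events = NULL, seed = NULL) {
  simulate_network(network, duration = network$dt, events = events,
                   seed = seed, state = state)
}

#' Extract the pyramidal trace of one layer from a simulation
#'
#' @param sim A `tg_sim` from [simulate_network()].
#' @param layer One of `"WM"`, `"L1"`, `"L2"`, `"theta"`.
#' @return Matrix (features x time), or a vector for `"theta"`.
#' @export
layer_trace <- function(sim, layer = c("L2", "L1", "WM", "theta")) {
  layer <- match.arg(layer)
  n <- sim$n_features
  idx <- switch(layer, WM = seq_len(n), L1 = n + seq_len(n),
                L2 = 2L * n + seq_len(n), theta = 3L * n + 1L)
  rows <- match(idx, sim$record_units)
  if (anyNA(rows)) stop("layer ", layer, " was not recorded in this run")
  out <- sim$z[rows, , drop = FALSE]
  if (layer == "theta") drop(out) else out
}

#' Working-memory drive with persistence and reset
#'
#' Converts a list of cue events into (i) rectangular drives to the WM
#' pyramidal units and (ii) the WM reset schedule: whenever a cue arrives
#' whose feature set differs from the currently maintained set (and whose
#' amplitude exceeds the reset threshold), the self-excitation state of all
#' WM units is zeroed at cue onset, so the new feature replaces the old one.
#'
#' @param cues A data.frame with columns `feature`, `onset` and optionally
#'   `duration` (default 0.05 s) and `amp` (default the calibrated cue
#'   amplitude).
#' @param amp_threshold Amplitude above which a cue triggers a reset.
#' @param n_features Units in the WM layer.
#' @return `list(events =, resets =)` for [simulate_network()].
#' @export
wm_drive <- function(cues, amp_threshold = 100, n_features = 75) {
  if (is.null(cues) || nrow(cues) == 0)
    return(list(events = NULL, resets = NULL))
  if (is.null(cues$duration)) cues$duration <- 0.05
  if (is.null(cues$amp)) cues$amp <- .tg_fixed$cue_amplitude
  cues <- cues[order(cues$onset), , drop = FALSE]
  events <- NULL; resets <- NULL
  maintained <- integer(0)
  for (i in seq_len(nrow(cues))) {
    cue <- cues[i, ]
    events <- rbind(events,
                    make_inputs(cue$feature, "WM", cue$onset,
                                cue$onset + cue$duration, cue$amp, "p"))
    if (cue$amp > amp_threshold && !setequal(cue$feature, maintained)) {
      if (length(maintained))
        resets <- rbind(resets,
                        data.frame(time = cue$onset,
                                   feature = seq_len(n_features)))
      maintained <- cue$feature
    }
  }
  list(events = events, resets = resets)
}

#' Scale synaptic kernel time constants of selected population classes
#'
#' Multiplies the named kernel time constants by `factor` (dividing the
#' reciprocal rate constants) while scaling the kernel gains by `1/factor`,
#' which preserves the kernel area (DC gain) so the affected dynamics are a
#' pure time rescale. `"theta_glutamatergic_and_slowGABA"` retunes the theta
#' generator's frequency to (base frequency)/factor;
#' `"L1L2_fastGABA"` changes the gamma frequency of the L1 and L2 units
#' (factor < 1 makes gamma faster).
#'
#' @param network A `tg_network`.
#' @param population_classes Character subset of
#'   `c("theta_glutamatergic_and_slowGABA", "L1L2_fastGABA")`.
#' @param factor Positive multiplicative factor on the time constants.
#' @return The modified network.
#' @export
scale_time_constants <- function(network, population_classes, factor) {
  stopifnot(inherits(network, "tg_network"))
  if (factor <= 0) stop("factor must be positive")
  ok <- c("theta_glutamatergic_and_slowGABA", "L1L2_fastGABA")
  if (!all(population_classes %in% ok))
    stop("unknown population class")
  up <- network$unitpar
  if ("theta_glutamatergic_and_slowGABA" %in% population_classes) {
    i <- layer_index(network, "theta")
    for (cc in c("we", "ws")) up[i, cc] <- up[i, cc] / factor
    for (cc in c("Ge", "Gs")) up[i, cc] <- up[i, cc] / factor
  }
  if ("L1L2_fastGABA" %in% population_classes) {
    i <- c(layer_index(network, "L1"), layer_index(network, "L2"))
    up[i, "wf"] <- up[i, "wf"] / factor
    up[i, "Gf"] <- up[i, "Gf"] / factor
  }
  network$unitpar <- up
  network
}
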