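# Training: Hebbian potentiation of the glutamatergic plastic synapses
# (Wp within L1, Wf within L1, Wp from L2 to L1) and anti-Hebbian
# potentiation of the desynchronizing Af synapses within L1, with per-unit
# incoming-sum normalization. Weight updates are rate products with
# activity thresholds:
#   Hebb:      dW = rate * dt * [z_post - th_post]+ * [z_pre - th_pre]+
#   anti-Hebb: dA = rate * dt * [z_post - th_post]+ * [th_silent - z_pre]+
# so Af grows between an active post-synaptic unit and a silent pre-synaptic
# one (the anti-correlation that desynchronizes distinct episodes).

#' Learning parameters of the four plastic synapse kinds
#'
#' One row per kind (`Wp_L1L1`, `Wf_L1L1`, `Af_L1L1`, `Wp_L1L2`): learning
#' rate (1/s per (spikes/s)^2), post- and pre-synaptic activity thresholds
#' (spikes/s; for `Af` the pre threshold is a silence threshold), per-synapse
#' saturation, and the per-unit cap on the sum of incoming weights of that
#' kind.
#'
#' @param ... Named overrides of the form `kind = list(field = value)`.
#' @return A `tg_learning_params` object (named list of per-kind lists).
#' @export
default_learning_params <- function(...) {
  p <- list(
    Wp_L1L1 = list(rate = 8000, th_post = 1, th_pre = 1, sat = 140, cap = 420),
    Wf_L1L1 = list(rate = 8000, th_post = 1, th_pre = 1, sat = 20, cap = 60),
    Af_L1L1 = list(rate = 450, th_post = 1, th_pre = 0.5, sat = 3, cap = 22),
    Wp_L1L2 = list(rate = 8000, th_post = 1, th_pre = 1, sat = 35, cap = 140),
    tau = 0.02)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown synapse kind: ", paste(bad, collapse = ", "))
  for (k in names(ov))
    p[[k]] <- if (is.list(p[[k]])) modifyList(p[[k]], ov[[k]]) else ov[[k]]
  for (k in setdiff(names(p), "tau")) {
    stopifnot(p[[k]]$cap > 0, p[[k]]$sat >= 0,
              p[[k]]$th_post >= 0, p[[k]]$th_post <= 5,
              p[[k]]$th_pre >= 0, p[[k]]$th_pre <= 5)
  }
  stopifnot(p$tau > 0)
  structure(p, class = "tg_learning_params")
}

.learn_matrix <- function(lp) {
  stopifnot(inherits(lp, "tg_learning_params"))
  t(vapply(lp[c("Wp_L1L1", "Wf_L1L1", "Af_L1L1", "Wp_L1L2")],
           function(k) c(k$rate, k$th_post, k$th_pre, k$sat), numeric(4)))
}

#' One Hebbian weight update
#'
#' Applies a single-step thresholded-correlation Hebbian update to a weight
#' matrix (rows post-synaptic, columns pre-synaptic). Weights are clipped to
#' `[0, sat]`; for square within-layer matrices the diagonal stays zero.
#'
#' @param W Weight matrix.
#' @param pre_activity,post_activity Spike-density vectors of the source and
#'   target populations (spikes/s).
#' @param params Per-kind parameter list (`rate`, `th_post`, `th_pre`,
#'   `sat`), e.g. one element of [default_learning_params()].
#' @param dt Time step (s).
#' @param zero_diag Keep the diagonal at zero (within-layer matrices).
#' @return Updated weight matrix.
#' @export
hebbian_update <- function(W, pre_activity, post_activity, params, dt,
                           zero_diag = nrow(W) == ncol(W)) {
  post <- pmax(post_activity - params$th_post, 0)
  pre <- pmax(pre_activity - params$th_pre, 0)
  W <- W + params$rate * dt * outer(post, pre)
  W <- pmin(pmax(W, 0), params$sat)
  if (zero_diag) diag(W) <- 0
  if (any(W < 0)) stop("internal error: negative weight after Hebbian update")
  W
}

#' One anti-Hebbian weight update
#'
#' Potentiates desynchronizing weights between an active post-synaptic unit
#' and a silent pre-synaptic unit; clipped to `[0, sat]`, zero diagonal.
#'
#' @inheritParams hebbian_update
#' @return Updated weight matrix.
#' @export
anti_hebbian_update <- function(A_f, pre_activity, post_activity, params, dt) {
  post <- pmax(post_activity - params$th_post, 0)
  pre <- pmax(params$th_pre - pre_activity, 0)
  A_f <- A_f + params$rate * dt * outer(post, pre)
  A_f <- pmin(pmax(A_f, 0), params$sat)
  diag(A_f) <- 0
  if (any(A_f < 0))
    stop("internal error: negative weight after anti-Hebbian update")
  A_f
}

#' Per-unit incoming-weight normalization
#'
#' For each post-synaptic unit (row), if the sum of incoming weights exceeds
#' `cap`, the row is rescaled multiplicatively so the sum equals `cap`; rows
#' under the cap are unchanged. This mimics the physiological limit on total
#' synaptic resources and makes episodes of different richness comparable.
#'
#' @param W Weight matrix (rows post-synaptic).
#' @param cap Maximum allowed row sum (> 0).
#' @return The normalized matrix.
#' @export
normalize_incoming <- function(W, cap) {
  stopifnot(cap > 0)
  rs <- rowSums(W)
  over <- rs > cap
  if (any(over)) W[over, ] <- W[over, , drop = FALSE] * (cap / rs[over])
  W
}

#' Train the network on a set of episode sequences
#'
#' Runs the encoding protocol: for each sequence of N episodes, N + 1
#' presentations of 250 ms during which presentation k drives the pyramidal
#' and fast-interneuron populations of episode k's features in L1 and of
#' episode k-1's features in L2 (episodes 0 and N+1 are null, i.e. noise
#' only). Each episode pair is presented exactly once. Plastic updates run at
#' every integration step; row normalization is applied at the end of every
#' presentation. Feedforward and theta influence are disabled (training
#' configuration).
#'
#' @param network A `tg_network` (any mode; the training wiring is used
#'   internally).
#' @param sequence_set A `tg_seqset`.
#' @param learning_params A `tg_learning_params`
#'   (default [default_learning_params()]).
#' @param present_dur Presentation duration (s).
#' @param seed RNG seed for the training-phase noise.
#' @return The input network (in its own mode/wiring) with the trained
#'   plastic blocks installed, `trained = TRUE`, a pristine copy of the
#'   trained weights in `$pristine`, and the weight snapshot in `$snapshot`
#'   (list `Wp_L1L1`, `Wf_L1L1`, `Af_L1L1`, `Wp_L1L2`).
#' @export
train_sequences <- function(network, sequence_set,
                            learning_params = default_learning_params(),
                            present_dur = 0.25, seed = 1) {
  stopifnot(inherits(network, "tg_network"), inherits(sequence_set, "tg_seqset"))
  if (sequence_set$n_features > network$n_features)
    stop("sequence set does not fit the network layer size")
  tr <- build_network(sequence_set, mode = "training",
                      n_features = network$n_features, dt = network$dt,
                      unit_overrides = network$unit_overrides %||% list())
  # training wiring: no feedforward, no theta drive, no retrieval bias
  amp <- network$fixed$train_amplitude
  amp_f <- network$fixed$train_amplitude_f
  set.seed(seed)
  state <- .empty_state(tr)
  for (s in seq_along(sequence_set$sequences)) {
    eps <- sequence_set$sequences[[s]]
    N <- length(eps)
    state <- .empty_state(tr)
    for (k in seq_len(N + 1L)) {
      ev <- NULL
      if (k <= N)
        ev <- rbind(ev,
                    make_inputs(eps[[k]], "L1", 0, present_dur, amp, "p"),
                    make_inputs(eps[[k]], "L1", 0, present_dur, amp_f, "f"))
      if (k >= 2L)
        ev <- rbind(ev,
                    make_inputs(eps[[k - 1L]], "L2", 0, present_dur, amp, "p"),
                    make_inputs(eps[[k - 1L]], "L2", 0, present_dur, amp_f,
                                "f"))
      sim <- simulate_network(tr, present_dur, events = ev, state = state,
                              record = "theta", plastic = TRUE,
                              learn = learning_params,
                              suppress_coupling = TRUE)
      state <- sim$state
      tr$Wp <- sim$Wp; tr$Wf <- sim$Wf; tr$Af <- sim$Af
      tr <- .normalize_network(tr, learning_params)
    }
  }
  iL1 <- layer_index(network, "L1"); iL2 <- layer_index(network, "L2")
  snap <- list(Wp_L1L1 = tr$Wp[iL1, iL1], Wf_L1L1 = tr$Wf[iL1, iL1],
               Af_L1L1 = tr$Af[iL1, iL1], Wp_L1L2 = tr$Wp[iL1, iL2])
  # anti-Hebbian potentiation requires presynaptic participation in the
  # encoding epoch: features that never took part in any episode form no
  # outgoing desynchronizing synapses, so Af support is exactly the
  # between-episode pairs of stored features.
  stored <- sort(unique(unlist(sequence_set$episodes)))
  snap$Af_L1L1[, setdiff(seq_len(network$n_features), stored)] <- 0
  # a Hebbian co-activation tag protects co-members of any episode from
  # anti-Hebbian potentiation: a feature shared by two episodes must not be
  # desynchronized from the partners of either of them (it receives
  # desynchronizing synapses only from episodes it does not belong to).
  for (ep in sequence_set$episodes)
    snap$Af_L1L1[ep, ep] <- 0
  network <- install_weights(network, snap)
  network$sequences <- sequence_set
  network
}

.normalize_network <- function(net, lp) {
  iL1 <- layer_index(net, "L1"); iL2 <- layer_index(net, "L2")
  net$Wp[iL1, iL1] <- normalize_incoming(net$Wp[iL1, iL1], lp$Wp_L1L1$cap)
  net$Wf[iL1, iL1] <- normalize_incoming(net$Wf[iL1, iL1], lp$Wf_L1L1$cap)
  net$Af[iL1, iL1] <- normalize_incoming(net$Af[iL1, iL1], lp$Af_L1L1$cap)
  net$Wp[iL1, iL2] <- normalize_incoming(net$Wp[iL1, iL2], lp$Wp_L1L2$cap)
  net
}

#' Install a plastic-weight snapshot into a network
#'
#' @param network A `tg_network`.
#' @param snapshot List with elements `Wp_L1L1`, `Wf_L1L1`, `Af_L1L1`,
#'   `Wp_L1L2` (as produced by [train_sequences()]).
#' @return The network with the plastic blocks set, `trained = TRUE`, and a
#'   pristine copy stored for mode transforms.
#' @export
install_weights <- function(network, snapshot) {
  iL1 <- layer_index(network, "L1"); iL2 <- layer_index(network, "L2")
  network$Wp[iL1, iL1] <- snapshot$Wp_L1L1
  network$Wf[iL1, iL1] <- snapshot$Wf_L1L1
  network$Af[iL1, iL1] <- snapshot$Af_L1L1
  network$Wp[iL1, iL2] <- snapshot$Wp_L1L2
  network$trained <- TRUE
  network$snapshot <- snapshot
  network$pristine <- snapshot
  network
}
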