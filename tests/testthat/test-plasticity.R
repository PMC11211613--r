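test_that("hebbian_update leaves weights unchanged without presynaptic drive", {
  lp <- default_learning_params()
  W <- matrix(runif(16), 4, 4); diag(W) <- 0
  W2 <- hebbian_update(W, rep(0, 4), rep(5, 4), lp$Wp_L1L1, 1e-4)
  expect_equal(W, W2)
})

test_that("anti-Hebbian growth requires anti-correlation", {
  lp <- default_learning_params()
  A <- matrix(0, 4, 4)
  # identical supra-threshold activities: no growth
  A2 <- anti_hebbian_update(A, rep(4, 4), rep(4, 4), lp$Af_L1L1, 1e-4)
  expect_equal(A2, A)
  # active post (units 1-2), silent pre (units 1-2): the active-post rows
  # grow weights from the silent pre columns and nowhere else
  A3 <- anti_hebbian_update(A, c(0, 0, 4, 4), c(4, 4, 0, 0), lp$Af_L1L1, 1e-4)
  off <- A3[1:2, 1:2]; off <- off[row(off) != col(off)]
  expect_true(all(off > 0))             # active post <- silent pre grows
  expect_true(all(A3[1:2, 3:4] == 0))   # active pre: no growth
  expect_true(all(A3[3:4, ] == 0))      # silent post: no growth
  expect_true(all(diag(A3) == 0))
})

test_that("weight updates stay in [0, sat] and respect the diagonal", {
  lp <- default_learning_params(Wp_L1L1 = list(rate = 1e9))
  W <- matrix(0, 3, 3)
  W2 <- hebbian_update(W, rep(5, 3), rep(5, 3), lp$Wp_L1L1, 1e-4)
  expect_true(all(W2 <= lp$Wp_L1L1$sat & W2 >= 0))
  expect_true(all(diag(W2) == 0))
})

test_that("normalize_incoming rescales only rows above the cap", {
  W <- rbind(c(0, 2, 2), c(0, 20, 30), c(1, 1, 1))
  W2 <- normalize_incoming(W, cap = 10)
  expect_equal(W2[1, ], W[1, ])           # under cap: unchanged
  expect_equal(sum(W2[2, ]), 10)          # rescaled to the cap
  expect_equal(W2[2, 2] / W2[2, 3], 20 / 30) # multiplicative rescale
  expect_equal(W2[3, ], W[3, ])
  expect_error(normalize_incoming(W, -1), "cap")
})

test_that("network training matches an independent scalar accumulation", {
  # drive two L1 units at constant amplitudes with coupling suppressed and
  # no noise; the C++ plastic path must equal a plain-R accumulation of the
  # same rule (including the low-pass activity filter) applied to the
  # recorded spike densities.
  net <- build_network(n_features = 2, mode = "training")
  net$noise_sd_p[] <- 0; net$noise_sd_f[] <- 0
  lp <- default_learning_params()
  ev <- rbind(data.frame(feature = 1, layer = "L1", pop = "p",
                         start = 0, end = 0.2, amp = 450),
              data.frame(feature = 2, layer = "L1", pop = "p",
                         start = 0, end = 0.2, amp = 430))
  sim <- simulate_network(net, 0.2, events = ev, plastic = TRUE, learn = lp,
                          suppress_coupling = TRUE)
  z <- layer_trace(sim, "L1")
  # scalar oracle: zlp(t+dt) = zlp + dt/tau (z - zlp); dW accumulates with
  # thresholds and saturation
  zlp <- c(0, 0); Wo <- matrix(0, 2, 2)
  k <- lp$Wp_L1L1
  for (s in seq_len(ncol(z))) {
    zlp <- zlp + (net$dt / lp$tau) * (z[, s] - zlp)
    for (i in 1:2) for (j in 1:2) {
      if (i == j) next
      post <- max(zlp[i] - k$th_post, 0); pre <- max(zlp[j] - k$th_pre, 0)
      Wo[i, j] <- min(Wo[i, j] + k$rate * net$dt * post * pre, k$sat)
    }
  }
  iL1 <- layer_index(net, "L1")
  expect_equal(sim$Wp[iL1, iL1], Wo, tolerance = 1e-8)
})

test_that("trained weight structure matches the associative architecture", {
  net <- trained_orth()
  sn <- net$snapshot
  set <- net$sequences
  eps <- set$episodes
  within <- matrix(FALSE, 75, 75); between <- matrix(FALSE, 75, 75)
  for (a in seq_along(eps)) for (b in seq_along(eps)) {
    for (i in eps[[a]]) for (j in eps[[b]]) {
      if (a == b && i != j) within[i, j] <- TRUE
      if (a != b) between[i, j] <- TRUE
    }
  }
  thr <- 0.05
  expect_true(all((sn$Wp_L1L1 > thr) == within))
  expect_true(all((sn$Wf_L1L1 > thr) == within))
  # desynchronizing synapses: exactly between-episode pairs
  expect_true(all((sn$Af_L1L1 > thr) == (between & !within)))
  # hetero-associative links: episode k receives from episode k-1 only
  super <- matrix(FALSE, 75, 75)
  for (sq in set$sequences)
    for (k in 2:length(sq))
      for (i in sq[[k]]) for (j in sq[[k - 1]]) super[i, j] <- TRUE
  expect_true(all((sn$Wp_L1L2 > thr) == super))
  # within-episode blocks are symmetric in support
  expect_true(all((sn$Wp_L1L1 > thr) == t(sn$Wp_L1L1 > thr)))
})

test_that("row sums respect the normalization caps after training", {
  lp <- default_learning_params()
  sn <- trained_orth()$snapshot
  expect_true(all(rowSums(sn$Wp_L1L1) <= lp$Wp_L1L1$cap + 1e-9))
  expect_true(all(rowSums(sn$Wf_L1L1) <= lp$Wf_L1L1$cap + 1e-9))
  expect_true(all(rowSums(sn$Af_L1L1) <= lp$Af_L1L1$cap + 1e-9))
  expect_true(all(rowSums(sn$Wp_L1L2) <= lp$Wp_L1L2$cap + 1e-9))
  expect_true(all(sn$Wp_L1L1 >= 0) && all(sn$Af_L1L1 >= 0))
})

test_that("presentation order does not change the learned supports", {
  mk_set <- function(rev) {
    s1 <- list(1:4, 5:8); s2 <- list(9:12, 13:16)
    seqs <- if (rev) list(s2, s1) else list(s1, s2)
    thetagamma:::.new_seqset(seqs, n_features = 16)
  }
  n1 <- train_sequences(build_network(mk_set(FALSE), n_features = 16),
                        mk_set(FALSE), seed = 1)
  n2 <- train_sequences(build_network(mk_set(TRUE), n_features = 16),
                        mk_set(TRUE), seed = 2)
  thr <- 0.05
  expect_identical(n1$snapshot$Wp_L1L1 > thr, n2$snapshot$Wp_L1L1 > thr)
  expect_identical(n1$snapshot$Af_L1L1 > thr, n2$snapshot$Af_L1L1 > thr)
})

test_that("richer episodes get weaker per-synapse weights; shared halve", {
  sn <- trained_nonorth()$snapshot
  # 6-feature episode 14 vs 4-feature episode 1 (per-synapse, unshared rows)
  w6 <- sn$Wp_L1L1[67, 66]   # within episode 14
  w4 <- sn$Wp_L1L1[2, 1]     # within episode 1
  expect_lt(w6, w4)
  # feature 71 is shared by episodes 2 and 14: incoming roughly half
  ratio <- sn$Wp_L1L1[71, 70] / w4
  expect_gt(ratio, 0.3)
  expect_lt(ratio, 0.65)
})
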