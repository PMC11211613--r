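test_that("default network has 3 x 75 units plus the theta generator", {
  net <- build_network()
  expect_equal(nrow(net$unitpar), 226)
  expect_equal(length(layer_index(net, "WM")), 75)
  expect_equal(length(layer_index(net, "L1")), 75)
  expect_equal(length(layer_index(net, "L2")), 75)
  expect_equal(length(layer_index(net, "theta")), 1)
  # feedforward matrices are diagonal and feature-preserving
  iWM <- layer_index(net, "WM"); iL1 <- layer_index(net, "L1")
  iL2 <- layer_index(net, "L2")
  ff <- net$Wp[iL1, iWM]
  expect_true(all(ff[row(ff) != col(ff)] == 0))
  expect_true(all(diag(ff) > 0))
  ff2 <- net$Wp[iL2, iL1]
  expect_true(all(ff2[row(ff2) != col(ff2)] == 0))
  # theta drive reaches every L1 unit uniformly, and only L1
  expect_true(all(net$Wp[iL1, layer_index(net, "theta")] > 0))
  expect_true(all(net$Wp[iL2, layer_index(net, "theta")] == 0))
  # plastic blocks start at zero
  expect_true(all(net$Wp[iL1, iL1] == 0))
  expect_true(all(net$Af == 0))
})

test_that("network construction is deterministic", {
  a <- build_network(make_orthogonal_set())
  b <- build_network(make_orthogonal_set())
  expect_identical(a$unitpar, b$unitpar)
  expect_identical(a$Wp, b$Wp)
})

test_that("build_network validates feature indices and mode", {
  small <- make_random_set(1, 2, c(4, 4), seed = 1, n_features = 75)
  expect_error(build_network(small, n_features = 10), "layer size")
})

test_that("with zero inter-unit weights each unit evolves as in isolation", {
  # noise off: the network integration of a decoupled unit must match the
  # single-unit path step for step
  net <- build_network(n_features = 2, mode = "training")
  net$noise_sd_p[] <- 0; net$noise_sd_f[] <- 0
  ev <- data.frame(feature = 1, layer = "L1", pop = "p",
                   start = 0, end = 0.3, amp = 450)
  sim <- simulate_network(net, 0.3, events = ev)
  iso <- simulate_unit(make_unit("gamma"), 0.3, u_p = 450)
  expect_equal(layer_trace(sim, "L1")[1, ], iso$z_p, tolerance = 1e-12)
})

test_that("a pyramidal->fast-interneuron link inhibits the target unit", {
  # two-unit toy: unit 1 driven, unit 2 driven; Wf link 1 -> 2 should lower
  # unit 2's mean activity. Oracle: an independent plain-R Euler integration
  # of the same two-unit system at dt/10.
  net <- build_network(n_features = 2, mode = "training")
  net$noise_sd_p[] <- 0; net$noise_sd_f[] <- 0
  iL1 <- layer_index(net, "L1")
  ev <- rbind(data.frame(feature = 1, layer = "L1", pop = "p",
                         start = 0, end = 0.5, amp = 450),
              data.frame(feature = 2, layer = "L1", pop = "p",
                         start = 0, end = 0.5, amp = 450))
  base <- simulate_network(net, 0.5, events = ev)
  netf <- net
  netf$Wf[iL1[2], iL1[1]] <- 60
  linked <- simulate_network(netf, 0.5, events = ev)
  m_base <- mean(layer_trace(base, "L1")[2, 2000:5000])
  m_link <- mean(layer_trace(linked, "L1")[2, 2000:5000])
  expect_lt(m_link, m_base)
  # independent refined-step oracle
  oracle <- two_unit_oracle(wf_link = 60, dt = 1e-5, dur = 0.5, u_p = 450)
  expect_equal(m_link, oracle$mean_z2, tolerance = 0.1)
})

test_that("WM maintains a 50 ms cue for over 300 ms and resets on new input", {
  net <- build_network(n_features = 3)
  net$noise_sd_p[] <- 0; net$noise_sd_f[] <- 0
  wd <- wm_drive(data.frame(feature = c(1, 2), onset = c(0.05, 0.5)),
                 n_features = 3)
  sim <- simulate_network(net, 1.0, events = wd$events, resets = wd$resets)
  WM <- layer_trace(sim, "WM")
  # maintained well after cue offset (cue ends at 0.1 s)
  expect_gt(min(WM[1, 4000:4900]), 3)
  # extinguished shortly after the second cue, new feature active
  expect_lt(max(WM[1, 6000:9000]), 1)
  expect_gt(min(WM[2, 7000:9000]), 3)
  # no cue ever: all WM units stay at the noise floor
  sim0 <- simulate_network(net, 0.6, seed = 1)
  expect_lt(max(layer_trace(sim0, "WM")), 1)
})

test_that("time-constant scaling is exact for theta and monotone for gamma", {
  net <- build_network()
  expect_identical(scale_time_constants(net, "L1L2_fastGABA", 1)$unitpar,
                   net$unitpar)
  expect_error(scale_time_constants(net, "L1L2_fastGABA", -1), "positive")
  expect_error(scale_time_constants(net, "everything", 1), "unknown")
  # theta: factor k rescales the limit cycle exactly -> frequency base/k
  base <- theta_base_hz()
  n2 <- scale_time_constants(net, "theta_glutamatergic_and_slowGABA",
                             theta_factor(2.67))
  i <- layer_index(n2, "theta")
  u <- structure(as.list(n2$unitpar[i, ]), class = "tg_unit_params")
  s <- simulate_unit(u, 4)
  f <- as.numeric(dominant_frequency(s$z_p[s$t > 1], s$dt))
  expect_equal(f, 2.67, tolerance = 0.05)
  # gamma: larger time-constant factor -> lower intrinsic frequency
  freqs <- sapply(c(0.6, 1, 1.6), function(k) {
    g <- make_unit("gamma")
    g$wf <- g$wf / k; g$Gf <- g$Gf / k
    s <- simulate_unit(g, 1.5, u_p = 450)
    as.numeric(dominant_frequency(s$z_p[s$t > 0.5], s$dt))
  })
  expect_true(all(diff(freqs) < 0))
})

test_that("simulation traces have the right shape and bounds", {
  net <- build_network(n_features = 5)
  sim <- simulate_network(net, 0.25, seed = 3)
  expect_equal(ncol(sim$z), round(0.25 / net$dt))
  expect_true(all(sim$z >= 0 & sim$z <= 5))
})
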