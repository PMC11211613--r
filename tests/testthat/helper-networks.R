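# Shared fixtures: training the 226-unit network takes ~40 s, so the two
# canonical trained networks are built once per test session and reused.
.fixtures <- new.env()

trained_orth <- function() {
  if (is.null(.fixtures$orth)) {
    set <- make_orthogonal_set()
    net <- build_network(set)
    .fixtures$orth <- train_sequences(net, set, seed = 1)
  }
  .fixtures$orth
}

trained_nonorth <- function() {
  if (is.null(.fixtures$nonorth)) {
    set <- make_nonorthogonal_set()
    net <- build_network(set)
    .fixtures$nonorth <- train_sequences(net, set, seed = 1)
  }
  .fixtures$nonorth
}

# small mean-row helper over a reduced assessment
mean_row <- function(net, n_runs, theta_hz = NA, gamma_hz = NA, seed = 1) {
  if (!is.na(theta_hz))
    net <- scale_time_constants(net, "theta_glutamatergic_and_slowGABA",
                                theta_factor(theta_hz))
  if (!is.na(gamma_hz))
    net <- scale_time_constants(net, "L1L2_fastGABA",
                                fast_gamma_factor(gamma_hz, base_hz = 35))
  tab <- success_table(net, n_runs = n_runs, duration = 1, seed = seed)
  unname(tab["Mean", ])
}

# expose the internal parameter-row packing for unit-level tests
.unitpar_row_test <- function(u) {
  getFromNamespace(".unitpar_row", "thetagamma")(u)
}

# Independent two-unit oracle: plain-R Euler integration (refined step) of
# two gamma units where unit 1's pyramidal output drives unit 2's fast
# interneurons through a glutamatergic kernel with weight wf_link.
two_unit_oracle <- function(wf_link, dt = 1e-5, dur = 0.5, u_p = 450) {
  u <- unit_presets()$gamma
  S <- function(v) pmin(pmax(5 / (1 + exp(-u$r * (v - u$v0))), 0), 5)
  n <- round(dur / dt)
  y <- matrix(0, 2, 6); w <- matrix(0, 2, 6)
  G <- c(u$Ge, u$Ge, u$Gs, u$Gf, u$Ge, u$Ge)
  W <- c(u$we, u$we, u$ws, u$wf, u$we, u$we)
  z2 <- numeric(n)
  for (s in seq_len(n)) {
    zp <- zs <- ze <- zf <- numeric(2)
    for (i in 1:2) {
      vp <- u$Cpe * y[i, 2] - u$Cps * y[i, 3] - u$Cpf * y[i, 4] + y[i, 5]
      zp[i] <- S(vp)
      ze[i] <- S(u$Cep * y[i, 1])
      zs[i] <- S(u$Csp * y[i, 1])
    }
    for (i in 1:2) {
      vf <- u$Cfp * y[i, 1] - u$Cfs * y[i, 3] - u$Cff * y[i, 4] + y[i, 6]
      zf[i] <- S(vf)
    }
    z2[s] <- zp[2]
    up <- c(u_p, u_p)
    uf <- c(0, wf_link * zp[1])
    for (i in 1:2) {
      src <- c(zp[i], ze[i], zs[i], zf[i], up[i], uf[i])
      for (k in 1:6) {
        yk <- y[i, k]
        y[i, k] <- y[i, k] + dt * w[i, k]
        w[i, k] <- w[i, k] + dt * (G[k] * W[k] * src[k] -
                                     2 * W[k] * w[i, k] - W[k]^2 * yk)
      }
    }
  }
  sel <- seq(round(0.2 / dt), round(0.5 / dt))
  list(mean_z2 = mean(z2[sel]))
}
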