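#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fixed-step Euler integrator for a network of four-population neural-mass
// units coupled by three inter-unit synapse classes:
//   Wp : pyramidal -> pyramidal, through the target's glutamatergic kernel
//   Wf : pyramidal -> fast-GABA, through the target's glutamatergic kernel
//   Af : pyramidal -> fast-GABA, algebraic (zero-lag) coupling
//
// Per-unit state: six second-order synaptic kernels, each a (y, dy) pair.
//   k1 glu(z_p)   internal pyramidal output, drives e/s/f and the Cpp loop
//   k2 glu(z_e)   excitatory-interneuron output, drives p
//   k3 slow(z_s)  slow-GABA output, drives p and f
//   k4 fast(z_f)  fast-GABA output, drives p and f (self-inhibition)
//   k5 glu(u_p)   total external input to the pyramidal population
//   k6 glu(u_f)   total external input to the fast-GABA population
//
// unitpar columns (one row per unit):
//  0 Cpe  1 Cep  2 Csp  3 Cps  4 Cfp  5 Cfs  6 Cpf  7 Cff  8 Cpp
//  9 Ge  10 we  11 Gs  12 ws  13 Gf  14 wf  15 r  16 v0  17 tonic_p 18 tonic_f
//
// env_events rows: unit (0-based), pop (0 = p, 1 = f), step0, step1, amplitude
// (drive active for steps s with step0 <= s < step1).
//
// learn: 4 x 4 matrix, one row per plastic kind in the order
//   Wp(L1,L1), Wf(L1,L1), Af(L1,L1), Wp(L1,L2);
// columns: rate, th_post, th_pre (for Af: silence threshold), sat.
// Plastic updates act on a low-pass-filtered copy of z_p (time constant
// tau_learn) so that correlations are carried by burst rates, not by the
// instantaneous phase within a gamma cycle. With suppress_coupling the
// inter-unit synapses are removed from the dynamics (encoding under high
// acetylcholine: lateral and feedback synapses transiently suppressed)
// while plastic accumulation still runs.

static inline double sigm5(double v, double r, double v0) {
  double z = 5.0 / (1.0 + std::exp(-r * (v - v0)));
  if (z < 0.0) z = 0.0;
  if (z > 5.0) z = 5.0;
  return z;
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(arma::mat Wp, arma::mat Wf, arma::mat Af,
              const arma::mat& unitpar,
              const arma::mat& env_events,
              const arma::vec& noise_sd_p, const arma::vec& noise_sd_f,
              const arma::vec& unif_min, const arma::vec& unif_max,
              const arma::ivec& reset_step, const arma::ivec& reset_unit,
              int n_steps, double dt, double dt_ref,
              arma::mat state,
              const arma::ivec& record_units, int record_every,
              bool record_pops,
              bool plastic, const arma::mat& learn,
              const arma::ivec& idxL1, const arma::ivec& idxL2,
              double tau_learn, bool suppress_coupling) {
  const int N = unitpar.n_rows;
  if ((int)Wp.n_rows != N || (int)Wp.n_cols != N)
    stop("Wp dimensions do not match the number of units");
  if ((int)Wf.n_rows != N || (int)Af.n_rows != N)
    stop("Wf/Af dimensions do not match the number of units");
  if ((int)state.n_rows != N || state.n_cols != 12)
    stop("state must be a units x 12 matrix");
  if (dt <= 0) stop("dt must be positive");

  const arma::vec Cpe = unitpar.col(0), Cep = unitpar.col(1),
    Csp = unitpar.col(2), Cps = unitpar.col(3), Cfp = unitpar.col(4),
    Cfs = unitpar.col(5), Cpf = unitpar.col(6), Cff = unitpar.col(7),
    Cpp = unitpar.col(8), Ge = unitpar.col(9), we = unitpar.col(10),
    Gs = unitpar.col(11), ws = unitpar.col(12), Gf = unitpar.col(13),
    wf = unitpar.col(14), rr = unitpar.col(15), v0 = unitpar.col(16),
    tonic_p = unitpar.col(17), tonic_f = unitpar.col(18);

  // per-step zero-mean noise sd, scaled so spectra are dt-invariant
  const double nscale = std::sqrt(dt_ref / dt);

  const int n_rec = record_units.n_elem;
  const int n_samp = (n_steps + record_every - 1) / record_every;
  arma::mat trace_p(n_rec, n_samp, arma::fill::zeros);
  arma::mat trace_e, trace_s, trace_f;
  if (record_pops) {
    trace_e.zeros(n_rec, n_samp);
    trace_s.zeros(n_rec, n_samp);
    trace_f.zeros(n_rec, n_samp);
  }

  arma::vec zp(N), ze(N), zs(N), zf(N), vp(N), vf(N);
  arma::vec zlp(N, arma::fill::zeros); // low-pass z_p for plasticity
  arma::vec up(N), uf(N), envp(N), envf(N);
  const int n_ev = env_events.n_rows;
  int rp = 0; // reset pointer (reset_step must be sorted)

  for (int s = 0; s < n_steps; ++s) {
    // state resets (working-memory update): zero the named units' kernels
    while (rp < (int)reset_step.n_elem && reset_step(rp) == s) {
      state.row(reset_unit(rp)).zeros();
      ++rp;
    }

    arma::vec y1 = state.col(0), y2 = state.col(1), y3 = state.col(2),
      y4 = state.col(3), y5 = state.col(4), y6 = state.col(5);

    // membrane potentials and spike densities
    for (int i = 0; i < N; ++i) {
      double v = Cpe(i) * y2(i) - Cps(i) * y3(i) - Cpf(i) * y4(i)
        + y5(i) + Cpp(i) * y1(i);
      vp(i) = v;
      zp(i) = sigm5(v, rr(i), v0(i));
      ze(i) = sigm5(Cep(i) * y1(i), rr(i), v0(i));
      zs(i) = sigm5(Csp(i) * y1(i), rr(i), v0(i));
    }
    // fast interneurons see the zero-lag Af input from presynaptic pyramidal
    arma::vec afin = suppress_coupling ? arma::vec(N, arma::fill::zeros)
                                       : arma::vec(Af * zp);
    for (int i = 0; i < N; ++i) {
      double v = Cfp(i) * y1(i) - Cfs(i) * y3(i) - Cff(i) * y4(i)
        + y6(i) + afin(i);
      vf(i) = v;
      zf(i) = sigm5(v, rr(i), v0(i));
    }

    if (!zp.is_finite())
      stop("non-finite pyramidal spike density at step %d", s + 1);

    // record
    if (s % record_every == 0) {
      int c = s / record_every;
      for (int k = 0; k < n_rec; ++k) {
        int i = record_units(k);
        trace_p(k, c) = zp(i);
        if (record_pops) {
          trace_e(k, c) = ze(i);
          trace_s(k, c) = zs(i);
          trace_f(k, c) = zf(i);
        }
      }
    }

    // external inputs
    envp.zeros();
    envf.zeros();
    for (int e = 0; e < n_ev; ++e) {
      if (s >= env_events(e, 2) && s < env_events(e, 3)) {
        int i = (int)env_events(e, 0);
        if (env_events(e, 1) < 0.5) envp(i) += env_events(e, 4);
        else envf(i) += env_events(e, 4);
      }
    }
    if (suppress_coupling) {
      up = envp + tonic_p;
      uf = envf + tonic_f;
    } else {
      up = Wp * zp + envp + tonic_p;
      uf = Wf * zp + envf + tonic_f;
    }
    for (int i = 0; i < N; ++i) {
      if (noise_sd_p(i) > 0) up(i) += R::rnorm(0.0, noise_sd_p(i) * nscale);
      if (noise_sd_f(i) > 0) uf(i) += R::rnorm(0.0, noise_sd_f(i) * nscale);
      if (unif_max(i) > 0) up(i) += R::runif(unif_min(i), unif_max(i));
    }

    // Euler advance of the six kernel pairs
    for (int i = 0; i < N; ++i) {
      double src[6] = {zp(i), ze(i), zs(i), zf(i), up(i), uf(i)};
      double G[6] = {Ge(i), Ge(i), Gs(i), Gf(i), Ge(i), Ge(i)};
      double W[6] = {we(i), we(i), ws(i), wf(i), we(i), we(i)};
      for (int k = 0; k < 6; ++k) {
        double y = state(i, k), w = state(i, k + 6);
        state(i, k) = y + dt * w;
        state(i, k + 6) = w + dt * (G[k] * W[k] * src[k]
                                      - 2.0 * W[k] * w - W[k] * W[k] * y);
      }
    }

    // plasticity (training mode): update the four plastic blocks in place
    if (plastic) {
      zlp += (dt / tau_learn) * (zp - zlp);
      const int nL1 = idxL1.n_elem, nL2 = idxL2.n_elem;
      // Wp(L1,L1) and Wf(L1,L1): Hebbian, diagonal stays zero
      for (int a = 0; a < nL1; ++a) {
        int i = idxL1(a);
        double post_p = zlp(i) - learn(0, 1);
        double post_f = zlp(i) - learn(1, 1);
        double post_a = zlp(i) - learn(2, 1);
        for (int b = 0; b < nL1; ++b) {
          if (a == b) continue;
          int j = idxL1(b);
          if (post_p > 0) {
            double pre = zlp(j) - learn(0, 2);
            if (pre > 0) {
              double w = Wp(i, j) + learn(0, 0) * dt * post_p * pre;
              Wp(i, j) = (w > learn(0, 3)) ? learn(0, 3) : w;
            }
          }
          if (post_f > 0) {
            double pre = zlp(j) - learn(1, 2);
            if (pre > 0) {
              double w = Wf(i, j) + learn(1, 0) * dt * post_f * pre;
              Wf(i, j) = (w > learn(1, 3)) ? learn(1, 3) : w;
            }
          }
          if (post_a > 0) {
            double pre = learn(2, 2) - zlp(j); // anti-Hebb: silent presynaptic
            if (pre > 0) {
              double w = Af(i, j) + learn(2, 0) * dt * post_a * pre;
              Af(i, j) = (w > learn(2, 3)) ? learn(2, 3) : w;
            }
          }
        }
        // Wp(L1,L2): hetero-associative Hebbian
        double post_h = zlp(i) - learn(3, 1);
        if (post_h > 0) {
          for (int b = 0; b < nL2; ++b) {
            int j = idxL2(b);
            double pre = zlp(j) - learn(3, 2);
            if (pre > 0) {
              double w = Wp(i, j) + learn(3, 0) * dt * post_h * pre;
              Wp(i, j) = (w > learn(3, 3)) ? learn(3, 3) : w;
            }
          }
        }
      }
    }
  }

  List out = List::create(
    _["trace_p"] = trace_p,
    _["state"] = state,
    _["Wp"] = Wp, _["Wf"] = Wf, _["Af"] = Af);
  if (record_pops) {
    out["trace_e"] = trace_e;
    out["trace_s"] = trace_s;
    out["trace_f"] = trace_f;
  }
  return out;
}
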