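---
title: "Theta-gamma coupled sequence memory: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta-gamma coupled sequence memory: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`thetagamma` simulates episodic-sequence memory in a hippocampus-inspired
network of neural-mass units. A *feature* is one computational unit per
layer; an *episode* is a set of features that occur together; a *sequence*
is a temporally ordered list of episodes. The network stores sequences
during an encoding phase and replays them during retrieval using a
theta-gamma code: all features of one episode fire synchronously within one
gamma burst, successive episodes occupy successive gamma bursts, and the
whole sequence repeats inside the depolarized ("on") half of each theta
cycle.

### The computational unit

Each unit is a four-population neural mass: pyramidal cells, excitatory
interneurons, and slow- and fast-GABAergic interneurons. Every synaptic
pathway is a second-order kernel

$$\ddot y = G\,\omega\,z_{\mathrm{pre}} - 2\omega\,\dot y - \omega^2 y,$$

with gain $G$ (mV) and reciprocal time constant $\omega$ (1/s); population
firing is the sigmoid $z = 5/(1 + e^{-r(v - v_0)})$, bounded at 5 spikes/s
(the detection threshold used throughout is 70% of this ceiling, 3.5
spikes/s). Internal couplings $C_{ij}$ (first index post-synaptic) select
the unit's intrinsic rhythm:

* **gamma** — silent at rest; when driven, the pyramidal/fast-GABA loop
  produces a ~30–35 Hz limit cycle. The excitatory interneurons act as a
  burst amplifier ($C_{ep} = 80$, $C_{pe} = 40$) and the slow-GABA loop
  ($\omega_s = 20$/s) leaves ~50 ms of refractoriness after each burst.
* **theta** — an autonomous relaxation oscillator built from the
  pyramidal/slow-GABA loop under tonic drive, calibrated to exactly
  4.00 Hz. No fast-GABA pathway participates, so multiplying the
  glutamatergic and slow-GABA time constants by a factor $k$ (and dividing
  the gains by $k$, which preserves kernel area) rescales the limit cycle in
  time exactly: the 2.67, 5 and 6 Hz regimes are pure time rescalings.
* **wm** — a gamma unit with a pyramidal self-excitation loop
  ($C_{pp} = 80$) and no slow self-inhibition: a 50 ms cue ignites
  persistent activity that outlives the cue by far more than 300 ms and is
  extinguished by zeroing the unit state when a different cue arrives.

The unit parameterization is this package's own: it was calibrated once so
that the emergent behavior matches the intended operating points (intrinsic
rhythm bands, silent-at-rest gamma units, working-memory persistence and
reset, and the retrieval success profile described below), and it is not
revisited thereafter.

### Architecture

Three layers of 75 units (WM, L1, L2 — one unit per feature, features
replicated identically across layers) plus a single theta-generator unit.
Fixed, non-plastic wiring: diagonal feedforward WM→L1 and L1→L2
(feature-preserving), and a uniform excitatory synapse from the theta
generator to every L1 pyramidal population. L1 additionally carries a tonic
inhibitory bias on its pyramidal inputs, so it is inhibited at rest and
rhythmically disinhibited by the theta drive; replay is only possible while
the theta wave is high. The L1→L2 feedforward is strong enough to act as a
saturating relay: L2 faithfully reports L1's episode bursts and is the
network's output.

Inter-unit synapses come in three kinds, all originating from pyramidal
cells: `Wp` (glutamatergic, onto pyramidal targets), `Wf` (glutamatergic,
onto fast interneurons — a bi-synaptic, synchronizing inhibition), and `Af`
(onto fast interneurons with near-instantaneous dynamics — implemented as
algebraic zero-lag coupling, appropriate for sub-millisecond synapses at
the 0.1 ms integration step). The plastic synapses are exactly
`Wp` and `Wf` within L1, `Af` within L1, and `Wp` from L2 to L1; everything
else is fixed.

### Training

Encoding presents each sequence of $N$ episodes as $N+1$ steps of 250 ms;
step $k$ drives the pyramidal (and, weakly, the fast-interneuron)
populations of episode $k$'s features in L1 and episode $k-1$'s features in
L2, with null episodes at both ends; each episode pair is presented exactly
once. During encoding the inter-unit synapses are suppressed in the
dynamics (the high-acetylcholine regime in which lateral and feedback
synapses are transiently ineffective) while plastic accumulation runs, so
the learned weights depend only on the presented correlations and not on
the order of presentation.

The Hebbian rule potentiates a weight by
$\Delta W = \eta\,[\,\bar z_{\mathrm{post}} - \theta\,]_+\,[\,\bar z_{\mathrm{pre}} - \theta\,]_+\,dt$
and the anti-Hebbian rule (for `Af`) by
$\Delta A = \eta\,[\,\bar z_{\mathrm{post}} - \theta\,]_+\,[\,\theta_s - \bar z_{\mathrm{pre}}\,]_+\,dt$,
where $\bar z$ is a 20 ms low-pass of the pyramidal spike density —
correlations are carried by burst rates, not by instantaneous phase within
a gamma cycle. Two refinements keep the `Af` support exactly on
between-episode pairs of stored features: units that never participate in
any episode form no outgoing desynchronizing synapses, and co-members of
any episode are protected from anti-Hebbian potentiation (a feature shared
by two episodes must not be desynchronized from the partners of either).
Without the latter, a shared feature acquires desynchronizing input from
its own partners (they are silent while its other episode is presented) and
is then vetoed by its own episode's burst during retrieval.

Weights saturate per synapse and every unit's incoming sum per synapse kind
is capped (multiplicative row rescaling at the end of every presentation).
The caps are chosen so that saturation-then-normalization, not the learning
rate, sets the final values; per-synapse strength then falls with episode
richness, and a feature shared by two episodes ends with incoming weights
roughly half those of an unshared feature while still receiving enough
recurrent drive to ignite with either episode.

### Retrieval dynamics

A 50 ms cue ignites its WM unit, which persists and continuously drives the
corresponding L1 unit. At each theta upswing the cued unit ignites first,
recruits its episode partners through the within-episode `Wp`
(the partners' bursts overlap the cued unit's burst only partially, which
is why the *first* episode's strict simultaneity criterion fails in a
fraction of cycles), the episode's L2 image kicks the next episode's L1
units through the hetero-associative `Wp`, and `Af` enforces
winner-take-all so that exactly one episode occupies each gamma burst.
Episodes advance every ~23 ms; the theta wave's falling flank ends the
replay, which is what makes the *last* episodes of a sequence the first to
fail as theta accelerates. At 2.67 Hz the on-phase is long enough for the
sequence to restart within the same cycle. Shared features ignite with
their episode but a few ms later than distinctive ones.

### Cycle-by-cycle assessment

The theta generator's own noise-free trace is the clock. Cycles are
delimited by upward crossings through 30% of the trace range — below the
half-range point, so that replay triggered on the rising flank falls inside
the cycle it belongs to. An episode is recovered within a cycle iff all of
its features' L2 spike densities exceed 3.5 spikes/s simultaneously for at
least one integration step; an episode is correctly placed iff its first
simultaneous crossing is strictly later than that of every *detected*
earlier episode (an undetected first episode does not penalize later ones —
the alternative strict-prefix rule would force Episode-2 success below
Episode-1 success, which contradicts the target success profile). The
success table runs 10 cued simulations of 1.0 s per sequence with distinct
derived seeds and reports per-episode percentages with an unweighted mean
row.

### Functioning modes

Isolation modes disconnect L1 from WM and add positive uniform noise to the
L1 pyramidal inputs each step. *Imagination* keeps all synapses and adds
noise drawn from [100, 300] — calibrated once as a range at which the
isolated network spontaneously replays at least one full stored sequence
per second; *dreaming* adds 50% more noise ([150, 450]) and scales all
plastic synapses by 1/3; *schizophrenia* uses dreaming-level noise and
halves `Af` only. In dreaming, weakened attractors plus shared features
produce hybrid sequences (a prefix of one sequence joined at a shared
feature into another's continuation); on a fully orthogonal set no hybrid
can form. With halved desynchronization, distinct episodes fire
superimposed — the superposition score counts integration steps at which
two or more episodes that share no feature satisfy the full detection
conjunction simultaneously. The no-theta variant replaces the oscillating
theta drive with a constant input of equal temporal mean, removing the
cyclic structure of replay.

## Numerical choices

Explicit fixed-step Euler at `dt = 1e-4` s (halving `dt` moves the dominant
frequency estimates by well under 2%). All kernel states start at zero; at
least 0.2 s (0.5 s in the bundled protocols) is discarded before any
spectral or detection analysis. Zero-mean Gaussian noise is drawn per step
with the magnitude defined at the reference step and rescaled by
$\sqrt{dt_{\mathrm{ref}}/dt}$, so noise spectra are `dt`-invariant. Sigmoid
outputs are clamped to [0, 5] to guard rounding. Ties in first-crossing
times count as ordering failures. Cycles whose on-phase is cut by the end
of the simulated window are excluded from the denominator; retrieval runs
simulate a margin past the scored window so the final cycle is complete.

## What the generator emulates — and what it does not

The synthetic sequence sets reproduce the canonical three-sequence,
five-episode structure (episode sizes 4–6; the non-orthogonal variant
shares one or two features per affected episode, 20–35% of the episode).
Feature indices not pinned by the canonical description are assigned by a
deterministic packing (sequence 1 → lowest indices). Passing tests on these
sets demonstrate the associative mechanism under controlled sharing; they
do not demonstrate robustness to overlapping naturalistic inputs, to more
than ~5 episodes per theta cycle, or to concurrent storage of many more
sequences.

## Known limitations

* The theta relaxation wave has ~46% duty; the success-profile geometry it
  supports implies an episode pace of ~23 ms rather than a nominal
  ~28 ms gamma period. One visible consequence: accelerating gamma to
  ~45 Hz at theta 5 Hz rescues the fourth episode essentially completely,
  rather than partially, and fast-gamma runs rarely show foreign-sequence
  intrusions.
* At dreaming-level synapse reduction (×1/3) the cued retrieval mode no
  longer completes sequences — the ignition margins of this
  parameterization are narrower than the phenomenon requires, so
  reduced-synapse retrieval is a known gap rather than a supported regime.
* Working-memory persistence is tonic rather than gamma-oscillatory.
* The first episode's success rate at 2.67 Hz is lower than at 4 Hz (the
  cue fires on a slower-rising flank).

## Reproducing the tables

```{r}
library(thetagamma)
set <- make_orthogonal_set()
net <- train_sequences(build_network(set), set, seed = 1)
success_table(net, n_runs = 10, duration = 1, seed = 1)

# frequency transforms
net267 <- scale_time_constants(net, "theta_glutamatergic_and_slowGABA",
                               theta_factor(2.67))
net45  <- scale_time_constants(net, "L1L2_fastGABA",
                               fast_gamma_factor(45, base_hz = 35))
```

The problem sizes used throughout the package's own checks are the study
conditions: 226 units, 1.0 s scored windows, 10 (or fewer, with wider
sampling tolerances) runs per sequence.
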