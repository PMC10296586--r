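---
title: "Delay-coupled columns, k-dimensional clocks, and dynamical modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay-coupled columns, k-dimensional clocks, and dynamical modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clocknets)
```

## The model family

`clocknets` implements a two-tier picture of cortex-like dynamics.

At the lower tier, a **neural column** is a dense directed network of `n`
excitable–refractory neurons.  We model each neuron as leaky
integrate-and-fire with an absolute refractory period: the membrane
potential decays toward rest with time constant `leak_tau`, an arriving
spike adds the edge weight instantaneously, crossing the threshold emits a
spike and silences the neuron for `refractory` time units.  Every edge
carries its own real-valued transmission delay; the simulation is
event-driven with no time step, so deliveries happen at emission time plus
delay exactly.  The real-valued delays are not a numerical convenience —
they are the point.  Sums of delays along different directed walks are
generically all distinct, so signals arrive at a neuron at many distinct
times, and the collective dynamics winds like a torus flow whose
independent cycles are the long viable loops of the graph.

At the upper tier, each column is summarised by a **k-dimensional clock**:
`k` phases, each winding mod 2π at its own rate.  Clocks sit on a
**range-dependent grid**: each ordered pair of columns at Euclidean grid
distance `d` is wired with probability `min(1, β exp(−d/λ))`.  Coupling is
by delayed phase-resetting maps (PRMs): each edge carries a trigger (a
designated sender phase crossing an edge-specific value), a real-valued
delay, and an instantaneous map applied to the receiver's phases on
arrival.  The whole is a generalised Kuramoto system; between events the
flow is exactly linear, so the event-driven integrator is closed-form and
the only numerical error is double-precision rounding (the edge-free
winding test holds to 1e−9 rad over 10³ time units).

### Design choices in the dynamics

Several ingredients are under-determined by the level of description we
work from, and are declared package choices:

* **Neuron model.**  "Excitable and refractory" admits many models; we use
  leaky integrate-and-fire with an absolute refractory period as the
  simplest member of the class, isolated behind `neuron_params()` so that
  richer models can be swapped in.  Kicks delivered during the refractory
  window are discarded, the simplest absolute-refractory semantics.
* **Trigger condition.**  A single designated phase upward-crossing an
  edge-specific value — the simplest edge-parameterisable condition with
  closed-form next-crossing times.  The inequality is strict: a clock
  sitting exactly at its trigger fires after a full revolution.
* **PRM form.**  The default is an additive phase kick.  A second,
  contracting family is provided (`prm = "pull"`): each receiver phase is
  pulled toward an edge-specific target by `s·sin(target − φ)`.  The pull
  map is what lets the network state *retain a trace* of past forcing,
  which the preconditioning experiment needs; the additive kick, being an
  isometry of the torus, forgets nothing and aligns nothing.
* **Range kernel.**  `p(d) = min(1, β e^{−d/λ})`, one interpretable length
  scale; an optional hard cutoff radius is exposed.  The grid is flat (no
  torus wrap-around).
* **Delays.**  Uniform on `[τmin, τmax]` within columns; bridge delays
  between columns default to twice that range, reflecting longer axonal
  paths.  Both are configuration.
* **Event ordering.**  Events are processed in (time, edge id) order with
  a stable final tie-break.  This matters precisely when dead heats occur:
  under unit delays many deliveries are exactly simultaneous, and the
  deterministic order makes those runs replayable.

## Estimating the degrees of freedom k

`estimate_k()` reduces a multichannel recording to a scalar observable
(first principal component of the smoothed rates, or of the sines of the
sampled phases), delay-embeds it, and estimates the
Grassberger–Procaccia correlation dimension.  Two slope estimates are
computed from the pairwise-distance distribution (with a Theiler window
excluding temporally close pairs): a least-squares fit of `log C(r)` vs
`log r` over mid-range radii, and Takens' maximum-likelihood slope below a
small cutoff radius (the 2% distance quantile).  The reported dimension is
the **smaller** of the two.  The rationale: for clean attractors the
correlation slope approaches the dimension from above as `r` shrinks, so
the small-radius route is the less biased one; for noisy signals the
smallest radii are inside the noise ball, where the slope climbs toward
the embedding dimension, and the mid-range route is the meaningful one.
Taking the minimum tracks the scaling regime in both situations.  On
quasi-periodic torus signals with 1–3 incommensurate frequencies the
rounded estimate `k_hat` matches the true dimension in ≥ 90% of seeds at
the default settings (embedding dimension 8–10, ≤ 3000 embedded points,
Theiler window 10 samples).

Known limitations: the estimator is data-limited above dimension ≈ 5 at
these problem sizes (correlation sums need data roughly exponential in the
dimension), so large attractors are reported compressed rather than
faithfully.  Estimating `k ≈ 10` for a column of 10,000 neurons is out of
desk-scale reach; the scaling study therefore runs at `n ≤ 800`, where the
attained dimensions are small, and treats the large-`n` statement as
qualitative.

## The scaling study and its regime

`k_scaling_study()` simulates columns of increasing size under sustained
stimulation and regresses the mean rounded dimension on `log n`.  The
study conditions are package choices, made once and documented here:

* **Wiring budget per neuron fixed**: edge probability `out_degree / n`
  with `out_degree = 16`.  At fixed density, larger columns become
  mean-field-like and synchronise into a single global wave whose
  dimension does not grow; at fixed out-degree the loop structure stays
  sparse and loop diversity grows with `n`.
* **Near-critical gain**: each edge carries weight `gain/out_degree`
  threshold units with `gain = 3`, just above the ignition threshold.
  Saturated columns (every neuron firing at the refractory ceiling) have
  noise-dominated rates whose estimated dimension is flat in `n`.
* **Long refractory period** (2.5 time units, longer than most single
  delays, delays uniform on [0.5, 3]): short loops are not viable, so the
  dynamics is carried by longish delay cycles — the objects `k` counts.
* **Stimulation**: an ignition volley into a fifth of the neurons at
  `t = 0` plus a weak sustained Poisson drive (rate 0.3 on `n/20` units),
  which keeps every replicate alive without drowning the recurrent
  dynamics.
* **Observable**: 60 recorded neurons, rates binned at 0.25 time units and
  smoothed with a 0.25-unit Gaussian kernel — light smoothing, because
  heavy smoothing erases exactly the fine temporal structure that
  distinguishes a large column from a small one.
* **Record length grows with size**: `600·log2(n/50)` time units, since
  resolving a higher-dimensional attractor requires more data; the first
  40 time units are discarded as transient.

Under these conditions the mean `k_hat` rises from ≈ 3.7 at `n = 100` to
≈ 5 at `n = 800`, is non-decreasing in `n`, and its Spearman correlation
with `log n` is ≥ 0.9 (the tests and the acceptance script recompute
this).  A corollary checked alongside: `2·k(n) > k(2n)` — in degrees of
freedom per neuron it is better to have two half-size columns than one
double-size column, which is the efficiency argument for a cortex built
from many roughly equal columns.

## The unit-delay quench

`delay_quench_experiment()` simulates the same column twice per seed —
once with its real-valued delays, once with every delay forced to 1.0 —
under identical stimulation.  In a leaky integrate-and-fire network with
instantaneous kicks, every threshold crossing happens at a delivery
instant, so all spike times live in the additive closure of the stimulus
times and the edge delays.  With generic real delays those sums are all
distinct; with a common unit delay, alternative directed walks of equal
hop count arrive simultaneously (*dead heats*), the set of attainable
event times collapses onto a lattice, and the attained dimension drops
sharply — in the default regime (`n = 200`, density 0.2) from `k ≈ 3`–4 to
0–1, with the count of distinct arrival times falling by roughly an order
of magnitude.  The four-neuron diamond fixture shows the mechanism in
isolation: two equal-hop walks produce exactly 2 distinct arrival times at
the convergence neuron with real delays and exactly 1 with unit delays.
This is the foundational objection to uniformly clocked neuromorphic
designs that the quench experiment operationalises.

## Reverse-engineering modes

`run_experiment_battery()` applies each forcing regime `reps` times (fresh
sub-seeds, randomised initial phases) and records responses over the
observed units.  Pairwise comparison uses
`d = 1 − max_{|ℓ| ≤ max_lag} cor(...)` over the flattened unit × time
matrices at integer bin shifts — responses matter through their relative
timing, not their absolute alignment.  If a windowed vector has zero
variance its correlation term is 0 unless the two windows are identical
(then 1), which preserves identity-at-zero while avoiding 0/0.  Lag search
is over integer bins only; sub-bin alignment is out of scope.

Average-linkage agglomerative clustering of the dissimilarity matrix gives
the mode hierarchy; cutting at coarser levels yields unions of finer
clusters, and each mode is summarised by its medoid response.
Significance is assessed against a circular-shift surrogate null: each
record's time bins are rotated by an independent offset drawn uniformly
over *all* bins, including zero.  Because a structureless battery is
invariant in distribution under that group, observed and surrogate
statistics are exchangeable and the permutation p-value
`(1 + #{null ≥ obs}) / (1 + n_perm)` is exactly calibrated — the package's
embodiment of the warning that clustering "finds" structure even where
there is none.  With `n_perm = 39`, the rejection event at α = 0.05 is
attainable exactly, and the calibration test over 200 structureless
batteries observes a rejection rate inside [0.02, 0.09].

**Mode competition** is measured, not enforced: `mode_exclusivity()` maps
a windows × modes activation distribution to `1 − mean H/log M`, reaching
1 when one mode is active at a time.

## Preconditioning

The preconditioning probe asks whether a currently active mode biases the
interpretation of an ambiguous stimulus.  Mode assignment at run time is
nearest-medoid under the battery dissimilarity — a declared
operationalisation, since "a mode being active" has no canonical online
definition.  The ambiguous stimulus defaults to a 50/50 superposition of
two regimes' forcing events (`mix_regimes()`).

The dedicated fixture (`preconditioning_fixture()`) makes the memory
mechanism transparent: all phases wind at the common rate 1, so priming
for a whole number of periods returns the network exactly to the primed
pattern at the probe's onset; the ambiguous probe then resets the first
phase of every forced clock (supporting both modes equally), while the
remaining memory phases carry whatever the priming left behind.  Unprimed
runs start from uniform random phases and are assigned near-randomly;
primed runs match the primed mode's medoid on the memory channels.
Across 20 seeds the primed mode's assignment probability exceeds the
unprimed baseline in a clear majority of seeds (typically 15–20 of 20 in
the runs the acceptance script reproduces).  The report also carries
the entropy reduction of the assignment distribution in bits, reported
as-is (it may be negative).

## Problem sizes and reproducibility

All studies run at desk scale: columns up to `n = 800` (the full cortex
would have ~10⁴ neurons per column and ~10⁶ columns; the configuration
arithmetic for those scales is `state_dimension()`), clock networks of
~10 clocks, batteries of tens of experiments, 200 calibration batteries.
Every stochastic step takes an explicit seed, sub-seeds are derived from
master seeds via `derive_seeds()`, and identical parameters plus seed
reproduce networks, event logs and phase records bit-for-bit.  What
passing these tests shows — and what it does not — should be read
carefully: the synthetic columns demonstrate the package's claims about
*this model family* (delay-loop-driven winding dynamics, quench under
delay uniformisation, recoverable response modes); they do not establish
anything about biological recordings, which have non-stationarities,
measurement noise and cell-type heterogeneity that the generator does not
emulate.
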