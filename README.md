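# clocknets

Simulation and reverse-engineering tools for cortex-like
*network-of-networks* dynamics: dense spiking "columns" with real-valued
transmission delays, generalised Kuramoto networks of k-dimensional clocks
coupled by delayed phase-resetting maps, estimation of the number of
dynamical degrees of freedom *k* from recordings, and discovery of
hierarchical dynamical response "modes" from batteries of stimulation
experiments.

## The scientific problem

The cortex is organised as densely connected neural columns (~10⁴ neurons
each) coupled into a sparser, range-dependent column-to-column network, with
every neuron-to-neuron transmission incurring its own real-valued delay.
Two consequences of that architecture drive this package:

1. **Columns behave like k-dimensional clocks.**  A single column's
   collective dynamics winds like a flow on a k-torus whose independent
   cycles are the long viable delay loops of its graph, with *k* growing
   like log *n*.  So the whole cortex can be summarised as a *generalised
   Kuramoto system*: N clocks, each with k phases winding mod 2π, coupled
   by directed edges that fire when a sender phase crosses an
   edge-dependent trigger, incur a delay τ, and apply an instantaneous
   phase-resetting map (PRM) to the receiver,

   φ̇ᵢ = ωᵢ  between events,  φⱼ ← Mₑ(φⱼ) on arrival of edge e at j,

   giving ~10⁷ state variables for a cortex-scale model (10 phases × 10⁶
   columns) instead of ≥ 10¹⁰ (one per neuron).

2. **Real-valued delays carry the capacity.**  If all delays are forced to
   a single unit value — as in uniformly clocked neuromorphic chips —
   alternative directed walks of equal hop count arrive simultaneously
   ("dead heats") and the attained *k* quenches.

On top of the simulators sits a reverse-engineering pipeline: batteries of
stimulation experiments, an offset-tolerant response dissimilarity,
hierarchical clustering into dynamical *modes* with permutation
significance, and measures of mode competition and of *preconditioning* —
how an active mode biases the response to the next, ambiguous stimulus.

The estimator at the core is the Grassberger–Procaccia correlation
dimension of a delay-embedded observable: C(r) ∝ r^D on the attractor,
with D read from the slope of log C(r) against log r (plus a Takens
maximum-likelihood refinement at small radii), and k̂ = round(D).

## A worked example

```r
library(clocknets)

# a 200-neuron column, sparse wiring, real-valued delays in [0.5, 3]
net <- generate_column_network(200, density = 16/200, delay_range = c(0.5, 3),
                               weight = 3/16, seed = 7)
net
#> column_network: 200 neurons, 3178 directed edges (density 0.08)
#>   delays in [0.5, 3] time units, seed 7

stim <- stimulus_regime("ignite",
  spikes  = data.frame(unit = 0:39, time = 0),
  poisson = data.frame(unit = 0:9, rate = 0.3, start = 0, end = 600),
  seed = 7)
tr <- simulate_spiking(net, neuron_params(refractory = 2.5), stim,
                       t_end = 600, seed = 7)
summary(tr)
#> spike_train over [0, 600]: 31185 spikes, mean rate 0.26 per unit-time
#>   inter-spike intervals: min 2.502, median 3.769

estimate_k(bin_and_smooth(tr, 0.25, 0.25), embed_dim = 10)
#> k_estimate: k_hat = 3 (correlation dimension 3.331, grassberger-procaccia)
#>   embedding: dim 10, lag 3 samples, Theiler 10, 2373 points, 2790703 pairs
```

The inter-spike-interval floor of 2.5 is the refractory period; the
estimated k̂ = 3 says the column's collective rate dynamics occupies a
roughly 3-dimensional torus-like attractor.  Forcing every delay in the
same column to 1.0 (`delay_quench_experiment()`) collapses k̂ to 0–1 and
cuts the number of distinct signal arrival times by an order of magnitude.

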