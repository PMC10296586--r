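# Small named systems used across examples, tests and the reverse-engineering
# studies: each instantiates one of the package's core scenarios at toy scale
# and is reproducible from its embedded seed.

#' Quasi-periodic torus test signal
#'
#' A sum of `j` sinusoids with pairwise incommensurate frequencies
#' (1, sqrt(2), sqrt(5), ...) and random initial phases: a trajectory dense
#' on a `j`-torus, whose correlation dimension is exactly `j`.  The default
#' record lengthens with `j`, since resolving a higher-dimensional attractor
#' needs more data.
#'
#' @param j number of incommensurate frequencies (1..4).
#' @param dt sampling interval.
#' @param t_end record length (default `300 * j` time units).
#' @param seed seed for the initial phases.
#' @return numeric vector of samples.
#' @export
make_torus_signal <- function(j, dt = 0.05, t_end = 300 * j, seed = 1) {
  j <- check_count(j, "j")
  if (j > 4) stop_invalid("j must be <= 4")
  freqs <- c(1, sqrt(2), sqrt(5), sqrt(11))[seq_len(j)]
  ph <- with_seed(seed, runif(j, 0, 2 * pi))
  t <- seq(0, t_end, by = dt)
  rowSums(vapply(seq_len(j), function(i) sin(freqs[i] * t + ph[i]),
                 numeric(length(t))))
}

#' Dead-heat diamond network
#'
#' Four neurons A=0, B=1, C=2, D=3 wired A->B->D and A->C->D: two parallel
#' directed walks of equal hop count.  With generic real delays a source spike
#' at A produces two distinct arrival times at D; with all delays equal to 1
#' the two walks dead-heat and only one arrival time remains.
#'
#' @param delays the four delays for edges A->B, A->C, B->D, C->D.
#' @return list with `network` (`column_network`), `params`
#'   ([neuron_params()], suprathreshold single-kick weights), and `stimulus`
#'   (one forced spike into A at t = 0).
#' @export
dead_heat_fixture <- function(delays = c(1.1, 1.2, 1.3, 1.6)) {
  edges <- data.frame(source = c(0L, 0L, 1L, 2L),
                      target = c(1L, 2L, 3L, 3L),
                      weight = 1, delay = delays)
  net <- structure(list(n = 4L, edges = edges, density = NA_real_,
                        delay_range = range(delays), weight = 1,
                        inhibitory_frac = 0, seed = 0L),
                   class = "column_network")
  list(network = net,
       params = neuron_params(threshold = 1, reset = 0, rest = 0,
                              leak_tau = 5, refractory = 0.5),
       stimulus = stimulus_regime("poke-A",
                                  spikes = data.frame(unit = 0L, time = 0)))
}

#' Three-neuron directed ring
#'
#' A suprathreshold ring 0 -> 1 -> 2 -> 0 with delays summing to 4.0; a
#' single forced spike makes the ring self-sustaining with period exactly
#' 4.0 time units.
#'
#' @param delays per-edge delays (default `c(1.1, 1.3, 1.6)`).
#' @return list with `network`, `params`, `stimulus` as in
#'   [dead_heat_fixture()].
#' @export
ring_fixture <- function(delays = c(1.1, 1.3, 1.6)) {
  edges <- data.frame(source = 0:2, target = c(1L, 2L, 0L),
                      weight = 1, delay = delays)
  net <- structure(list(n = 3L, edges = edges, density = NA_real_,
                        delay_range = range(delays), weight = 1,
                        inhibitory_frac = 0, seed = 0L),
                   class = "column_network")
  list(network = net,
       params = neuron_params(threshold = 1, reset = 0, rest = 0,
                              leak_tau = 5, refractory = 0.5),
       stimulus = stimulus_regime("poke-0",
                                  spikes = data.frame(unit = 0L, time = 0)))
}

# periodic reset train into a set of clocks: the canonical strong forcing
# used by the battery fixtures (resets entrain every forced phase regardless
# of initial conditions)
reset_train <- function(clocks, t_end, period, value, phases = 1:3,
                        offset = 0) {
  times <- seq(offset, t_end, by = period)
  grid <- expand.grid(phase = as.integer(phases), time = times,
                      clock = as.integer(clocks))
  data.frame(clock = grid$clock, time = grid$time, phase = grid$phase,
             value = (value + 1.3 * (grid$phase - 1)) %% (2 * pi),
             mode = "reset")
}

#' Clock-network battery fixture
#'
#' A small range-dependent grid of k-dimensional clocks with contracting
#' (pull) phase-resetting couplings, plus three forcing regimes that entrain
#' disjoint clock subsets with periodic phase resets at distinct periods.
#' Responses to the three regimes form three well-separated dynamical modes.
#'
#' @param rows,cols grid size.
#' @param k phases per clock.
#' @param t_end horizon the regimes cover.
#' @param seed seed for the network.
#' @return list with `network` (`clock_network`), `regimes` (list of three
#'   [clock_stimulus()]), `t_end`, and `sample_dt`.
#' @export
clock_battery_fixture <- function(rows = 3, cols = 3, k = 3, t_end = 40,
                                  seed = 1) {
  outer <- generate_range_dependent_grid(rows, cols, beta = 0.9, lambda = 1.2,
                                         seed = seed)
  net <- generate_clock_network(outer, k = k, rate_range = c(0.8, 1.6),
                                delay_range = c(0.4, 1.2), prm = "pull",
                                pull_strength = 0.8, seed = seed)
  nc <- net$n_clocks
  sets <- split(0:(nc - 1), rep_len(1:3, nc))
  periods <- c(2.1, 2.9, 3.7)
  values <- c(0.5, 2.5, 4.5)
  regimes <- lapply(1:3, function(i)
    clock_stimulus(paste0("regime", LETTERS[i]),
                   reset_train(sets[[i]], t_end, periods[i], values[i],
                               phases = seq_len(k))))
  list(network = net, regimes = regimes, t_end = t_end, sample_dt = 0.25)
}

#' Deterministic fixture suite
#'
#' Bundles the named small systems used throughout the package — the
#' dead-heat diamond, the three-neuron ring, the three-regime clock battery,
#' and quasi-periodic torus test signals for j = 1..3 — all reproducible
#' from the given seed.
#'
#' @param seed master seed.
#' @return a named list of fixtures.
#' @export
make_fixture_suite <- function(seed = 1) {
  list(dead_heat = dead_heat_fixture(),
       ring = ring_fixture(),
       clock_battery = clock_battery_fixture(seed = seed),
       torus_signals = lapply(1:3, function(j)
         make_torus_signal(j, seed = seed + j)))
}
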