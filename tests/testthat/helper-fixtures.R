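# In-code fixtures shared across the test files.

# two neurons A -> B with a single suprathreshold edge
two_neuron_chain <- function(delay = 1.7, weight = 1) {
  structure(list(
    n = 2L,
    edges = data.frame(source = 0L, target = 1L, weight = weight,
                       delay = delay),
    density = NA_real_, delay_range = c(delay, delay), weight = weight,
    inhibitory_frac = 0, seed = 0L),
    class = "column_network")
}

chain_params <- function(refractory = 1)
  neuron_params(threshold = 1, reset = 0, rest = 0, leak_tau = 5,
                refractory = refractory)

poke <- function(unit = 0L, times = 0)
  stimulus_regime("poke", spikes = data.frame(unit = unit, time = times))

# hand-built outer network (positions on a line), for clock constructions
line_outer <- function(edges, n) {
  structure(list(rows = 1L, cols = n,
                 positions = data.frame(id = 0:(n - 1), row = 0,
                                        col = 0:(n - 1)),
                 edges = edges, beta = 1, lambda = 1, cutoff = Inf,
                 seed = 0L),
            class = "outer_network")
}

# clock network built by hand: k = 1 per clock, explicit edge table
manual_clock_net <- function(n, phases0, rates, edges, prm_kicks) {
  outer <- line_outer(data.frame(source = edges$sender,
                                 target = edges$receiver), n)
  structure(list(n_clocks = n, k = rep(1L, n),
                 phases0 = matrix(phases0, ncol = 1),
                 rates = matrix(rates, ncol = 1),
                 edges = edges, prm_type = "kick",
                 prm_val = matrix(prm_kicks, ncol = 1),
                 pull_strength = 0, outer = outer, seed = 0L),
            class = "clock_network")
}

# battery of records with three planted response patterns plus noise
planted_records <- function(n_per = 3, units = 4, bins = 60, snr = 8,
                            seed = 1) {
  set.seed(seed)
  templates <- lapply(1:3, function(i) matrix(rnorm(units * bins), units, bins))
  recs <- list()
  for (g in 1:3) for (r in seq_len(n_per)) {
    m <- templates[[g]] * snr + matrix(rnorm(units * bins), units, bins)
    recs[[length(recs) + 1]] <- response_record(
      sprintf("g%d#%d", g, r), paste0("g", g), m, 1)
  }
  recs
}

noise_records <- function(E = 8, units = 3, bins = 40, seed = 1) {
  set.seed(seed)
  lapply(seq_len(E), function(i)
    response_record(paste0("n", i), paste0("r", i),
                    matrix(rnorm(units * bins), units, bins), 1))
}

# memoised heavyweight computations shared between acceptance blocks
.cache <- new.env(parent = emptyenv())

cached_scaling_study <- function() {
  if (is.null(.cache$scaling))
    .cache$scaling <- k_scaling_study(c(100, 200, 400, 800), reps = 10,
                                      seed = 1)
  .cache$scaling
}
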