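test_that("a forced spike propagates along a delayed chain exactly", {
  tr <- simulate_spiking(two_neuron_chain(1.7), chain_params(), poke(),
                         t_end = 10, record_deliveries = TRUE)
  expect_equal(tr$events$unit, c(0L, 1L))
  expect_equal(tr$events$time[1], 0)
  expect_lt(abs(tr$events$time[2] - 1.7), 1e-9)
  # the delivery happens at emission + delay exactly
  expect_identical(tr$deliveries$time, 0 + 1.7)
})

test_that("the absolute refractory period absorbs close inputs", {
  tr <- simulate_spiking(two_neuron_chain(1.7), chain_params(refractory = 1),
                         poke(times = c(0, 0.3)), t_end = 10)
  expect_equal(sum(tr$events$unit == 0), 1)
})

test_that("a suprathreshold ring self-sustains with the delay-sum period", {
  fx <- ring_fixture(delays = c(1.1, 1.3, 1.6))   # period 4.0
  tr <- simulate_spiking(fx$network, fx$params, fx$stimulus, t_end = 21)
  # hand-computed schedule for > 5 periods
  t0 <- c(0, 1.1, 2.4)                      # first pass through the ring
  sched <- data.frame(unit = rep(0:2, 6),
                      time = rep(t0, 6) + rep(4 * (0:5), each = 3))
  sched <- sched[sched$time <= 21, ]
  sched <- sched[order(sched$time, sched$unit), ]
  expect_equal(nrow(tr$events), nrow(sched))
  expect_equal(tr$events$unit, sched$unit)
  expect_equal(tr$events$time, sched$time, tolerance = 1e-9)
})

test_that("no excitation means no spikes, and no spike precedes the stimulus", {
  net <- generate_column_network(20, 0.3, seed = 4)
  p <- chain_params()
  empty <- stimulus_regime("none", spikes = data.frame(unit = integer(),
                                                       time = numeric()))
  expect_equal(nrow(simulate_spiking(net, p, empty, t_end = 10)$events), 0)
  late <- simulate_spiking(net, p, poke(unit = 0:4, times = 2), t_end = 10)
  if (nrow(late$events)) expect_true(min(late$events$time) >= 2)
})

test_that("inter-spike intervals respect the refractory period everywhere", {
  for (s in 1:3) {
    net <- generate_column_network(60, 0.25, c(0.5, 2), weight = 0.4,
                                   seed = s)
    p <- neuron_params(refractory = 0.8)
    stim <- stimulus_regime("drive",
      poisson = data.frame(unit = 0:9, rate = 2, start = 0, end = 30),
      seed = s)
    tr <- simulate_spiking(net, p, stim, t_end = 30, seed = s)
    isi <- unlist(lapply(split(tr$events$time, tr$events$unit), diff))
    if (length(isi)) expect_true(min(isi) >= 0.8 - 1e-12)
  }
})

test_that("simulation replays identically from the same seed", {
  net <- generate_column_network(40, 0.3, weight = 0.5, seed = 6)
  stim <- stimulus_regime("drive",
    poisson = data.frame(unit = 0:4, rate = 1, start = 0, end = 20), seed = 3)
  a <- simulate_spiking(net, chain_params(), stim, 20, seed = 11,
                        record_deliveries = TRUE)
  b <- simulate_spiking(net, chain_params(), stim, 20, seed = 11,
                        record_deliveries = TRUE)
  expect_identical(a$events, b$events)
  expect_identical(a$deliveries, b$deliveries)
})

test_that("invalid simulation inputs raise informative errors", {
  net <- two_neuron_chain()
  expect_error(simulate_spiking(net, chain_params(), poke(), t_end = 0),
               "t_end")
  expect_error(simulate_spiking(net, chain_params(), poke(unit = 99L), 10),
               "99")
  expect_error(neuron_params(threshold = 0, rest = 0), "threshold")
})

test_that("distinct arrival counts expose dead heats under unit delays", {
  fx <- dead_heat_fixture()
  real <- simulate_spiking(fx$network, fx$params, fx$stimulus, 10,
                           record_deliveries = TRUE)
  expect_equal(count_distinct_arrival_times(real, units = 3), 2L)

  unit_net <- fx$network
  unit_net$edges$delay <- rep(1, 4)
  unit <- simulate_spiking(unit_net, fx$params, fx$stimulus, 10,
                           record_deliveries = TRUE)
  expect_equal(count_distinct_arrival_times(unit, units = 3), 1L)

  # dead-heat property: unit-delay counts never exceed real-delay counts
  expect_lte(count_distinct_arrival_times(unit),
             count_distinct_arrival_times(real))
  expect_equal(count_distinct_arrival_times(
    data.frame(unit = integer(), time = numeric())), 0L)
})
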