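test_that("winding advances phases linearly modulo 2*pi", {
  cl <- kclock(c(0, pi / 2), c(1, 0.5))
  expect_equal(wind(cl, 0), cl$phases)
  cl2 <- kclock(c(1, 2), c(1, 2))
  expect_equal(wind(cl2, 2 * pi), cl2$phases, tolerance = 1e-12)
  expect_equal(wind(cl, 3), c(3 %% (2 * pi), pi / 2 + 1.5), tolerance = 1e-12)
  expect_error(wind(cl, -1), "dt")
})

test_that("next trigger crossings are strict and closed-form", {
  cl <- kclock(c(1.2), c(1))
  expect_equal(next_trigger_time(cl, c(1, 1.2), t_now = 5), 5 + 2 * pi,
               tolerance = 1e-9)
  cl2 <- kclock(c(3 * pi / 2), c(pi))
  expect_equal(next_trigger_time(cl2, c(1, 0)), 0.5, tolerance = 1e-12)
  cl0 <- kclock(c(0), c(0))
  expect_error(next_trigger_time(cl0, c(1, 1)), "zero rate")
})

test_that("additive phase kicks compose and wrap", {
  expect_equal(apply_prm(c(1, 2), c(0, 0)), c(1, 2))
  expect_equal(apply_prm(c(2 * pi - 0.1, 0), c(0.2, 0)), c(0.1, 0),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:10) {
    ph <- runif(4, 0, 2 * pi); d1 <- runif(4, -3, 3); d2 <- runif(4, -3, 3)
    expect_equal(apply_prm(apply_prm(ph, d1), d2),
                 apply_prm(ph, (d1 + d2) %% (2 * pi)), tolerance = 1e-12)
  }
  expect_error(apply_prm(c(1, 2), c(1)), "length")
})

test_that("edge-free networks wind exactly along the closed form", {
  g <- generate_range_dependent_grid(2, 2, beta = 0, lambda = 1, seed = 1)
  net <- generate_clock_network(g, k = 3, seed = 2)
  rec <- simulate_clock_network(net, t_end = 50, sample_dt = 0.5)
  expected <- vapply(rec$times, function(t)
    (as.numeric(t(net$phases0)) + as.numeric(t(net$rates)) * t) %% (2 * pi),
    numeric(12))
  expect_lt(max(abs(rec$phases - expected)), 1e-9)
  expect_true(all(rec$phases >= 0 & rec$phases < 2 * pi))
})

test_that("a single coupled edge follows the crossing-count oracle", {
  edges <- data.frame(sender = 0L, receiver = 1L, trigger_phase = 1L,
                      trigger_value = 0, delay = 0.7)
  net <- manual_clock_net(2, phases0 = c(1, 2), rates = c(1, 1),
                          edges = edges, prm_kicks = 0.3)
  rec <- simulate_clock_network(net, t_end = 50, sample_dt = 0.5)
  emits <- (2 * pi - 1) + 2 * pi * (0:20)
  oracle <- vapply(rec$times, function(t)
    (2 + t + 0.3 * sum(emits <= t - 0.7)) %% (2 * pi), numeric(1))
  expect_lt(max(abs(rec$phases[2, ] - oracle)), 1e-9)
})

test_that("emission times increase and arrivals equal emission plus delay", {
  g <- generate_range_dependent_grid(3, 3, beta = 0.8, lambda = 1.5, seed = 7)
  net <- generate_clock_network(g, k = 2, seed = 7)
  rec <- simulate_clock_network(net, t_end = 40, sample_dt = 1)
  ev <- rec$events
  expect_gt(nrow(ev), 0)
  expect_identical(ev$arrival_time,
                   ev$emit_time + net$edges$delay[ev$edge + 1L])
  for (e in unique(ev$edge)) {
    tt <- ev$emit_time[ev$edge == e]
    if (length(tt) > 1) expect_true(all(diff(tt) > 0))
  }
})

test_that("clock simulation replays identically", {
  g <- generate_range_dependent_grid(2, 3, beta = 0.8, lambda = 1.5, seed = 3)
  net <- generate_clock_network(g, k = 2, prm = "pull", seed = 3)
  stim <- clock_stimulus("s", data.frame(clock = 0L, time = c(1, 2.5),
                                         phase = 1L, value = 1, mode = "kick"))
  a <- simulate_clock_network(net, stim, 30, sample_dt = 0.5,
                              initial_phases = "random", seed = 12)
  b <- simulate_clock_network(net, stim, 30, sample_dt = 0.5,
                              initial_phases = "random", seed = 12)
  expect_identical(a$phases, b$phases)
  expect_identical(a$events, b$events)
})

test_that("unit delays collapse distinct arrival times in clock networks", {
  # A drives twin clocks B and C identically; B and C each drive D.  With
  # generic delays on A->B vs A->C the twins desynchronise and D hears two
  # arrival streams; with all delays unity they stay in perfect lockstep.
  build <- function(delays) {
    edges <- data.frame(sender = c(0L, 0L, 1L, 2L),
                        receiver = c(1L, 2L, 3L, 3L),
                        trigger_phase = 1L,
                        trigger_value = c(0, 0, 1, 1),
                        delay = delays)
    manual_clock_net(4, phases0 = c(0.5, 2, 2, 4), rates = c(1.3, 1, 1, 1),
                     edges = edges, prm_kicks = c(0.8, 0.8, 0.4, 0.4))
  }
  real <- simulate_clock_network(build(c(1.1, 1.7, 1.3, 1.6)), t_end = 60,
                                 sample_dt = 1)
  unit <- simulate_clock_network(build(rep(1, 4)), t_end = 60, sample_dt = 1)
  n_real <- count_distinct_arrival_times(real, units = 3)
  n_unit <- count_distinct_arrival_times(unit, units = 3)
  expect_lt(n_unit, n_real)
})

test_that("state-variable counts multiply units by phases", {
  expect_identical(state_dimension(1e6, 10), 1e7)
  expect_identical(state_dimension(1e10, 1), 1e10)
  expect_identical(state_dimension(1, 3), 3)
  expect_error(state_dimension(0, 1), "units")
})

test_that("stimulus validation names the offending clock", {
  g <- generate_range_dependent_grid(2, 2, 0.5, 1, seed = 1)
  net <- generate_clock_network(g, k = 2, seed = 1)
  bad <- clock_stimulus("bad", data.frame(clock = 7L, time = 1, phase = 1L,
                                          value = 1))
  expect_error(simulate_clock_network(net, bad, 10, sample_dt = 1), "7")
})
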