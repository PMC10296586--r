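test_that("binning counts spikes exactly and conserves totals", {
  empty <- structure(list(events = data.frame(unit = integer(),
                                              time = numeric()),
                          t_end = 10, observed = 0:2),
                     class = "spike_train")
  sig <- bin_and_smooth(empty, 1)
  expect_true(all(sig$rates == 0))
  expect_equal(dim(sig$rates), c(3, 10))

  one <- structure(list(events = data.frame(unit = 0L, time = 0.5),
                        t_end = 5, observed = 0L),
                   class = "spike_train")
  sig1 <- bin_and_smooth(one, 1)
  expect_equal(as.numeric(sig1$counts), c(1, 0, 0, 0, 0))

  set.seed(2)
  tr <- structure(list(events = data.frame(unit = sample(0:3, 200, TRUE),
                                           time = runif(200, 0, 20)),
                       t_end = 20, observed = 0:3),
                  class = "spike_train")
  tr$events <- tr$events[order(tr$events$time), ]
  sig2 <- bin_and_smooth(tr, 0.7, kernel_width = 1)
  nb <- floor(20 / 0.7)
  in_window <- sum(tr$events$time < nb * 0.7)
  expect_equal(sum(sig2$counts), in_window)
  expect_error(bin_and_smooth(tr, 0), "bin_width")
})

test_that("constant recordings have zero degrees of freedom", {
  expect_equal(estimate_k(rep(3.2, 2000))$k_hat, 0L)
})

test_that("the correlation dimension recovers circles and 2-tori", {
  t <- seq(0, 400, by = 0.05)
  e1 <- estimate_k(sin(t))
  expect_equal(e1$k_hat, 1L)
  e2 <- estimate_k(make_torus_signal(2, seed = 5))
  expect_equal(e2$k_hat, 2L)
})

test_that("the estimate is invariant to affine rescaling", {
  y <- make_torus_signal(2, seed = 9)
  a <- estimate_k(y)
  b <- estimate_k(5 * y + 3)
  expect_equal(a$k_hat, b$k_hat)
  expect_equal(a$dim_raw, b$dim_raw, tolerance = 1e-10)
})

test_that("phase records of an uncoupled 3-phase clock embed as a 3-torus", {
  outer <- line_outer(data.frame(source = integer(), target = integer()), 1)
  net <- structure(list(n_clocks = 1L, k = 3L,
                        phases0 = matrix(c(0.3, 1.1, 4.0), 1),
                        rates = matrix(c(1, sqrt(2), sqrt(5)), 1),
                        edges = data.frame(sender = integer(),
                                           receiver = integer(),
                                           trigger_phase = integer(),
                                           trigger_value = numeric(),
                                           delay = numeric()),
                        prm_type = "kick",
                        prm_val = matrix(numeric(0), 0, 3),
                        pull_strength = 0, outer = outer, seed = 0L),
                   class = "clock_network")
  rec <- simulate_clock_network(net, t_end = 900, sample_dt = 0.05)
  expect_equal(estimate_k(rec)$k_hat, 3L)
})

test_that("too-short recordings raise an insufficient-data error", {
  expect_error(estimate_k(sin(seq(0, 5, by = 0.05))), "need >=")
})

test_that("a single-size scaling study yields one row without trend stats", {
  res <- k_scaling_study(40, reps = 2, t_end = 250, seed = 3)
  expect_equal(nrow(res), 1)
  expect_null(attr(res, "spearman"))
  expect_true(is.data.frame(attr(res, "runs")))
})

test_that("identical delay assignments give identical quench arms", {
  net <- generate_column_network(60, 16 / 60, c(0.5, 3), weight = 3 / 16,
                                 seed = 2)
  net$edges$delay <- rep(1, nrow(net$edges))    # both arms now identical
  p <- neuron_params(refractory = 2.5)
  stim <- stimulus_regime("drive",
    spikes = data.frame(unit = 0:11, time = 0),
    poisson = data.frame(unit = 0:2, rate = 0.3, start = 0, end = 250),
    seed = 1)
  q <- delay_quench_experiment(net, p, stim, seeds = c(4, 5), t_end = 250)
  expect_equal(q$k_real, q$k_unit)
  expect_equal(q$arrivals_real, q$arrivals_unit)
  expect_equal(attr(q, "fraction_quenched"), 1)
})
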