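test_that("a battery produces labelled, replayable records", {
  fx <- clock_battery_fixture(seed = 2)
  recs <- run_experiment_battery(fx$network, fx$regimes, reps = 5,
                                 t_end = fx$t_end,
                                 sample_dt = fx$sample_dt, seed = 10)
  expect_length(recs, 15)
  expect_equal(table(vapply(recs, function(r) r$regime, character(1))),
               table(rep(c("regimeA", "regimeB", "regimeC"), each = 5)))
  recs2 <- run_experiment_battery(fx$network, fx$regimes, reps = 5,
                                  t_end = fx$t_end,
                                  sample_dt = fx$sample_dt, seed = 10)
  expect_identical(lapply(recs, `[[`, "mat"), lapply(recs2, `[[`, "mat"))
})

test_that("a one-rep battery equals a direct simulation at its sub-seed", {
  fx <- clock_battery_fixture(seed = 2)
  reg <- fx$regimes[1]
  recs <- run_experiment_battery(fx$network, reg, reps = 1, t_end = fx$t_end,
                                 sample_dt = fx$sample_dt, seed = 21)
  sub <- derive_seeds(21, 1)
  direct <- simulate_clock_network(fx$network, reg[[1]], fx$t_end,
                                   sample_dt = fx$sample_dt,
                                   initial_phases = "random", seed = sub)
  expect_identical(recs[[1]]$mat, sin(direct$phases))
})

test_that("the dissimilarity is zero for self and shifted copies", {
  set.seed(8)
  base <- matrix(rnorm(5 * 70), 5, 70)
  r1 <- response_record("a", "x", base[, 1:60], 1)
  r2 <- response_record("b", "x", base[, 4:63], 1)   # r1 shifted by 3 bins
  expect_equal(response_dissimilarity(r1, r1, max_lag = 5), 0,
               tolerance = 1e-12)
  expect_lt(response_dissimilarity(r1, r2, max_lag = 5), 1e-10)
  expect_gt(response_dissimilarity(r1, r2, max_lag = 2), 0.1)
})

test_that("independent noise responses are near-orthogonal", {
  set.seed(4)
  r1 <- response_record("a", "x", matrix(rnorm(4 * 400), 4, 400), 1)
  r2 <- response_record("b", "y", matrix(rnorm(4 * 400), 4, 400), 1)
  d <- response_dissimilarity(r1, r2, max_lag = 5)
  expect_lt(abs(d - 1), 0.15)
})

test_that("widening the lag search never increases the dissimilarity", {
  set.seed(6)
  for (i in 1:5) {
    r1 <- response_record("a", "x", matrix(rnorm(3 * 50), 3, 50), 1)
    r2 <- response_record("b", "y", matrix(rnorm(3 * 50), 3, 50), 1)
    expect_lte(response_dissimilarity(r1, r2, max_lag = 8),
               response_dissimilarity(r1, r2, max_lag = 3) + 1e-12)
  }
})

test_that("the dissimilarity matrix is symmetric with an exact zero diagonal", {
  recs <- noise_records(E = 6, seed = 2)
  D <- dissimilarity_matrix(recs, max_lag = 3)
  expect_equal(unclass(D), t(unclass(D)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 2))
  expect_error(dissimilarity_matrix(recs[1]), "at least 2")

  # permuting the records permutes rows and columns consistently
  perm <- c(3, 1, 6, 2, 5, 4)
  Dp <- dissimilarity_matrix(recs[perm], max_lag = 3)
  expect_equal(unclass(Dp), unclass(D)[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)

  # a duplicated record is at distance zero from its twin
  Dd <- dissimilarity_matrix(c(recs[1], recs[1]), max_lag = 3)
  expect_equal(Dd[1, 2], 0, tolerance = 1e-12)
})

test_that("hierarchical modes recover planted blocks and nest across levels", {
  recs <- planted_records(n_per = 4, seed = 3)
  D <- dissimilarity_matrix(recs, max_lag = 3)
  hm <- hierarchical_modes(D, levels = c(2, 3))
  labs <- attr(D, "regimes")
  expect_equal(mclust::adjustedRandIndex(hm$cuts[["3"]], labs), 1)
  # nesting: level-2 clusters are unions of level-3 clusters
  expect_true(all(tapply(hm$cuts[["2"]], hm$cuts[["3"]],
                         function(x) length(unique(x))) == 1))
  # medoids belong to their clusters
  for (L in names(hm$cuts))
    expect_equal(unname(hm$cuts[[L]][hm$medoids[[L]]]),
                 sort(unique(hm$cuts[[L]])))

  two <- dissimilarity_matrix(recs[1:2], max_lag = 3)
  hm2 <- hierarchical_modes(two, levels = 2)
  expect_equal(sort(unname(hm2$cuts[["2"]])), c(1, 2))
  expect_error(hierarchical_modes(two, levels = 5), "levels")
})

test_that("clustering significance is exact-minimum for planted modes", {
  expect_error(clustering_significance(noise_records(4), n_perm = 0),
               "n_perm")
  recs <- planted_records(n_per = 4, snr = 10, seed = 5)
  sig <- clustering_significance(recs, n_perm = 99, level = 3, seed = 2)
  expect_equal(sig$p_value, 0.01)
  expect_gt(sig$observed, max(sig$null))
})

test_that("mode exclusivity interpolates between lockout and co-activation", {
  expect_equal(mode_exclusivity(matrix(c(1, 0, 0, 1, 0, 0), 2, 3,
                                       byrow = TRUE)), 1)
  expect_equal(mode_exclusivity(matrix(1 / 4, 5, 4)), 0)
  half <- rbind(matrix(c(1, 0, 0, 0), 2, 4, byrow = TRUE),
                matrix(1 / 4, 2, 4))
  expect_equal(mode_exclusivity(half), 0.5)
  expect_error(mode_exclusivity(matrix(1, 3, 1)), "modes")
})

test_that("null priming leaves the assignment distribution unchanged", {
  fx <- preconditioning_fixture(seed = 4)
  recs <- run_experiment_battery(fx$network, fx$regimes, reps = 4,
                                 t_end = fx$t_end,
                                 sample_dt = fx$sample_dt, seed = 6)
  D <- dissimilarity_matrix(recs, max_lag = 5)
  hm <- hierarchical_modes(D, levels = 2)
  null_prime <- clock_stimulus("primeA",
    data.frame(clock = integer(), time = numeric(), phase = integer(),
               value = numeric(), mode = character()))
  rep_ <- preconditioning_index(fx$network, hm, recs, list(A = null_prime),
                                fx$ambiguous, reps = 8, level = 2,
                                t_prime = fx$t_prime, seed = 3)
  expect_lte(rep_$index, 0.5)
  # internal consistency of the entropy bookkeeping
  h2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  expect_equal(rep_$entropy_reduction_bits,
               h2(rep_$unprimed) - mean(vapply(rep_$primed, h2, numeric(1))))
})

test_that("priming biases the ambiguous response toward the primed mode", {
  fx <- preconditioning_fixture(seed = 5)
  recs <- run_experiment_battery(fx$network, fx$regimes, reps = 4,
                                 t_end = fx$t_end,
                                 sample_dt = fx$sample_dt, seed = 11)
  D <- dissimilarity_matrix(recs, max_lag = 5)
  hm <- hierarchical_modes(D, levels = 2)
  rep_ <- preconditioning_index(fx$network, hm, recs, fx$regimes,
                                fx$ambiguous, reps = 8, level = 2,
                                t_prime = fx$t_prime, seed = 9)
  pA <- rep_$primed$A[rep_$prime_modes["A"]]
  uA <- rep_$unprimed[rep_$prime_modes["A"]]
  expect_gt(pA, uA)
})
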