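test_that("column generator rejects invalid parameters", {
  expect_error(generate_column_network(5, 1.2), "density")
  expect_error(generate_column_network(5, 0.5, delay_range = c(0, 1)),
               "tau_min")
  expect_error(generate_column_network(0, 0.5), "n must be")
})

test_that("degenerate densities force the edge count", {
  expect_equal(nrow(generate_column_network(1, 1, seed = 1)$edges), 0)
  full <- generate_column_network(3, 1, delay_range = c(0.2, 0.9), seed = 2)
  expect_equal(nrow(full$edges), 6)
  expect_true(all(full$edges$delay >= 0.2 & full$edges$delay <= 0.9))
  expect_true(all(full$edges$source != full$edges$target))
})

test_that("edge counts and delays match the binomial/uniform law", {
  n <- 50; density <- 0.2; tmin <- 0.5; tmax <- 2
  nets <- lapply(1:500, function(s)
    generate_column_network(n, density, c(tmin, tmax), seed = s))
  counts <- vapply(nets, function(x) nrow(x$edges), numeric(1))
  mu <- density * n * (n - 1)
  se_mean <- sqrt(mu * (1 - density)) / sqrt(500)
  expect_lt(abs(mean(counts) - mu), 3 * se_mean)
  delays <- unlist(lapply(nets, function(x) x$edges$delay))
  se_delay <- (tmax - tmin) / sqrt(12) / sqrt(length(delays))
  expect_lt(abs(mean(delays) - (tmin + tmax) / 2), 3 * se_delay)
})

test_that("real-valued delays are never lattice-repeated", {
  net <- generate_column_network(200, 0.1, c(0.5, 2), seed = 9)
  expect_equal(anyDuplicated(net$edges$delay), 0)
})

test_that("generation is deterministic in the seed", {
  a <- generate_column_network(40, 0.3, seed = 77)
  b <- generate_column_network(40, 0.3, seed = 77)
  expect_identical(a, b)
  g1 <- generate_range_dependent_grid(4, 4, 0.8, 1.3, seed = 5)
  g2 <- generate_range_dependent_grid(4, 4, 0.8, 1.3, seed = 5)
  expect_identical(g1, g2)
})

test_that("grid generator respects trivial probability limits", {
  expect_equal(nrow(generate_range_dependent_grid(3, 3, 0, 1, seed = 1)$edges),
               0)
  g <- generate_range_dependent_grid(2, 2, 1, 1e9, seed = 1)
  expect_equal(nrow(g$edges), 12)   # all ordered pairs of 4 columns
  expect_error(generate_range_dependent_grid(3, 3, 1, -1), "lambda")
})

test_that("connection frequency follows the range-dependent kernel", {
  beta <- 1; lam <- 1
  tab_all <- list()
  for (s in 1:400) {
    g <- generate_range_dependent_grid(5, 5, beta, lam, seed = s + 3000)
    tab_all[[s]] <- outer_edge_distances(g)
  }
  # all ordered pair distances on the 5x5 grid
  pos <- generate_range_dependent_grid(5, 5, 0, 1, seed = 1)$positions
  d_all <- sqrt(outer(pos$row, pos$row, "-")^2 + outer(pos$col, pos$col, "-")^2)
  d_all <- d_all[d_all > 0]
  observed <- unlist(tab_all)
  for (d in sort(unique(round(d_all, 9)))[1:6]) {
    n_pairs <- sum(abs(d_all - d) < 1e-9) * 400
    p <- min(1, beta * exp(-d / lam))
    phat <- sum(abs(observed - d) < 1e-9) / n_pairs
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n_pairs) + 1e-12)
  }
})

test_that("network-of-networks bridges follow the outer edges", {
  g0 <- generate_range_dependent_grid(2, 2, 0, 1, seed = 1)
  non0 <- assemble_network_of_networks(g0, n = 4, density = 0.5,
                                       bridge_density = 0.5, seed = 1)
  expect_equal(nrow(non0$inter_edges), 0)

  outer1 <- line_outer(data.frame(source = 0L, target = 1L), 2)
  non <- assemble_network_of_networks(outer1, n = 3, density = 0.5,
                                      bridge_density = 1, seed = 2)
  expect_equal(nrow(non$inter_edges), 9)
  expect_true(all(non$inter_edges$source_col == 0))
  expect_true(all(non$inter_edges$target_col == 1))
  expect_true(all(non$inter_edges$delay > 0))

  # replayed assembly is byte-identical
  outer3 <- generate_range_dependent_grid(3, 1, 0.9, 1, seed = 4)
  n1 <- assemble_network_of_networks(outer3, n = 5, density = 0.4,
                                     bridge_density = 0.3, seed = 8)
  n2 <- assemble_network_of_networks(outer3, n = 5, density = 0.4,
                                     bridge_density = 0.3, seed = 8)
  expect_identical(n1, n2)

  # every bridge's column pair is an outer edge
  key_outer <- paste(outer3$edges$source, outer3$edges$target)
  key_bridge <- paste(n1$inter_edges$source_col, n1$inter_edges$target_col)
  expect_true(all(key_bridge %in% key_outer))
})

test_that("bridge delays sit in the shifted inter-column range", {
  outer1 <- line_outer(data.frame(source = 0L, target = 1L), 2)
  non <- assemble_network_of_networks(outer1, n = 6, density = 0.5,
                                      delay_range = c(0.5, 2),
                                      bridge_density = 1, seed = 3)
  expect_true(all(non$inter_edges$delay >= 1 & non$inter_edges$delay <= 4))
})
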