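# Network generators: dense within-column directed graphs with real-valued
# delays, range-dependent column-to-column grids, and their assembly into a
# network-of-networks.  Unit and column ids are 0-based throughout, matching
# the event-driven cores.

#' Generate a dense within-column spiking network
#'
#' Samples a simple directed graph on `n` neurons in which each ordered pair
#' `(i, j)`, `i != j`, is an edge independently with probability `density`.
#' Each edge carries a membrane-kick amplitude and a transmission delay drawn
#' uniformly on `delay_range` — delays are generic real values, deliberately
#' not constrained to any lattice, which is what gives large columns their
#' many distinct signal arrival times.
#'
#' @param n number of neurons (>= 1).
#' @param density edge probability in `[0, 1]`.
#' @param delay_range length-2 vector `(tau_min, tau_max)`, `0 < tau_min <= tau_max`,
#'   in model time units.
#' @param weight excitatory kick amplitude per edge (potential units).
#' @param seed integer seed; identical parameters and seed reproduce the
#'   network exactly.
#' @param inhibitory_frac fraction of edges whose weight is negated (default 0:
#'   purely excitatory).
#' @return an object of class `column_network`: a list with `n`, `edges`
#'   (data frame `source`, `target`, `weight`, `delay`; ids in `[0, n)`),
#'   and the generating parameters.
#' @examples
#' net <- generate_column_network(20, density = 0.3, seed = 1)
#' net
#' @export
generate_column_network <- function(n, density, delay_range = c(0.5, 2),
                                    weight = 1, seed = 1,
                                    inhibitory_frac = 0) {
  n <- check_count(n, "n")
  density <- check_number(density, "density", 0, 1)
  if (length(delay_range) != 2 || !all(is.finite(delay_range)))
    stop_invalid("delay_range must be two finite numbers")
  if (delay_range[1] <= 0 || delay_range[1] > delay_range[2])
    stop_invalid("delay_range requires 0 < tau_min <= tau_max (got %g, %g)",
                 delay_range[1], delay_range[2])
  inhibitory_frac <- check_number(inhibitory_frac, "inhibitory_frac", 0, 1)

  edges <- with_seed(seed, {
    keep <- runif(n * n) < density
    idx <- which(keep) - 1L
    src <- idx %/% n
    tgt <- idx %% n
    ok <- src != tgt                       # no self-edges
    src <- src[ok]; tgt <- tgt[ok]
    ne <- length(src)
    delay <- runif(ne, delay_range[1], delay_range[2])
    w <- rep(weight, ne)
    if (inhibitory_frac > 0 && ne > 0) {
      flip <- runif(ne) < inhibitory_frac
      w[flip] <- -w[flip]
    }
    data.frame(source = src, target = tgt, weight = w, delay = delay)
  })

  structure(list(n = n, edges = edges, density = density,
                 delay_range = as.numeric(delay_range), weight = weight,
                 inhibitory_frac = inhibitory_frac, seed = as.integer(seed)),
            class = "column_network")
}

#' @export
print.column_network <- function(x, ...) {
  cat(sprintf("column_network: %d neurons, %d directed edges (density %.3g)\n",
              x$n, nrow(x$edges), x$density))
  cat(sprintf("  delays in [%.4g, %.4g] time units, seed %d\n",
              x$delay_range[1], x$delay_range[2], x$seed))
  invisible(x)
}

#' Generate a range-dependent column-to-column grid network
#'
#' Columns sit on a flat `rows` x `cols` grid; each ordered pair of distinct
#' columns at Euclidean grid distance `d` is connected by a directed edge with
#' probability `p(d) = min(1, beta * exp(-d / lambda))`, so nearby columns are
#' much more likely to be wired than distant ones.  All edges are directional;
#' there is no torus wrap-around.
#'
#' @param rows,cols grid dimensions (`rows * cols >= 1`).
#' @param beta base connection probability scale (>= 0).
#' @param lambda decay length in grid-distance units (> 0).
#' @param seed integer seed.
#' @param cutoff optional hard cutoff radius: pairs farther apart than this get
#'   probability 0 (default `Inf`, no cutoff).
#' @return an object of class `outer_network` with `positions` (data frame
#'   `id`, `row`, `col`; ids 0-based, row-major) and `edges` (data frame
#'   `source`, `target`).
#' @examples
#' g <- generate_range_dependent_grid(5, 5, beta = 1, lambda = 1, seed = 7)
#' g
#' @export
generate_range_dependent_grid <- function(rows, cols, beta, lambda, seed = 1,
                                          cutoff = Inf) {
  rows <- check_count(rows, "rows")
  cols <- check_count(cols, "cols")
  beta <- check_number(beta, "beta", 0)
  if (length(lambda) != 1 || !is.finite(lambda) || lambda <= 0)
    stop_invalid("lambda must be a single number > 0 (got %s)", format(lambda))
  nc <- rows * cols
  ids <- 0:(nc - 1)
  pos <- data.frame(id = ids, row = ids %/% cols, col = ids %% cols)

  dx <- outer(pos$row, pos$row, "-")
  dy <- outer(pos$col, pos$col, "-")
  d <- sqrt(dx^2 + dy^2)
  p <- pmin(beta * exp(-d / lambda), 1)
  p[d > cutoff] <- 0
  diag(p) <- 0

  edges <- with_seed(seed, {
    keep <- matrix(runif(nc * nc), nc, nc) < p
    idx <- which(keep, arr.ind = TRUE)
    data.frame(source = idx[, 1] - 1L, target = idx[, 2] - 1L)
  })
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(rows = rows, cols = cols, positions = pos, edges = edges,
                 beta = beta, lambda = lambda, cutoff = cutoff,
                 seed = as.integer(seed)),
            class = "outer_network")
}

#' @export
print.outer_network <- function(x, ...) {
  cat(sprintf("outer_network: %d x %d grid, %d directed edges (beta %.3g, lambda %.3g)\n",
              x$rows, x$cols, nrow(x$edges), x$beta, x$lambda))
  invisible(x)
}

# Euclidean grid distance for each edge of an outer network (used by the
# range-monotonicity checks).
outer_edge_distances <- function(outer) {
  p <- outer$positions
  sqrt((p$row[outer$edges$source + 1L] - p$row[outer$edges$target + 1L])^2 +
       (p$col[outer$edges$source + 1L] - p$col[outer$edges$target + 1L])^2)
}

#' Assemble a network-of-networks from an outer grid
#'
#' Builds one dense column per grid node and, for every directed edge of the
#' outer network, samples neuron-level "bridge" connections from the sending
#' column to the receiving column, each present independently with probability
#' `bridge_density`.  Bridge delays default to a range twice the within-column
#' one, reflecting the longer axonal paths between columns.
#'
#' @param outer an `outer_network`.
#' @param n,density,delay_range,weight per-column generation parameters, as in
#'   [generate_column_network()].
#' @param bridge_density probability of each (sender neuron, receiver neuron)
#'   bridge across a connected column pair, in `[0, 1]`.
#' @param bridge_delay_range delay range for bridges (default `2 * delay_range`).
#' @param bridge_weight kick amplitude of bridges (default `weight`).
#' @param seed integer master seed; per-column sub-seeds are derived from it.
#' @return an object of class `network_of_networks` with `columns` (list of
#'   `column_network`), `inter_edges` (data frame `source_col`, `source_unit`,
#'   `target_col`, `target_unit`, `weight`, `delay`) and the `outer` network.
#' @export
assemble_network_of_networks <- function(outer, n, density,
                                         delay_range = c(0.5, 2), weight = 1,
                                         bridge_density = 0.05,
                                         bridge_delay_range = 2 * delay_range,
                                         bridge_weight = weight, seed = 1) {
  if (!inherits(outer, "outer_network"))
    stop_invalid("outer must be an outer_network")
  bridge_density <- check_number(bridge_density, "bridge_density", 0, 1)
  nc <- nrow(outer$positions)
  seeds <- derive_seeds(seed, nc + 1L)

  columns <- lapply(seq_len(nc), function(i)
    generate_column_network(n, density, delay_range, weight, seed = seeds[i]))

  ne <- nrow(outer$edges)
  inter <- with_seed(seeds[nc + 1L], {
    out <- vector("list", ne)
    if (ne > 0) {
      for (e in seq_len(ne)) {
        sc <- outer$edges$source[e]
        tc <- outer$edges$target[e]
        keep <- which(runif(n * n) < bridge_density) - 1L
        if (length(keep)) {
          out[[e]] <- data.frame(
            source_col = sc, source_unit = keep %/% n,
            target_col = tc, target_unit = keep %% n,
            weight = bridge_weight,
            delay = runif(length(keep), bridge_delay_range[1],
                          bridge_delay_range[2]))
        }
      }
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out)) do.call(rbind, out)
    else data.frame(source_col = integer(), source_unit = integer(),
                    target_col = integer(), target_unit = integer(),
                    weight = numeric(), delay = numeric())
  })

  structure(list(columns = columns, inter_edges = inter, outer = outer,
                 bridge_density = bridge_density,
                 bridge_delay_range = as.numeric(bridge_delay_range),
                 seed = as.integer(seed)),
            class = "network_of_networks")
}

#' @export
print.network_of_networks <- function(x, ...) {
  ns <- vapply(x$columns, function(cl) cl$n, integer(1))
  cat(sprintf("network_of_networks: %d columns (%d neurons total), %d bridges\n",
              length(x$columns), sum(ns), nrow(x$inter_edges)))
  print(x$outer)
  invisible(x)
}

# Flatten a network-of-networks to one global edge list.  Global unit id of
# (column c, unit u) = offset[c + 1] + u with columns in id order.
flatten_network <- function(x) {
  if (inherits(x, "column_network")) {
    return(list(n = x$n, edges = x$edges, offsets = 0L))
  }
  if (!inherits(x, "network_of_networks"))
    stop_invalid("expected a column_network or network_of_networks")
  ns <- vapply(x$columns, function(cl) cl$n, integer(1))
  offsets <- c(0L, cumsum(ns))
  intra <- do.call(rbind, lapply(seq_along(x$columns), function(i) {
    e <- x$columns[[i]]$edges
    if (nrow(e) == 0) return(NULL)
    data.frame(source = e$source + offsets[i], target = e$target + offsets[i],
               weight = e$weight, delay = e$delay)
  }))
  inter <- if (nrow(x$inter_edges) > 0) {
    data.frame(
      source = x$inter_edges$source_unit + offsets[x$inter_edges$source_col + 1L],
      target = x$inter_edges$target_unit + offsets[x$inter_edges$target_col + 1L],
      weight = x$inter_edges$weight, delay = x$inter_edges$delay)
  } else NULL
  edges <- rbind(intra, inter)
  if (is.null(edges))
    edges <- data.frame(source = integer(), target = integer(),
                        weight = numeric(), delay = numeric())
  list(n = sum(ns), edges = edges, offsets = offsets[-length(offsets)])
}
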