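# Preconditioning fixture: a clock network whose state carries the trace of
# past forcing.  All phases wind at the common rate 1, so after priming for a
# whole number of winding periods the network sits exactly on the primed
# regime's trajectory; an ambiguous probe then resets only part of each
# clock, and the remaining "memory" phases decide the mode assignment.

#' Preconditioning fixture
#'
#' A small grid of k-dimensional clocks, all phases winding at the common
#' rate 1, with two single-shot forcing regimes that stamp distinct phase
#' patterns onto disjoint clock subsets at t = 0.  Because every phase winds
#' at the same rate, a network primed with a regime for a whole number of
#' periods (2*pi time units each) returns exactly to the primed pattern, so
#' the primed trajectory stays on the regime's mode; the fixture's
#' `t_prime` is the nearest sample-grid multiple of four periods.  The
#' `ambiguous` probe resets the same pattern values on the first phase of
#' every forced clock — equally supporting both modes — while the remaining
#' "memory" phases retain whatever the priming left behind.  The default
#' grid splits evenly into the two forced subsets.
#'
#' @param rows,cols grid size.
#' @param k phases per clock (>= 2; only the first phase is probed).
#' @param t_end battery record length.
#' @param sample_dt sampling interval.
#' @param seed seed for the network.
#' @return list with `network`, `regimes` (list of two single-shot
#'   [clock_stimulus()]), `ambiguous`, `t_prime`, `t_end`, `sample_dt`.
#' @export
preconditioning_fixture <- function(rows = 2, cols = 4, k = 3, t_end = 40,
                                    sample_dt = 0.25, seed = 1) {
  if (k < 2) stop_invalid("k must be >= 2")
  outer <- generate_range_dependent_grid(rows, cols, beta = 0.5, lambda = 1,
                                         seed = seed)
  net <- generate_clock_network(outer, k = k, rate_range = c(1, 1),
                                delay_range = c(0.5, 1.5), prm = "pull",
                                pull_strength = 0.15, seed = seed)
  nc <- net$n_clocks
  half <- nc %/% 2
  sets <- list(A = 0:(half - 1), B = half:(nc - 1))
  values <- list(A = 0.7, B = 3.9)

  stamp <- function(clocks, v, phases) {
    grid <- expand.grid(phase = as.integer(phases), clock = as.integer(clocks))
    data.frame(clock = grid$clock, time = 0, phase = grid$phase,
               value = (v + 1.1 * (grid$phase - 1)) %% (2 * pi),
               mode = "reset")
  }
  regimes <- list(
    A = clock_stimulus("primeA", stamp(sets$A, values$A, seq_len(k))),
    B = clock_stimulus("primeB", stamp(sets$B, values$B, seq_len(k))))
  ambiguous <- clock_stimulus("ambiguous", rbind(
    stamp(sets$A, values$A, 1L),
    stamp(sets$B, values$B, 1L)))

  period <- 2 * pi                       # common winding period of all phases
  t_prime <- round(4 * period / sample_dt) * sample_dt
  list(network = net, regimes = regimes, ambiguous = ambiguous,
       t_prime = t_prime, t_end = t_end, sample_dt = sample_dt)
}
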