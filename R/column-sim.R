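# Event-driven simulation of excitable-refractory neurons with exact
# real-valued transmission delays.  The neuron model is leaky integrate-and-fire
# with an absolute refractory period: the simplest dynamics that is excitable
# (fires only when driven past threshold) and refractory (cannot fire again
# within rho).  Potentials are advanced lazily in closed form at event times,
# so there is no time step and delivery times are exact.

#' Neuron dynamics parameters
#'
#' Parameters of the excitable-refractory (leaky integrate-and-fire) neuron.
#' A neuron's potential decays exponentially toward `rest` with time constant
#' `leak_tau`; an arriving kick adds the edge weight instantaneously; crossing
#' `threshold` emits a spike, resets the potential to `reset`, and silences the
#' neuron for `refractory` time units (kicks delivered during that window are
#' discarded).
#'
#' @param threshold firing threshold (potential units; must exceed `rest`).
#' @param reset post-spike potential.
#' @param rest resting potential.
#' @param leak_tau leak time constant (> 0, time units).
#' @param refractory absolute refractory period rho (> 0, time units).
#' @return an object of class `neuron_params`.
#' @export
neuron_params <- function(threshold = 1, reset = 0, rest = 0,
                          leak_tau = 10, refractory = 1) {
  if (threshold <= rest)
    stop_invalid("threshold (%g) must exceed rest (%g)", threshold, rest)
  leak_tau <- check_number(leak_tau, "leak_tau", 0, strict_lower = TRUE)
  refractory <- check_number(refractory, "refractory", 0, strict_lower = TRUE)
  structure(list(threshold = threshold, reset = reset, rest = rest,
                 leak_tau = leak_tau, refractory = refractory),
            class = "neuron_params")
}

#' Stimulus regime
#'
#' A forcing regime for a spiking network: a labelled set of input spikes
#' delivered to specific units, given explicitly and/or as Poisson rate
#' descriptors realised at simulation time from the regime's seed.
#'
#' @param label regime identifier.
#' @param spikes data frame with columns `unit`, `time` and optionally
#'   `amplitude` (defaults at simulation time to `threshold - rest`, i.e. a
#'   kick that fires a resting neuron).
#' @param poisson data frame with columns `unit`, `rate`, `start`, `end`:
#'   independent Poisson spike trains per row.
#' @param seed seed used to realise the Poisson part.
#' @return an object of class `stimulus_regime`.
#' @export
stimulus_regime <- function(label, spikes = NULL, poisson = NULL, seed = 1) {
  if (!is.null(spikes)) {
    if (!all(c("unit", "time") %in% names(spikes)))
      stop_invalid("spikes must have columns unit, time")
    if (any(spikes$time < 0)) stop_invalid("stimulus spike times must be >= 0")
  }
  if (!is.null(poisson)) {
    if (!all(c("unit", "rate", "start", "end") %in% names(poisson)))
      stop_invalid("poisson must have columns unit, rate, start, end")
    if (any(poisson$rate < 0)) stop_invalid("poisson rates must be >= 0")
  }
  structure(list(label = as.character(label), spikes = spikes,
                 poisson = poisson, seed = as.integer(seed)),
            class = "stimulus_regime")
}

# Expand a stimulus_regime into an explicit (unit, time, amplitude) table.
realize_stimulus <- function(stimulus, params, t_end, n_units, seed = NULL) {
  if (!inherits(stimulus, "stimulus_regime"))
    stop_invalid("stimulus must be a stimulus_regime")
  amp0 <- params$threshold - params$rest
  parts <- list()
  if (!is.null(stimulus$spikes) && nrow(stimulus$spikes) > 0) {
    s <- stimulus$spikes
    amp <- if ("amplitude" %in% names(s)) s$amplitude else rep(amp0, nrow(s))
    parts$fixed <- data.frame(unit = as.integer(s$unit), time = s$time,
                              amplitude = amp)
  }
  if (!is.null(stimulus$poisson) && nrow(stimulus$poisson) > 0) {
    p <- stimulus$poisson
    parts$pois <- with_seed(seed %||% stimulus$seed, {
      out <- lapply(seq_len(nrow(p)), function(i) {
        w <- c(max(0, p$start[i]), min(t_end, p$end[i]))
        if (w[2] <= w[1] || p$rate[i] <= 0) return(NULL)
        m <- rpois(1, p$rate[i] * (w[2] - w[1]))
        if (m == 0) return(NULL)
        data.frame(unit = as.integer(p$unit[i]),
                   time = sort(runif(m, w[1], w[2])), amplitude = amp0)
      })
      out <- out[!vapply(out, is.null, logical(1))]
      if (length(out)) do.call(rbind, out) else NULL
    })
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  ev <- if (length(parts)) do.call(rbind, parts)
        else data.frame(unit = integer(), time = numeric(),
                        amplitude = numeric())
  bad <- ev$unit < 0 | ev$unit >= n_units
  if (any(bad))
    stop_invalid("stimulus targets unknown unit(s): %s (network has units 0..%d)",
                 paste(unique(ev$unit[bad]), collapse = ", "), n_units - 1L)
  ev <- ev[order(ev$time, ev$unit), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Simulate an excitable-refractory spiking network
#'
#' Exact event-driven simulation on a [generate_column_network()] graph (or a
#' whole [assemble_network_of_networks()], flattened to global unit ids).
#' Every spike schedules one delivery per outgoing edge at emission time plus
#' that edge's delay; deliveries are processed in (time, edge id) order with a
#' stable final tie-break, which makes simultaneous "dead-heat" arrivals —
#' the central phenomenon under unit delays — deterministic.
#'
#' @param network a `column_network` or `network_of_networks`.
#' @param params a [neuron_params()] object.
#' @param stimulus a [stimulus_regime()].
#' @param t_end simulation horizon (> 0, time units).
#' @param observed integer vector of unit ids whose spikes are recorded
#'   (default: all units).
#' @param seed seed used to realise rate-based stimulus terms.
#' @param record_deliveries if `TRUE`, also log every synaptic delivery
#'   (needed by [count_distinct_arrival_times()]).
#' @param max_events hard cap on processed events.
#' @return an object of class `spike_train`: `events` (data frame `unit`,
#'   `time`, time-ordered), `t_end`, `observed`, and (optionally)
#'   `deliveries`.
#' @examples
#' net <- generate_column_network(30, 0.3, seed = 2)
#' stim <- stimulus_regime("volley",
#'   spikes = data.frame(unit = 0:4, time = 0))
#' simulate_spiking(net, neuron_params(), stim, t_end = 20)
#' @export
simulate_spiking <- function(network, params, stimulus, t_end,
                             observed = NULL, seed = 1,
                             record_deliveries = FALSE, max_events = 2e8) {
  if (!inherits(params, "neuron_params"))
    stop_invalid("params must be a neuron_params object")
  t_end <- check_number(t_end, "t_end", 0, strict_lower = TRUE)
  flat <- flatten_network(network)
  observed <- if (is.null(observed)) 0:(flat$n - 1L) else as.integer(observed)
  if (any(observed < 0 | observed >= flat$n))
    stop_invalid("observed units out of range 0..%d", flat$n - 1L)
  stim <- realize_stimulus(stimulus, params, t_end, flat$n, seed = seed)

  rec <- logical(flat$n)
  rec[observed + 1L] <- TRUE
  res <- cpp_simulate_spiking(
    flat$n,
    as.integer(flat$edges$source), as.integer(flat$edges$target),
    as.numeric(flat$edges$weight), as.numeric(flat$edges$delay),
    params$threshold, params$reset, params$rest,
    params$leak_tau, params$refractory,
    as.integer(stim$unit), as.numeric(stim$time), as.numeric(stim$amplitude),
    t_end, rec, record_deliveries, max_events)

  structure(list(
    events = data.frame(unit = res$spike_unit, time = res$spike_time),
    t_end = t_end, observed = sort(observed),
    deliveries = if (record_deliveries)
      data.frame(unit = res$deliv_unit, time = res$deliv_time) else NULL,
    params = params, stimulus_label = stimulus$label,
    n_units = flat$n),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train: %d spikes from %d observed units over [0, %g]\n",
              nrow(x$events), length(x$observed), x$t_end))
  if (!is.null(x$deliveries))
    cat(sprintf("  delivery log: %d synaptic arrivals\n", nrow(x$deliveries)))
  invisible(x)
}

#' @export
summary.spike_train <- function(object, ...) {
  ev <- object$events
  rate <- if (length(object$observed))
    nrow(ev) / length(object$observed) / object$t_end else 0
  cat(sprintf("spike_train over [0, %g]: %d spikes, mean rate %.3g per unit-time\n",
              object$t_end, nrow(ev), rate))
  if (nrow(ev)) {
    isi <- unlist(lapply(split(ev$time, ev$unit), function(t) diff(sort(t))),
                  use.names = FALSE)
    if (length(isi))
      cat(sprintf("  inter-spike intervals: min %.4g, median %.4g\n",
                  min(isi), median(isi)))
  }
  invisible(object)
}

#' Count distinct signal arrival times
#'
#' Counts, unit by unit, how many distinct delivery timestamps occur within a
#' window, and sums over units.  Two alternative directed walks of equal hop
#' count arrive simultaneously when all delays are equal ("dead heats"),
#' so this count drops sharply when real-valued delays are replaced by a unit
#' delay — the quantity behind the unit-delay quenching experiment.
#'
#' @param x a `spike_train` simulated with `record_deliveries = TRUE`, a
#'   `phase_record`, or a data frame with columns `unit`, `time`.
#' @param window length-2 numeric window `[t0, t1]` of arrival times to count.
#' @param tol times are rounded to multiples of `tol` before comparison.
#' @param units optional subset of receiving unit ids.
#' @return integer: total number of distinct arrival times, summed over units.
#' @export
count_distinct_arrival_times <- function(x, window = c(0, Inf), tol = 1e-9,
                                         units = NULL) {
  UseMethod("count_distinct_arrival_times")
}

count_distinct_core <- function(unit, time, window, tol, units) {
  keep <- time >= window[1] & time <= window[2]
  if (!is.null(units)) keep <- keep & unit %in% units
  if (!any(keep)) return(0L)
  key <- paste(unit[keep], round(time[keep] / tol))
  length(unique(key))
}

#' @export
count_distinct_arrival_times.spike_train <- function(x, window = c(0, Inf),
                                                     tol = 1e-9, units = NULL) {
  if (is.null(x$deliveries))
    stop_invalid("spike_train has no delivery log; simulate with record_deliveries = TRUE")
  count_distinct_core(x$deliveries$unit, x$deliveries$time, window, tol, units)
}

#' @export
count_distinct_arrival_times.data.frame <- function(x, window = c(0, Inf),
                                                    tol = 1e-9, units = NULL) {
  if (nrow(x) == 0) return(0L)
  count_distinct_core(x$unit, x$time, window, tol, units)
}

#' @export
count_distinct_arrival_times.phase_record <- function(x, window = c(0, Inf),
                                                      tol = 1e-9, units = NULL) {
  ev <- x$events
  if (nrow(ev) == 0) return(0L)
  count_distinct_core(ev$receiver, ev$arrival_time, window, tol, units)
}
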