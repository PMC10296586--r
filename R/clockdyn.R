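# Generalised Kuramoto dynamics: k-dimensional clocks (winding maps on a
# k-torus) on a range-dependent grid, coupled by directed edges that fire when
# a designated sender phase upward-crosses an edge-specific trigger value,
# incur a real-valued delay, and apply an instantaneous phase-resetting map
# (PRM) to the receiver.  Between events the flow is exactly linear, so the
# event-driven integration is closed-form, with no discretisation error.

TWO_PI <- 2 * pi

#' A k-dimensional clock
#'
#' A clock with `k` independent phases, each winding around mod 2*pi at its
#' own angular rate.  Rates must be non-negative; simulation additionally
#' requires them strictly positive (a zero-rate phase never crosses any
#' trigger).
#'
#' @param phases numeric vector of initial phases (reduced mod 2*pi).
#' @param rates numeric vector of angular rates (radians per time unit),
#'   same length.
#' @return an object of class `kclock`.
#' @examples
#' cl <- kclock(c(0, pi / 2), c(1, 0.5))
#' wind(cl, 3)
#' @export
kclock <- function(phases, rates) {
  if (length(phases) < 1 || length(phases) != length(rates))
    stop_invalid("phases and rates must be equal-length vectors, k >= 1")
  if (any(!is.finite(phases)) || any(!is.finite(rates)) || any(rates < 0))
    stop_invalid("rates must be finite and >= 0")
  structure(list(phases = phases %% TWO_PI, rates = as.numeric(rates),
                 k = length(phases)),
            class = "kclock")
}

#' @export
print.kclock <- function(x, ...) {
  cat(sprintf("kclock: k = %d, rates in [%.3g, %.3g] rad/time\n",
              x$k, min(x$rates), max(x$rates)))
  invisible(x)
}

#' Wind a clock forward
#'
#' Advances all phases of a [kclock()] by `dt` time units in closed form:
#' `(phases + rates * dt) mod 2*pi`.
#'
#' @param clock a `kclock`.
#' @param dt elapsed time (>= 0).
#' @return the phase vector after winding.
#' @export
wind <- function(clock, dt) {
  if (length(dt) != 1 || !is.finite(dt) || dt < 0)
    stop_invalid("dt must be a single number >= 0 (got %s)", format(dt))
  (clock$phases + clock$rates * dt) %% TWO_PI
}

#' Next trigger-crossing time
#'
#' Smallest `t > t_now` at which phase `j` of the clock upward-crosses the
#' value `c`, computed in closed form from linear winding.  The inequality is
#' strict: a clock sitting exactly at the trigger fires after a full
#' revolution.
#'
#' @param clock a `kclock`.
#' @param trigger length-2 vector `(j, c)`: phase index (1-based) and crossing
#'   value in `[0, 2*pi)`.
#' @param t_now current time.
#' @return the crossing time.
#' @export
next_trigger_time <- function(clock, trigger, t_now = 0) {
  j <- check_count(trigger[1], "trigger phase index")
  if (j > clock$k) stop_invalid("trigger index %d exceeds k = %d", j, clock$k)
  cr <- trigger[2] %% TWO_PI
  w <- clock$rates[j]
  if (w == 0)
    stop_invalid("phase %d has zero rate and never crosses the trigger", j)
  gap <- (cr - clock$phases[j]) %% TWO_PI
  if (gap < 1e-12) gap <- TWO_PI
  t_now + gap / w
}

#' Apply a phase-resetting kick
#'
#' The default PRM: an additive phase kick, `(phases + delta) mod 2*pi`.
#' Applying `delta1` then `delta2` equals applying their sum.
#'
#' @param phases phase vector.
#' @param delta kick vector of the same length.
#' @return the kicked phase vector in `[0, 2*pi)`.
#' @export
apply_prm <- function(phases, delta) {
  if (length(phases) != length(delta))
    stop_invalid("phases (length %d) and delta (length %d) must match",
                 length(phases), length(delta))
  (phases + delta) %% TWO_PI
}

#' Generate a clock network on a range-dependent grid
#'
#' Places one k-dimensional clock at each node of an [generate_range_dependent_grid()]
#' outer network and equips every outer edge with a trigger condition (a
#' randomly chosen sender phase and crossing value), a real-valued delay, and
#' a phase-resetting map.  Two PRM families are available: `"kick"` (additive
#' phase kick, the default) and `"pull"` (each receiver phase is pulled toward
#' an edge-specific target phase with the given strength — a contracting map,
#' under which the network state retains a trace of past forcing).
#'
#' @param outer an `outer_network`.
#' @param k phases per clock (default 10).
#' @param rate_range rates are drawn log-uniformly in this band
#'   (radians per time unit).
#' @param delay_range edge delays drawn uniformly in this range (> 0).
#' @param prm `"kick"` or `"pull"`.
#' @param kick_scale for `"kick"`: components of the kick vector are drawn
#'   uniformly in `[-kick_scale, kick_scale]`.
#' @param pull_strength for `"pull"`: coupling strength in `(0, 1]`.
#' @param seed integer seed.
#' @return an object of class `clock_network`.
#' @export
generate_clock_network <- function(outer, k = 10, rate_range = c(0.5, 2),
                                   delay_range = c(0.5, 2),
                                   prm = c("kick", "pull"),
                                   kick_scale = 0.5, pull_strength = 0.8,
                                   seed = 1) {
  if (!inherits(outer, "outer_network"))
    stop_invalid("outer must be an outer_network")
  k <- check_count(k, "k")
  prm <- match.arg(prm)
  if (delay_range[1] <= 0)
    stop_invalid("delay_range must be strictly positive")
  nc <- nrow(outer$positions)
  ne <- nrow(outer$edges)

  with_seed(seed, {
    rates <- matrix(exp(runif(nc * k, log(rate_range[1]), log(rate_range[2]))),
                    nrow = nc)
    phases0 <- matrix(runif(nc * k, 0, TWO_PI), nrow = nc)
    edges <- data.frame(
      sender = outer$edges$source, receiver = outer$edges$target,
      trigger_phase = if (ne) sample.int(k, ne, replace = TRUE) else integer(),
      trigger_value = runif(ne, 0, TWO_PI),
      delay = runif(ne, delay_range[1], delay_range[2]))
    prm_val <- if (ne == 0) matrix(numeric(0), 0, k)
    else if (prm == "kick") matrix(runif(ne * k, -kick_scale, kick_scale), nrow = ne)
    else matrix(runif(ne * k, 0, TWO_PI), nrow = ne)

    structure(list(n_clocks = nc, k = rep(k, nc),
                   phases0 = phases0, rates = rates,
                   edges = edges, prm_type = prm, prm_val = prm_val,
                   pull_strength = pull_strength, outer = outer,
                   seed = as.integer(seed)),
              class = "clock_network")
  })
}

#' @export
print.clock_network <- function(x, ...) {
  cat(sprintf("clock_network: %d clocks x k = %d phases, %d coupled edges (PRM: %s)\n",
              x$n_clocks, x$k[1], nrow(x$edges), x$prm_type))
  invisible(x)
}

#' Clock stimulus
#'
#' External forcing for a clock network: a labelled list of events, each
#' applying an instantaneous map to one phase of one clock, through the same
#' mechanism as internal edge signals.  `mode = "kick"` adds `value` to the
#' phase; `mode = "reset"` sets the phase to `value`.
#'
#' @param label regime identifier.
#' @param events data frame with columns `clock` (0-based id), `time`,
#'   `phase` (1-based phase index), `value`, and optionally `mode`
#'   (default `"kick"`).
#' @return an object of class `clock_stimulus`.
#' @export
clock_stimulus <- function(label, events) {
  need <- c("clock", "time", "phase", "value")
  if (!all(need %in% names(events)))
    stop_invalid("events must have columns %s", paste(need, collapse = ", "))
  if (any(events$time < 0)) stop_invalid("stimulus times must be >= 0")
  if (!"mode" %in% names(events)) events$mode <- "kick"
  if (!all(events$mode %in% c("kick", "reset")))
    stop_invalid("event mode must be 'kick' or 'reset'")
  structure(list(label = as.character(label), events = events),
            class = "clock_stimulus")
}

#' Simulate a generalised Kuramoto clock network
#'
#' Exact event-driven integration: between events all phases wind linearly;
#' trigger crossings are found in closed form; each emission schedules an
#' arrival at emission time + edge delay (exactly), which applies the edge's
#' PRM to the receiver; external stimulus events act through the same
#' mechanism.  Events are processed in (time, edge id) order.  Phases of
#' observed clocks are sampled every `sample_dt`; a sample at time `s`
#' reflects the state before events scheduled exactly at `s`.
#'
#' @param net a `clock_network`.
#' @param stimulus a [clock_stimulus()] or `NULL`.
#' @param t_end horizon (> 0).
#' @param observed 0-based clock ids to sample (default all).
#' @param sample_dt sampling interval (> 0).
#' @param initial_phases optional matrix (clocks x k) overriding the network's
#'   stored initial phases, or the string `"random"` to draw them uniformly
#'   from `seed`.
#' @param seed seed used when `initial_phases = "random"`.
#' @param max_events hard cap on processed events.
#' @return an object of class `phase_record`: `times`, `phases` (matrix with
#'   one row per observed clock phase, named `clock<i>.<j>`), and `events`
#'   (data frame `edge`, `receiver`, `emit_time`, `arrival_time`).
#' @examples
#' g <- generate_range_dependent_grid(2, 2, beta = 1, lambda = 2, seed = 3)
#' net <- generate_clock_network(g, k = 3, seed = 3)
#' rec <- simulate_clock_network(net, t_end = 10, sample_dt = 0.5)
#' rec
#' @export
simulate_clock_network <- function(net, stimulus = NULL, t_end,
                                   observed = NULL, sample_dt = 0.1,
                                   initial_phases = NULL, seed = 1,
                                   max_events = 2e8) {
  if (!inherits(net, "clock_network"))
    stop_invalid("net must be a clock_network")
  t_end <- check_number(t_end, "t_end", 0, strict_lower = TRUE)
  sample_dt <- check_number(sample_dt, "sample_dt", 0, strict_lower = TRUE)
  nc <- net$n_clocks
  observed <- if (is.null(observed)) 0:(nc - 1L) else as.integer(observed)
  if (any(observed < 0 | observed >= nc))
    stop_invalid("observed clocks out of range 0..%d", nc - 1L)

  ph0 <- net$phases0
  if (identical(initial_phases, "random")) {
    ph0 <- with_seed(seed,
      matrix(runif(length(net$phases0), 0, TWO_PI), nrow = nc))
  } else if (!is.null(initial_phases)) {
    if (!identical(dim(initial_phases), dim(net$phases0)))
      stop_invalid("initial_phases must be a %d x %d matrix", nc, net$k[1])
    ph0 <- initial_phases %% TWO_PI
  }

  k <- net$k
  koff <- c(0L, cumsum(k))
  # row-per-clock matrices to concatenated vectors
  phase0 <- as.numeric(t(ph0))
  rates <- as.numeric(t(net$rates))
  if (any(rates <= 0)) stop_invalid("all clock rates must be > 0 to simulate")

  ne <- nrow(net$edges)
  prm_off <- c(0L, cumsum(k[net$edges$receiver + 1L]))
  prm_val <- if (ne) as.numeric(t(net$prm_val)) else numeric()
  prm_type <- rep(if (net$prm_type == "pull") 1L else 0L, ne)
  prm_strength <- rep(net$pull_strength %||% 0, ne)

  st <- if (is.null(stimulus))
    data.frame(clock = integer(), time = numeric(), phase = integer(),
               value = numeric(), mode = character())
  else {
    if (!inherits(stimulus, "clock_stimulus"))
      stop_invalid("stimulus must be a clock_stimulus")
    ev <- stimulus$events
    bad <- ev$clock < 0 | ev$clock >= nc
    if (any(bad))
      stop_invalid("stimulus targets unknown clock(s): %s",
                   paste(unique(ev$clock[bad]), collapse = ", "))
    if (any(ev$phase < 1 | ev$phase > k[ev$clock + 1L]))
      stop_invalid("stimulus phase index out of range for its clock")
    ev
  }

  res <- cpp_simulate_clocks(
    nc, as.integer(koff), phase0, rates,
    as.integer(net$edges$sender), as.integer(net$edges$receiver),
    as.integer(net$edges$trigger_phase) - 1L,
    as.numeric(net$edges$trigger_value), as.numeric(net$edges$delay),
    as.integer(prm_off), prm_val, prm_type, as.numeric(prm_strength),
    as.integer(st$clock), as.numeric(st$time), as.integer(st$phase) - 1L,
    as.numeric(st$value), as.integer(st$mode == "reset"),
    t_end, sample_dt, as.integer(observed), max_events)

  phases <- res$phases
  rownames(phases) <- unlist(lapply(observed, function(c)
    sprintf("clock%d.%d", c, seq_len(k[c + 1L]))))
  ev <- data.frame(edge = res$ev_edge,
                   receiver = if (length(res$ev_edge))
                     net$edges$receiver[res$ev_edge + 1L] else integer(),
                   emit_time = res$ev_emit, arrival_time = res$ev_arrival)

  structure(list(times = res$sample_times, phases = phases, events = ev,
                 observed = observed, sample_dt = sample_dt, t_end = t_end,
                 k = k[observed + 1L],
                 stimulus_label = if (is.null(stimulus)) NULL else stimulus$label),
            class = "phase_record")
}

#' @export
print.phase_record <- function(x, ...) {
  cat(sprintf("phase_record: %d clocks (%d phase channels) sampled %d times (dt = %g)\n",
              length(x$observed), nrow(x$phases), length(x$times), x$sample_dt))
  cat(sprintf("  %d trigger emissions logged over [0, %g]\n",
              nrow(x$events), x$t_end))
  invisible(x)
}

#' Number of dynamical state variables
#'
#' Configuration arithmetic for a system of `units` dynamical elements with
#' `phases_per_unit` phase variables each: the clock-level cortex model has
#' one k-dimensional clock per neural column, while the neuron-level model
#' carries one phase per neuron.
#'
#' @param units number of units (clocks or neurons).
#' @param phases_per_unit phases per unit (default 1).
#' @return total number of state variables, as a double (counts can exceed
#'   the integer range).
#' @examples
#' state_dimension(1e6, 10)   # clock-level cortex model
#' state_dimension(1e10, 1)   # neuron-level model
#' @export
state_dimension <- function(units, phases_per_unit = 1) {
  if (length(units) != 1 || !is.finite(units) || units < 1 ||
      units != floor(units))
    stop_invalid("units must be a single positive integer-valued number")
  if (length(phases_per_unit) != 1 || !is.finite(phases_per_unit) ||
      phases_per_unit < 1 || phases_per_unit != floor(phases_per_unit))
    stop_invalid("phases_per_unit must be a single positive integer-valued number")
  as.numeric(units) * as.numeric(phases_per_unit)
}
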