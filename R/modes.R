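# Reverse-engineering pipeline: run batteries of stimulation experiments,
# compare the recorded responses with an offset-tolerant dissimilarity (it is
# the relative firing pattern that matters, not absolute time), cluster the
# responses hierarchically into dynamical "modes", test the clustering against
# a circular-shift surrogate null, and quantify mode competition and
# preconditioning.

#' A single experiment response
#'
#' @param id experiment identifier.
#' @param regime label of the forcing regime that produced the response.
#' @param mat observed-units x time-bins matrix (rates for spiking systems,
#'   sines of sampled phases for clock networks).
#' @param bin_width time per bin.
#' @return an object of class `response_record`.
#' @export
response_record <- function(id, regime, mat, bin_width) {
  if (!is.matrix(mat) || any(!is.finite(mat)))
    stop_invalid("mat must be a finite matrix")
  structure(list(id = id, regime = as.character(regime), mat = mat,
                 bin_width = bin_width),
            class = "response_record")
}

#' @export
print.response_record <- function(x, ...) {
  cat(sprintf("response_record '%s' (regime %s): %d channels x %d bins\n",
              x$id, x$regime, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Run a battery of stimulation experiments
#'
#' Simulates `reps` independent runs of each forcing regime (each run under a
#' fresh sub-seed derived from the master seed) and converts every run into a
#' [response_record()].  For a `clock_network` system the initial phases are
#' redrawn uniformly per run and the response channels are the sines of the
#' sampled phases; for a spiking system (a list with elements `network` and
#' `params`) the channels are binned, smoothed firing rates.
#'
#' @param system a `clock_network`, or `list(network = , params = )` for a
#'   spiking system.
#' @param regimes list of [clock_stimulus()] / [stimulus_regime()] objects
#'   (>= 1).
#' @param reps runs per regime (>= 1).
#' @param t_end horizon per run.
#' @param observed units/clocks to record (default all).
#' @param sample_dt sampling interval for clock systems.
#' @param bin_width,kernel_width rate extraction for spiking systems.
#' @param seed master seed; the whole battery is reproducible from it.
#' @return list of `response_record`s, one per (regime, rep), with ids
#'   `"<label>#<rep>"`.
#' @export
run_experiment_battery <- function(system, regimes, reps, t_end,
                                   observed = NULL, sample_dt = 0.25,
                                   bin_width = 0.25, kernel_width = 0.5,
                                   seed = 1) {
  if (length(regimes) < 1) stop_invalid("need at least one regime")
  reps <- check_count(reps, "reps")
  seeds <- matrix(derive_seeds(seed, length(regimes) * reps),
                  nrow = length(regimes))
  records <- list()
  for (g in seq_along(regimes)) {
    for (r in seq_len(reps)) {
      rec <- run_one_experiment(system, regimes[[g]], t_end, observed,
                                sample_dt, bin_width, kernel_width,
                                seeds[g, r])
      rec$id <- sprintf("%s#%d", rec$regime, r)
      records[[length(records) + 1]] <- rec
    }
  }
  records
}

# one (regime, sub-seed) run -> response_record; exposed logic shared with
# preconditioning_index
run_one_experiment <- function(system, regime, t_end, observed, sample_dt,
                               bin_width, kernel_width, sub_seed) {
  if (inherits(system, "clock_network")) {
    rec <- simulate_clock_network(system, regime, t_end, observed = observed,
                                  sample_dt = sample_dt,
                                  initial_phases = "random", seed = sub_seed)
    response_record(regime$label, regime$label, sin(rec$phases), sample_dt)
  } else if (is.list(system) && !is.null(system$network)) {
    tr <- simulate_spiking(system$network, system$params, regime, t_end,
                           observed = observed, seed = sub_seed)
    sig <- bin_and_smooth(tr, bin_width, kernel_width)
    response_record(regime$label, regime$label, sig$rates, bin_width)
  } else stop_invalid("system must be a clock_network or list(network, params)")
}

#' Offset-tolerant response dissimilarity
#'
#' `d = 1 - max` over integer bin lags `|l| <= max_lag` of the Pearson
#' correlation between the two flattened unit x time matrices restricted to
#' their overlapping window at shift `l`.  Values lie in `[0, 2]`; `d = 0`
#' iff some shift aligns the responses perfectly.  If either windowed vector
#' has zero variance its correlation term is 0, unless the two windows are
#' identical (then 1), so `d(r, r) = 0` always.
#'
#' @param r1,r2 `response_record`s with identical channel sets and bin widths.
#' @param max_lag maximum absolute lag, in bins.
#' @return dissimilarity in `[0, 2]`.
#' @export
response_dissimilarity <- function(r1, r2, max_lag = 5) {
  if (!identical(dim(r1$mat), dim(r2$mat)))
    stop_invalid("response shapes differ: %s vs %s",
                 paste(dim(r1$mat), collapse = "x"),
                 paste(dim(r2$mat), collapse = "x"))
  if (!isTRUE(all.equal(r1$bin_width, r2$bin_width)))
    stop_invalid("bin widths differ")
  cpp_diss_pair(r1$mat, r2$mat, as.integer(max_lag))
}

#' All pairwise response dissimilarities
#'
#' @param records list of >= 2 [response_record()]s of identical shape.
#' @param max_lag maximum absolute lag in bins.
#' @return an object of class `dissimilarity_matrix`: a symmetric E x E
#'   matrix with zero diagonal, with attributes `max_lag`, `ids`, `regimes`.
#' @export
dissimilarity_matrix <- function(records, max_lag = 5) {
  if (length(records) < 2) stop_invalid("need at least 2 records")
  dims <- vapply(records, function(r) dim(r$mat), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_invalid("all records must share one shape")
  D <- cpp_diss_matrix(lapply(records, function(r) r$mat),
                       as.integer(max_lag))
  ids <- vapply(records, function(r) as.character(r$id), character(1))
  dimnames(D) <- list(ids, ids)
  structure(D, max_lag = as.integer(max_lag), ids = ids,
            regimes = vapply(records, function(r) r$regime, character(1)),
            class = c("dissimilarity_matrix", "matrix"))
}

#' Hierarchical dynamical modes
#'
#' Agglomerative clustering of the experiment responses; each cluster at a cut
#' level is a dynamical "mode" — a class of similar internal responses — and
#' cutting at a coarser level always yields unions of finer-level clusters.
#' Each mode is summarised by its medoid response (the member minimising the
#' summed dissimilarity to the rest of its cluster).
#'
#' @param D a [dissimilarity_matrix()].
#' @param linkage agglomeration method (default `"average"`).
#' @param levels cluster counts at which to cut (default `c(2, 3)`).
#' @return an object of class `mode_hierarchy`: the `hclust` merge tree,
#'   `cuts` (named list: level -> integer assignments), and `medoids`
#'   (named list: level -> record index per cluster).
#' @export
hierarchical_modes <- function(D, linkage = "average", levels = c(2, 3)) {
  E <- nrow(D)
  levels <- sort(unique(as.integer(levels)))
  if (any(levels < 1) || any(levels > E))
    stop_invalid("cut levels must lie in 1..%d", E)
  hc <- hclust(as.dist(D), method = linkage)
  cuts <- lapply(levels, function(L) cutree(hc, k = L))
  names(cuts) <- as.character(levels)
  medoids <- lapply(cuts, function(assign) {
    vapply(sort(unique(assign)), function(cl) {
      members <- which(assign == cl)
      members[which.min(rowSums(D[members, members, drop = FALSE]))]
    }, integer(1))
  })
  structure(list(hclust = hc, cuts = cuts, medoids = medoids,
                 levels = levels, ids = attr(D, "ids"),
                 regimes = attr(D, "regimes")),
            class = "mode_hierarchy")
}

#' @export
print.mode_hierarchy <- function(x, ...) {
  cat(sprintf("mode_hierarchy over %d responses; cuts at %s modes\n",
              length(x$cuts[[1]]), paste(x$levels, collapse = ", ")))
  for (L in names(x$cuts)) {
    sizes <- table(x$cuts[[L]])
    cat(sprintf("  level %s: cluster sizes %s\n", L,
                paste(as.integer(sizes), collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.mode_hierarchy <- function(x, ...) {
  plot(x$hclust, labels = x$ids, xlab = "experiment", sub = "",
       main = "dynamical response modes", ...)
  invisible(x)
}

# mean between-cluster minus mean within-cluster dissimilarity at a k-cluster
# cut of D (the clustering-quality statistic used by the significance test)
cluster_separation_statistic <- function(D, level, linkage = "average") {
  hc <- hclust(as.dist(D), method = linkage)
  assign <- cutree(hc, k = level)
  same <- outer(assign, assign, "==") & upper.tri(D)
  diff <- (!outer(assign, assign, "==")) & upper.tri(D)
  w <- if (any(same)) mean(D[same]) else 0
  b <- if (any(diff)) mean(D[diff]) else 0
  b - w
}

#' Permutation significance of the mode clustering
#'
#' Whenever you look for clusters you will find some, even where there should
#' be none; this test quantifies whether the observed mode structure exceeds
#' that baseline.  The statistic is the mean between-cluster minus mean
#' within-cluster dissimilarity at the chosen cut.  The null is generated by
#' recomputing it on surrogate batteries in which each record's time bins are
#' circularly shifted by an independent random offset — destroying
#' regime-specific relative timing while preserving each record's marginal
#' structure.  The offset is drawn uniformly over all bins (including 0), so
#' under a structureless battery the observed statistic and the surrogates are
#' exchangeable and the p-value is exactly calibrated.
#'
#' @param records list of [response_record()]s.
#' @param n_perm number of surrogates (>= 1).
#' @param level cluster count at which the statistic is computed (default 2).
#' @param max_lag lag tolerance of the dissimilarity.
#' @param linkage agglomeration method.
#' @param seed seed for the surrogate offsets.
#' @return an object of class `significance_report`: `observed`, `null`
#'   (vector of surrogate statistics), `p_value`
#'   `= (1 + #\{null >= observed\}) / (1 + n_perm)`, `n_perm`, `seed`.
#' @export
clustering_significance <- function(records, n_perm, level = 2, max_lag = 5,
                                    linkage = "average", seed = 1) {
  n_perm <- check_count(n_perm, "n_perm")
  mats <- lapply(records, function(r) r$mat)
  ml <- as.integer(max_lag)
  obs <- cluster_separation_statistic(cpp_diss_matrix(mats, ml), level,
                                      linkage)
  nb <- ncol(mats[[1]])
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    shifted <- lapply(mats, function(m) {
      off <- sample.int(nb, 1) - 1L
      if (off == 0) m else m[, c((off + 1):nb, 1:off), drop = FALSE]
    })
    cluster_separation_statistic(cpp_diss_matrix(shifted, ml), level, linkage)
  }, numeric(1)))
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  structure(list(observed = obs, null = null, p_value = p,
                 n_perm = n_perm, level = level, seed = as.integer(seed)),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf(
    "clustering significance: statistic %.4f, null mean %.4f, p = %.4g (%d surrogates)\n",
    x$observed, mean(x$null), x$p_value, x$n_perm))
  invisible(x)
}

#' Mode exclusivity
#'
#' Modes are competitive: at any moment essentially one mode is active.  For a
#' windows x modes matrix of mode-activation probabilities this returns
#' `1 - mean_w H(p_w) / log M`, where `H` is Shannon entropy: 1 when exactly
#' one mode is active in every window, 0 under uniform co-activation.
#'
#' @param activations matrix (windows x M, M >= 2) of per-window mode
#'   distributions; rows are renormalised to sum to 1.
#' @return exclusivity in `[0, 1]`.
#' @export
mode_exclusivity <- function(activations) {
  activations <- as.matrix(activations)
  M <- ncol(activations)
  if (M < 2) stop_invalid("need at least 2 modes (got %d)", M)
  if (any(activations < 0)) stop_invalid("activations must be non-negative")
  p <- activations / rowSums(activations)
  H <- apply(p, 1, function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  })
  1 - mean(H) / log(M)
}

#' Preconditioning by an active mode
#'
#' Measures how a currently active mode biases the response to an ambiguous
#' incoming stimulus.  The ambiguous regime is run (a) from rest (random
#' initial phases) and (b) from states pre-driven by each priming regime for
#' `t_prime` time units (the ambiguous events then follow, shifted in time,
#' and only the post-priming window is recorded).  Each response is assigned
#' to the mode of its nearest medoid; the report compares the assignment
#' distributions.
#'
#' @param system a `clock_network` (the preconditioning probe is defined for
#'   clock systems, whose phase state carries the primed trace).
#' @param hierarchy a [hierarchical_modes()] result built from `records`.
#' @param records the battery the hierarchy was built from (medoid responses
#'   are looked up here).
#' @param priming_regimes named list of [clock_stimulus()] regimes to prime
#'   with; each must correspond to a mode in the hierarchy (majority cluster
#'   of its battery records).
#' @param ambiguous a [clock_stimulus()], e.g. from [mix_regimes()].
#' @param reps probe runs per arm.
#' @param level hierarchy cut level used for mode assignment.
#' @param t_prime priming duration (rounded to a sample grid multiple).
#' @param sample_dt sampling interval (must match the battery's bin width).
#' @param max_lag lag tolerance for nearest-medoid assignment.
#' @param seed master seed.
#' @return an object of class `preconditioning_report`: `unprimed`
#'   (assignment distribution over modes), `primed` (one distribution per
#'   priming regime), `index` (mean increase in the probability of the primed
#'   mode, clipped to `[0, 1]`), `entropy_reduction_bits`
#'   `= H2(unprimed) - mean H2(primed)` (may be negative; reported as-is),
#'   and `prime_modes` (the mode each priming regime maps to).
#' @export
preconditioning_index <- function(system, hierarchy, records, priming_regimes,
                                  ambiguous, reps = 10, level = 2,
                                  t_prime = NULL, sample_dt = NULL,
                                  max_lag = 5, seed = 1) {
  if (!inherits(system, "clock_network"))
    stop_invalid("system must be a clock_network")
  level <- as.character(level)
  if (!level %in% names(hierarchy$cuts))
    stop_invalid("hierarchy has no cut at level %s", level)
  assign_vec <- hierarchy$cuts[[level]]
  if (max(assign_vec) < 2) stop_invalid("need >= 2 modes at the chosen level")
  medoid_idx <- hierarchy$medoids[[level]]
  medoids <- records[medoid_idx]
  nb <- ncol(records[[1]]$mat)
  sample_dt <- sample_dt %||% records[[1]]$bin_width
  t_resp <- nb * sample_dt
  t_prime <- t_prime %||% t_resp
  t_prime <- round(t_prime / sample_dt) * sample_dt

  regimes <- vapply(records, function(r) r$regime, character(1))
  prime_modes <- vapply(priming_regimes, function(p) {
    members <- which(regimes == p$label)
    if (!length(members))
      stop_invalid("priming regime '%s' has no battery records", p$label)
    as.integer(names(which.max(table(assign_vec[members]))))
  }, integer(1))

  M <- max(assign_vec)
  assign_response <- function(mat) {
    d <- vapply(medoids, function(m)
      cpp_diss_pair(mat, m$mat, as.integer(max_lag)), numeric(1))
    as.integer(sort(unique(assign_vec))[which.min(d)])
  }

  seeds <- matrix(derive_seeds(seed, reps * (1 + length(priming_regimes))),
                  nrow = reps)
  unprimed_assign <- integer(reps)
  primed_assign <- matrix(NA_integer_, reps, length(priming_regimes))
  for (r in seq_len(reps)) {
    rec <- simulate_clock_network(system, ambiguous, t_end = t_resp,
                                  sample_dt = sample_dt,
                                  initial_phases = "random",
                                  seed = seeds[r, 1])
    unprimed_assign[r] <- assign_response(sin(trim_record(rec, 0, nb)))
    for (pi in seq_along(priming_regimes)) {
      p <- priming_regimes[[pi]]
      amb_shift <- ambiguous$events
      amb_shift$time <- amb_shift$time + t_prime
      combined <- clock_stimulus(
        paste0(p$label, "+", ambiguous$label),
        rbind(p$events[p$events$time < t_prime, , drop = FALSE], amb_shift))
      rec <- simulate_clock_network(system, combined,
                                    t_end = t_prime + t_resp,
                                    sample_dt = sample_dt,
                                    initial_phases = "random",
                                    seed = seeds[r, pi + 1])
      resp <- sin(trim_record(rec, round(t_prime / sample_dt), nb))
      primed_assign[r, pi] <- assign_response(resp)
    }
  }

  dist_of <- function(a) tabulate(a, nbins = M) / length(a)
  unprimed <- dist_of(unprimed_assign)
  primed <- lapply(seq_along(priming_regimes), function(pi)
    dist_of(primed_assign[, pi]))
  names(primed) <- names(priming_regimes) %||%
    vapply(priming_regimes, function(p) p$label, character(1))

  gain <- mean(vapply(seq_along(priming_regimes), function(pi)
    primed[[pi]][prime_modes[pi]] - unprimed[prime_modes[pi]], numeric(1)))
  h2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  structure(list(
    unprimed = unprimed, primed = primed,
    prime_modes = prime_modes,
    index = min(1, max(0, gain)),
    entropy_reduction_bits = h2(unprimed) -
      mean(vapply(primed, h2, numeric(1))),
    assignments = list(unprimed = unprimed_assign, primed = primed_assign),
    reps = reps, seed = as.integer(seed)),
    class = "preconditioning_report")
}

# columns [start_bin + 1, start_bin + nb] of a phase_record's sample matrix
trim_record <- function(rec, start_bin, nb) {
  rec$phases[, (start_bin + 1):(start_bin + nb), drop = FALSE]
}

#' @export
print.preconditioning_report <- function(x, ...) {
  cat("preconditioning report:\n  unprimed mode distribution: ",
      paste(sprintf("%.2f", x$unprimed), collapse = " "), "\n", sep = "")
  for (nm in names(x$primed))
    cat(sprintf("  primed by %-10s (mode %d): %s\n", nm,
                x$prime_modes[[nm]],
                paste(sprintf("%.2f", x$primed[[nm]]), collapse = " ")))
  cat(sprintf("  preconditioning index %.3f, entropy reduction %.3f bits\n",
              x$index, x$entropy_reduction_bits))
  invisible(x)
}

#' Mix two regimes into an ambiguous stimulus
#'
#' The default ambiguous probe: a 50/50 superposition in which each event of
#' either regime is kept independently with probability `p`.
#'
#' @param a,b [clock_stimulus()] regimes.
#' @param p keep probability per event.
#' @param seed seed for the subsampling (`NULL` keeps every event of both).
#' @return a [clock_stimulus()] labelled `"<a>|<b>"`.
#' @export
mix_regimes <- function(a, b, p = 0.5, seed = NULL) {
  ev <- rbind(a$events, b$events)
  if (!is.null(seed))
    ev <- with_seed(seed, ev[runif(nrow(ev)) < p, , drop = FALSE])
  ev <- ev[order(ev$time), , drop = FALSE]
  clock_stimulus(paste0(a$label, "|", b$label), ev)
}
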