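# Serialisation: networks as JSON (canonical) and GraphML (interoperability),
# edge lists and spike trains as CSV, configurations as YAML with JSON
# equivalence.  Real-valued times and delays are written at full double
# precision so that round trips are lossless to <= 1e-12 relative error.

#' Write a network to JSON
#'
#' Canonical serialisation for `column_network`, `outer_network`,
#' `network_of_networks` and `clock_network` objects; [read_network()]
#' reconstructs an object equal to the input (ids exactly, reals to full
#' double precision).
#'
#' @param x the network object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(x, path) {
  type <- class(x)[1]
  if (!type %in% c("column_network", "outer_network", "network_of_networks",
                   "clock_network"))
    stop_invalid("cannot serialise objects of class %s", type)
  payload <- unclass(x)
  if (type == "network_of_networks") {
    payload$columns <- lapply(payload$columns, unclass)
    payload$outer <- unclass(payload$outer)
  }
  if (type == "clock_network") payload$outer <- unclass(payload$outer)
  jsonlite::write_json(list(type = type, data = payload), path,
                       digits = NA, auto_unbox = TRUE, dataframe = "columns",
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path JSON file.
#' @return the reconstructed network object.
#' @export
read_network <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_data("%s: not valid JSON (%s)", path,
                              conditionMessage(e)))
  if (is.null(obj$type) || is.null(obj$data))
    stop_data("%s: expected fields 'type' and 'data'", path)
  d <- obj$data

  col_df <- function(e, cols, int_cols = character()) {
    out <- lapply(cols, function(nm) {
      v <- unlist(e[[nm]]) %||% numeric()
      if (nm %in% int_cols) as.integer(v) else as.numeric(v)
    })
    names(out) <- cols
    as.data.frame(out)
  }
  num_mat <- function(x, ncol) {
    if (is.null(x) || length(x) == 0) return(matrix(numeric(0), 0, ncol))
    do.call(rbind, lapply(x, function(row) as.numeric(unlist(row))))
  }
  scalars <- function(dst, src, names) {
    for (nm in names) dst[[nm]] <- unlist(src[[nm]]) %||% NULL
    dst
  }
  build_column <- function(cl) {
    out <- list(n = as.integer(cl$n),
                edges = col_df(cl$edges,
                               c("source", "target", "weight", "delay"),
                               c("source", "target")))
    out <- scalars(out, cl, c("density", "delay_range", "weight",
                              "inhibitory_frac", "seed"))
    structure(out, class = "column_network")
  }
  build_outer <- function(o) {
    structure(list(
      rows = as.integer(o$rows), cols = as.integer(o$cols),
      positions = col_df(o$positions, c("id", "row", "col"),
                         c("id", "row", "col")),
      edges = col_df(o$edges, c("source", "target"), c("source", "target")),
      beta = unlist(o$beta), lambda = unlist(o$lambda),
      cutoff = unlist(o$cutoff) %||% Inf, seed = unlist(o$seed)),
      class = "outer_network")
  }

  switch(obj$type,
    column_network = build_column(d),
    outer_network = build_outer(d),
    network_of_networks = {
      structure(list(
        columns = lapply(d$columns, build_column),
        inter_edges = col_df(d$inter_edges,
          c("source_col", "source_unit", "target_col", "target_unit",
            "weight", "delay"),
          c("source_col", "source_unit", "target_col", "target_unit")),
        outer = build_outer(d$outer),
        bridge_density = unlist(d$bridge_density),
        bridge_delay_range = unlist(d$bridge_delay_range),
        seed = unlist(d$seed)),
        class = "network_of_networks")
    },
    clock_network = {
      k <- as.integer(unlist(d$k))
      structure(list(
        n_clocks = as.integer(d$n_clocks), k = k,
        phases0 = num_mat(d$phases0, k[1]),
        rates = num_mat(d$rates, k[1]),
        edges = col_df(d$edges,
          c("sender", "receiver", "trigger_phase", "trigger_value", "delay"),
          c("sender", "receiver", "trigger_phase")),
        prm_type = unlist(d$prm_type),
        prm_val = num_mat(d$prm_val, k[1]),
        pull_strength = unlist(d$pull_strength),
        outer = build_outer(d$outer), seed = unlist(d$seed)),
        class = "clock_network")
    },
    stop_data("%s: unknown network type '%s'", path, obj$type))
}

#' Export a network edge list as CSV
#'
#' Header `source,target,weight,delay`.
#'
#' @param x a `column_network`.
#' @param path output file.
#' @export
write_edges_csv <- function(x, path) {
  if (!inherits(x, "column_network"))
    stop_invalid("edge-list CSV export is defined for column_network")
  write.csv(format(x$edges, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Writes the directed graph with `weight` and `delay` edge attributes via
#' igraph, for interoperability with external graph tools.
#'
#' @param x a `column_network`.
#' @param path output file.
#' @export
write_graphml <- function(x, path) {
  if (!inherits(x, "column_network"))
    stop_invalid("GraphML export is defined for column_network")
  g <- igraph::make_empty_graph(n = x$n, directed = TRUE)
  if (nrow(x$edges))
    g <- igraph::add_edges(g, rbind(x$edges$source + 1L, x$edges$target + 1L),
                           weight = x$edges$weight, delay = x$edges$delay)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file into a column network
#'
#' @param path GraphML file written by [write_graphml()].
#' @return a `column_network` (generation parameters are not recoverable from
#'   GraphML and are set to `NA`).
#' @export
read_graphml <- function(path) {
  g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                error = function(e)
                  stop_data("%s: not valid GraphML (%s)", path,
                            conditionMessage(e)))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(source = as.integer(el[, 1]) - 1L,
                      target = as.integer(el[, 2]) - 1L,
                      weight = igraph::edge_attr(g, "weight") %||%
                        rep(NA_real_, nrow(el)),
                      delay = igraph::edge_attr(g, "delay") %||%
                        rep(NA_real_, nrow(el)))
  structure(list(n = igraph::vcount(g), edges = edges, density = NA_real_,
                 delay_range = c(NA_real_, NA_real_), weight = NA_real_,
                 inhibitory_frac = NA_real_, seed = NA_integer_),
            class = "column_network")
}

#' Write a spike train
#'
#' CSV export (`unit,time` with header) and a lossless JSON form carrying
#' `t_end` and the observed unit set as well.
#'
#' @param x a `spike_train`.
#' @param path output file; extension `.json` selects the JSON form, anything
#'   else CSV.
#' @export
write_spike_train <- function(x, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(events = x$events, t_end = x$t_end,
                              observed = x$observed),
                         path, digits = NA, dataframe = "columns",
                         auto_unbox = TRUE)
  } else {
    df <- data.frame(unit = x$events$unit,
                     time = format(x$events$time, digits = 15, trim = TRUE,
                                   scientific = FALSE))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a spike train
#'
#' @param path a file written by [write_spike_train()].
#' @param t_end,observed metadata to attach when reading the CSV form (the
#'   JSON form carries its own).
#' @return a `spike_train`.
#' @export
read_spike_train <- function(path, t_end = NULL, observed = NULL) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    ev <- if (NROW(obj$events) == 0)
      data.frame(unit = integer(), time = numeric())
    else as.data.frame(obj$events)
    return(structure(list(events = ev, t_end = obj$t_end,
                          observed = as.integer(obj$observed),
                          deliveries = NULL),
                     class = "spike_train"))
  }
  lines <- readLines(path)
  if (!length(lines) || !identical(lines[1], "unit,time"))
    stop_data("%s: expected header 'unit,time'", path)
  ev <- data.frame(unit = integer(), time = numeric())
  if (length(lines) > 1) {
    parts <- strsplit(lines[-1], ",", fixed = TRUE)
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      if (length(p) != 2)
        stop_data("%s line %d: expected 2 fields 'unit,time', found %d",
                  path, i + 1L, length(p))
      tm <- suppressWarnings(as.numeric(p[2]))
      if (is.na(tm))
        stop_data("%s line %d: field 'time' is not numeric: '%s'",
                  path, i + 1L, p[2])
      un <- suppressWarnings(as.integer(p[1]))
      if (is.na(un))
        stop_data("%s line %d: field 'unit' is not an integer: '%s'",
                  path, i + 1L, p[1])
    }
    ev <- data.frame(unit = as.integer(vapply(parts, `[`, "", 1)),
                     time = as.numeric(vapply(parts, `[`, "", 2)))
  }
  structure(list(events = ev,
                 t_end = t_end %||% if (nrow(ev)) max(ev$time) else 0,
                 observed = observed %||% sort(unique(ev$unit)),
                 deliveries = NULL),
            class = "spike_train")
}

#' Export a clock-network event log as CSV
#'
#' Header `edge,emit_time,arrival_time`.
#'
#' @param x a `phase_record`.
#' @param path output file.
#' @export
write_event_log_csv <- function(x, path) {
  df <- data.frame(edge = x$events$edge,
                   emit_time = format(x$events$emit_time, digits = 15,
                                      trim = TRUE, scientific = FALSE),
                   arrival_time = format(x$events$arrival_time, digits = 15,
                                         trim = TRUE, scientific = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' A bag of named parameters with a mandatory master seed; round-trips
#' losslessly through YAML (canonical) or JSON.
#'
#' @param seed master seed (mandatory: no silent entropy).
#' @param ... further named parameters (scalars, vectors, nested lists).
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed, ...) {
  if (missing(seed)) stop_invalid("a run_config requires an explicit seed")
  seed <- check_count(seed, "seed", min = 0)
  structure(c(list(seed = seed), list(...)), class = "run_config")
}

#' Write a configuration
#'
#' @param x a [run_config()].
#' @param path output file; extension `.json` selects JSON, anything else
#'   YAML.
#' @export
write_config <- function(x, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(unclass(x), path, digits = NA, auto_unbox = TRUE)
  else
    writeLines(yaml::as.yaml(unclass(x), precision = 15), path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#'
#' @param path YAML or JSON file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else tryCatch(yaml::read_yaml(path),
                error = function(e)
                  stop_data("%s: not valid YAML (%s)", path,
                            conditionMessage(e)))
  if (is.null(obj$seed)) stop_data("%s: config lacks a seed", path)
  obj$seed <- as.integer(obj$seed)
  structure(obj, class = "run_config")
}
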