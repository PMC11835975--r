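#' Populations, projections and execution instances
#'
#' A network is a list of populations (groups of neurons sharing parameters)
#' connected by projections (weight matrices), with every non-input
#' population assigned to exactly one *execution instance* -- the unit that
#' fits and runs on one substrate allocation. Input populations are pure
#' spike sources: their events are supplied externally to every run that
#' consumes them, so they carry no instance of their own.
#'
#' @param name Population name (unique within a network).
#' @param size Neuron count.
#' @param params A [lif_params()] (ignored for input populations).
#' @param instance Execution-instance id (character); `NA` for inputs.
#' @param is_input If `TRUE` the population is an external spike source.
#' @param record_spikes,record_membrane Observable recording flags.
#' @return An object of class `snn_population`.
#' @export
population <- function(name, size, params = lif_params(), instance = NA,
                       is_input = FALSE, record_spikes = TRUE,
                       record_membrane = FALSE) {
  stopifnot(is.character(name), is_count(size))
  if (!is_input) {
    stopifnot(inherits(params, "lif_params"))
    if (!params$leaky_integrate_only && params$v_th <= params$v_reset)
      stop("spiking population needs v_th > v_reset")
  }
  structure(list(name = name, size = as.integer(size), params = params,
                 instance = if (is.na(instance)) NA_character_
                            else as.character(instance),
                 is_input = isTRUE(is_input),
                 record_spikes = isTRUE(record_spikes),
                 record_membrane = isTRUE(record_membrane)),
            class = "snn_population")
}

#' @rdname population
#' @param source,target Population names.
#' @param weights Either a dense `(size_source, size_target)` matrix, or for
#'   `connectivity = "explicit"` a data frame with columns `i` (source neuron),
#'   `j` (target neuron), `w` (weight), internally expanded to dense.
#' @param connectivity `"dense"` or `"explicit"`.
#' @export
projection <- function(source, target, weights,
                       connectivity = c("dense", "explicit")) {
  connectivity <- match.arg(connectivity)
  if (connectivity == "explicit") {
    stopifnot(is.data.frame(weights),
              all(c("i", "j", "w") %in% names(weights)))
    pairs <- weights
    if (any(!is.finite(pairs$w))) stop("weights must be finite")
    W <- NULL
    attr_pairs <- pairs
  } else {
    W <- as.matrix(weights)
    if (any(!is.finite(W))) stop("weights must be finite")
    attr_pairs <- NULL
  }
  structure(list(source = source, target = target, W = W,
                 pairs = attr_pairs, connectivity = connectivity),
            class = "snn_projection")
}

#' Assemble a spiking network
#'
#' @param populations List of [population()]s.
#' @param projections List of [projection()]s.
#' @return Object of class `snn_network`.
#' @export
snn_network <- function(populations, projections = list()) {
  names(populations) <- vapply(populations, `[[`, character(1), "name")
  if (anyDuplicated(names(populations)))
    stop("population names must be unique")
  for (pr in projections) {
    if (!pr$source %in% names(populations) ||
        !pr$target %in% names(populations))
      stop(sprintf("projection %s -> %s references unknown population",
                   pr$source, pr$target))
    tgt <- populations[[pr$target]]
    if (tgt$is_input) stop("projections cannot target input populations")
    src <- populations[[pr$source]]
    if (pr$connectivity == "explicit") {
      if (any(pr$pairs$i < 1) || any(pr$pairs$i > src$size) ||
          any(pr$pairs$j < 1) || any(pr$pairs$j > tgt$size))
        stop("explicit connectivity indices outside population sizes")
    } else if (nrow(pr$W) != src$size || ncol(pr$W) != tgt$size) {
      stop(sprintf("projection %s -> %s weight shape (%d, %d) != (%d, %d)",
                   pr$source, pr$target, nrow(pr$W), ncol(pr$W),
                   src$size, tgt$size))
    }
  }
  structure(list(populations = populations, projections = projections),
            class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("<snn_network> %d population(s), %d projection(s)\n",
              length(x$populations), length(x$projections)))
  for (p in x$populations) {
    cat(sprintf("  %-12s size %4d  %s%s\n", p$name, p$size,
                if (p$is_input) "input"
                else if (p$params$leaky_integrate_only) "LI " else "LIF",
                if (!is.na(p$instance)) paste0("  @", p$instance) else ""))
  }
  invisible(x)
}

proj_matrix <- function(pr, net) {
  if (pr$connectivity == "explicit") {
    W <- matrix(0, net$populations[[pr$source]]$size,
                net$populations[[pr$target]]$size)
    W[cbind(pr$pairs$i, pr$pairs$j)] <- pr$pairs$w
    W
  } else pr$W
}

#' Derive inter-execution projections
#'
#' Scans the network topology for projections whose source and target live in
#' different execution instances; each becomes an inter-execution projection:
#' the recorded output events of the source instance are translated (source
#' neuron id to target input label, here the identity on the projection's
#' source population) and played back into the target instance.
#' Within-instance projections are untouched. Projections out of input
#' populations never cross: external stimuli are delivered to each consuming
#' run directly.
#'
#' @param net An [snn_network()].
#' @return List of inter-execution projections, each
#'   `list(source_instance, target_instance, source, target, translation)`.
#' @export
derive_inter_execution <- function(net) {
  stopifnot(inherits(net, "snn_network"))
  for (p in net$populations) {
    if (!p$is_input && is.na(p$instance))
      stop(sprintf("population '%s' is not assigned to an execution instance",
                   p$name))
  }
  out <- list()
  for (pr in net$projections) {
    src <- net$populations[[pr$source]]
    tgt <- net$populations[[pr$target]]
    if (src$is_input) next
    if (!identical(src$instance, tgt$instance)) {
      out[[length(out) + 1L]] <- list(
        source_instance = src$instance,
        target_instance = tgt$instance,
        source = pr$source, target = pr$target,
        translation = stats::setNames(seq_len(src$size), seq_len(src$size)))
    }
  }
  out
}

#' Schedule execution instances into sequential stages
#'
#' Builds the inter-execution dependency DAG and returns a layered topological
#' order: instances in the same stage have no mutual data dependency and are
#' eligible for concurrent execution on a large enough multi-chip system;
#' stages run sequentially. Within a stage, instances are sorted by id so runs
#' are reproducible. The number of stages equals the longest dependency-path
#' length. A dependency cycle between instances is an error: recurrence must
#' be confined to a single execution instance.
#'
#' @param net An [snn_network()].
#' @return List of character vectors (instance ids), one per stage.
#' @export
schedule <- function(net) {
  iep <- derive_inter_execution(net)
  insts <- sort(unique(stats::na.omit(
    vapply(net$populations, `[[`, character(1), "instance"))))
  edges <- unique(do.call(rbind, c(list(
    data.frame(from = character(), to = character())),
    lapply(iep, function(e)
      data.frame(from = e$source_instance, to = e$target_instance)))))
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  indeg <- stats::setNames(integer(length(insts)), insts)
  for (t in edges$to) indeg[t] <- indeg[t] + 1L
  stages <- list()
  remaining <- insts
  while (length(remaining)) {
    ready <- remaining[indeg[remaining] == 0L]
    if (!length(ready))
      stop(paste("cross-instance recurrent dependency detected:",
                 "recurrence must be confined to one execution instance"))
    ready <- sort(ready)
    stages[[length(stages) + 1L]] <- ready
    remaining <- setdiff(remaining, ready)
    drop <- edges$from %in% ready
    for (t in edges$to[drop]) indeg[t] <- indeg[t] - 1L
    edges <- edges[!drop, , drop = FALSE]
  }
  stages
}

#' Run a partitioned network
#'
#' Executes the network's instances in schedule order through the lattice
#' emulator: each instance integrates its populations, its recorded spike
#' events are translated and replayed into dependent instances (timestamps
#' preserved unchanged -- inter-instance communication is buffered, not
#' real-time), and all recorded observables are returned. With
#' `mode = "constrained"`, each instance quantizes its weights, passes its
#' external input events through the bandwidth limit, and clips recorded
#' traces.
#'
#' Merged replayed streams are ordered by (sample, time, source population,
#' neuron); the order only matters for bandwidth-limit tie-breaking since
#' within-bin drive accumulation is commutative.
#'
#' @param net An [snn_network()].
#' @param stimuli An [event_batch()] covering every input population.
#' @param T Window length (us).
#' @param dt Lattice step (us).
#' @param mode `"ideal"` or `"constrained"`.
#' @param spec A [chip_spec()].
#' @param cycle,queue_depth Bandwidth parameters (constrained mode).
#' @return Object of class `snn_run`: `events` and `traces` keyed by
#'   population, `by_instance` grouping population names per instance,
#'   `schedule`, `n_dropped` per instance, plus `T`, `dt`, `mode`.
#' @export
run_network <- function(net, stimuli, T, dt = 0.5,
                        mode = c("ideal", "constrained"),
                        spec = chip_spec(), cycle = 0.008, queue_depth = 4L) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "snn_network"), inherits(stimuli, "event_batch"))
  stages <- schedule(net)
  B <- n_samples(stimuli)
  if (B < 1) stop("stimuli contain no samples")
  input_pops <- names(net$populations)[vapply(net$populations, `[[`,
                                              logical(1), "is_input")]
  miss <- setdiff(input_pops,
                  intersect(input_pops, unique(stimuli$population)))
  # an input population with no outgoing projection may legitimately be silent
  used_inputs <- unique(vapply(net$projections, `[[`, character(1), "source"))
  miss <- intersect(miss, used_inputs)
  if (length(miss))
    stop("missing stimulus for input population(s): ",
         paste(miss, collapse = ", "))

  pop_inst <- vapply(net$populations, `[[`, character(1), "instance")
  all_events <- list()
  all_traces <- list()
  n_dropped <- stats::setNames(integer(0), character(0))

  for (stage in stages) {
    for (inst in stage) {
      is_inp <- vapply(net$populations, `[[`, logical(1), "is_input")
      local_pops <- names(net$populations)[!is_inp & !is.na(pop_inst) &
                                             pop_inst == inst]
      projs <- Filter(function(pr) pr$target %in% local_pops,
                      net$projections)
      # drivers: input populations and remote source populations
      drv <- unique(vapply(projs, `[[`, character(1), "source"))
      drv <- setdiff(drv, local_pops)
      pops <- list()
      for (nm in local_pops) {
        p <- net$populations[[nm]]
        pops[[nm]] <- list(size = p$size, params = p$params, is_input = FALSE,
                           record_spikes = TRUE,
                           record_membrane = p$record_membrane)
      }
      for (nm in drv) {
        pops[[nm]] <- list(size = net$populations[[nm]]$size, is_input = TRUE)
      }
      ext <- list()
      for (nm in drv) {
        ext[[nm]] <- if (net$populations[[nm]]$is_input) {
          ev <- stimuli[stimuli$population == nm, , drop = FALSE]
          event_batch(ev$sample_id, ev$time_us, ev$population, ev$neuron_id,
                      n_samples = B)
        } else {
          all_events[[nm]]  # replayed from the source instance, times kept
        }
      }
      ext_events <- if (length(ext)) do.call(rbind_events,
                                             c(unname(ext),
                                               list(n_samples = B)))
                    else event_batch(n_samples = B)
      pl <- lapply(projs, function(pr)
        list(source = pr$source, target = pr$target,
             W = proj_matrix(pr, net)))
      res <- integrate_populations(pops, pl, ext_events, B, T, dt, mode,
                                   spec, cycle, queue_depth)
      for (nm in local_pops) {
        all_events[[nm]] <- res$events[[nm]]
        if (!is.null(res$traces[[nm]])) all_traces[[nm]] <- res$traces[[nm]]
      }
      n_dropped[inst] <- res$n_dropped
    }
  }
  by_instance <- split(names(pop_inst)[!is.na(pop_inst)],
                       pop_inst[!is.na(pop_inst)])
  structure(list(events = all_events, traces = all_traces,
                 by_instance = by_instance, schedule = stages,
                 n_dropped = n_dropped, T = T, dt = dt, mode = mode),
            class = "snn_run")
}

#' @export
print.snn_run <- function(x, ...) {
  cat(sprintf("<snn_run> mode %s, T = %g us, dt = %g us\n", x$mode, x$T,
              x$dt))
  cat(sprintf("  schedule: %s\n",
              paste(vapply(x$schedule, function(s)
                paste0("{", paste(s, collapse = ","), "}"), character(1)),
                collapse = " -> ")))
  for (nm in names(x$events)) {
    cat(sprintf("  %-12s %d spike(s)%s\n", nm, nrow(x$events[[nm]]),
                if (!is.null(x$traces[[nm]])) ", traces recorded" else ""))
  }
  if (any(x$n_dropped > 0))
    cat(sprintf("  dropped events: %s\n",
                paste(names(x$n_dropped), x$n_dropped, sep = "=",
                      collapse = ", ")))
  invisible(x)
}
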