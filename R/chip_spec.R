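#' Substrate resource description
#'
#' A `chip_spec` collects the resource constants of a single neuromorphic
#' substrate (one accelerator chip): how many analog neuron circuits it has,
#' the synaptic fan-in per circuit, how hardware synapses are paired to form
#' signed weights, weight resolution, how many event labels a synapse row can
#' distinguish, the event-link capacity, the readout clipping range of the
#' membrane ADC, and the multiplicative routing factors that bound on-chip
#' fan-out. The defaults reproduce the single-chip BrainScaleS-2 constants:
#' 512 neuron circuits, fan-in 256 per circuit, two 6-bit synapses per signed
#' weight, 64 labels per synapse row, and two events per link clock cycle.
#'
#' @param n_circuits Number of physical neuron circuits.
#' @param fan_in_per_circuit Hardware synapses (unsigned weights) per circuit.
#' @param synapses_per_signed_weight Hardware synapses used to represent one
#'   signed weight (2 = one excitatory + one inhibitory row).
#' @param weight_levels Levels per hardware synapse (64 = 6 bit).
#' @param labels_per_row Distinct event labels addressable on one synapse row.
#' @param max_events_per_cycle Spike events the event link processes per
#'   clock cycle.
#' @param readout_range Length-2 numeric, dimensionless clipping bounds applied
#'   to recorded membrane samples in constrained mode.
#' @param fanout_factors Multiplicative routing factors whose product is the
#'   maximum on-chip fan-out of one neuron.
#' @return An object of class `chip_spec`.
#' @examples
#' spec <- chip_spec()
#' max_fanout(spec)        # 32768
#' max_signed_fan_in(spec) # 65536
#' @export
chip_spec <- function(n_circuits = 512L,
                      fan_in_per_circuit = 256L,
                      synapses_per_signed_weight = 2L,
                      weight_levels = 64L,
                      labels_per_row = 64L,
                      max_events_per_cycle = 2L,
                      readout_range = c(-1, 1),
                      fanout_factors = c(2L, 32L, 2L, 256L)) {
  counts <- c(n_circuits = n_circuits,
              fan_in_per_circuit = fan_in_per_circuit,
              synapses_per_signed_weight = synapses_per_signed_weight,
              weight_levels = weight_levels,
              labels_per_row = labels_per_row,
              max_events_per_cycle = max_events_per_cycle)
  if (any(counts < 1) || any(counts != as.integer(counts)))
    stop("all chip_spec counts must be integers >= 1")
  if (length(readout_range) != 2L || readout_range[1] >= readout_range[2])
    stop("readout_range must be (lo, hi) with lo < hi")
  if (length(fanout_factors) < 1L || any(fanout_factors < 1))
    stop("fanout_factors must be counts >= 1")
  structure(list(
    n_circuits = as.integer(n_circuits),
    fan_in_per_circuit = as.integer(fan_in_per_circuit),
    synapses_per_signed_weight = as.integer(synapses_per_signed_weight),
    weight_levels = as.integer(weight_levels),
    labels_per_row = as.integer(labels_per_row),
    max_events_per_cycle = as.integer(max_events_per_cycle),
    readout_range = as.numeric(readout_range),
    fanout_factors = as.integer(fanout_factors)
  ), class = "chip_spec")
}

#' @export
print.chip_spec <- function(x, ...) {
  cat("<chip_spec>\n")
  cat(sprintf("  neuron circuits      : %d\n", x$n_circuits))
  cat(sprintf("  fan-in per circuit   : %d hardware synapses\n",
              x$fan_in_per_circuit))
  cat(sprintf("  signed weight        : %d synapses, %d levels each\n",
              x$synapses_per_signed_weight, x$weight_levels))
  cat(sprintf("  labels per row       : %d\n", x$labels_per_row))
  cat(sprintf("  events per cycle     : %d\n", x$max_events_per_cycle))
  cat(sprintf("  readout range        : [%g, %g]\n",
              x$readout_range[1], x$readout_range[2]))
  cat(sprintf("  max fan-out          : %d (= %s)\n", max_fanout(x),
              paste(x$fanout_factors, collapse = " x ")))
  cat(sprintf("  max signed fan-in    : %d\n", max_signed_fan_in(x)))
  invisible(x)
}

#' Load a chip spec from a YAML or JSON config
#'
#' Fields not present in the file keep their defaults; unknown fields are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML or JSON file with `chip_spec` field names.
#' @return A [chip_spec()].
#' @export
read_chip_spec <- function(path) {
  cfg <- read_config(path)
  chip_spec_from_list(cfg)
}

chip_spec_from_list <- function(cfg) {
  stopifnot(is.list(cfg))
  allowed <- names(formals(chip_spec))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown chip_spec fields: ", paste(bad, collapse = ", "))
  do.call(chip_spec, cfg)
}

#' Neuron circuits needed for a given signed fan-in
#'
#' Physical neuron circuits can be combined (shorted) to multiply the synaptic
#' fan-in of one logical neuron: each extra circuit contributes its full
#' complement of hardware synapses. Circuits combine in powers of two, so the
#' result is the smallest power of two `p` with
#' `p * fan_in_per_circuit >= synapses_per_signed_weight * fan_in_signed`.
#'
#' @param fan_in_signed Number of signed synaptic inputs the logical neuron
#'   must receive.
#' @param spec A [chip_spec()].
#' @return Integer count of combined circuits per logical neuron.
#' @examples
#' circuits_per_neuron(784) # 8: 28x28 image, one signed weight per pixel
#' circuits_per_neuron(484) # 4
#' @export
circuits_per_neuron <- function(fan_in_signed, spec = chip_spec()) {
  stopifnot(inherits(spec, "chip_spec"))
  fan_in_signed <- as.integer(fan_in_signed)
  if (length(fan_in_signed) != 1L || is.na(fan_in_signed) || fan_in_signed < 1L)
    stop("fan_in_signed must be a single count >= 1")
  limit <- max_signed_fan_in(spec)
  if (fan_in_signed > limit)
    stop(sprintf(paste0("fan-in %d exceeds full-chip capacity of %d signed ",
                        "weights (%d circuits x %d synapses / %d per signed ",
                        "weight)"),
                 fan_in_signed, limit, spec$n_circuits,
                 spec$fan_in_per_circuit, spec$synapses_per_signed_weight))
  need <- spec$synapses_per_signed_weight * as.numeric(fan_in_signed)
  p <- 1L
  while (p * spec$fan_in_per_circuit < need) p <- p * 2L
  p
}

#' Logical neurons available in one run
#'
#' Combining `cpn` circuits per logical neuron leaves
#' `n_circuits / cpn` logical neurons per substrate execution.
#'
#' @param cpn Circuits combined per logical neuron; must divide `n_circuits`.
#' @param spec A [chip_spec()].
#' @return Integer neuron count per run.
#' @examples
#' neurons_per_run(8) # 64
#' @export
neurons_per_run <- function(cpn, spec = chip_spec()) {
  stopifnot(inherits(spec, "chip_spec"))
  cpn <- as.integer(cpn)
  if (length(cpn) != 1L || is.na(cpn) || cpn < 1L)
    stop("cpn must be a single count >= 1")
  if (spec$n_circuits %% cpn != 0L)
    stop(sprintf("cpn = %d does not divide the %d available neuron circuits",
                 cpn, spec$n_circuits))
  spec$n_circuits %/% cpn
}

#' Maximum on-chip fan-out of a single neuron
#'
#' Product of the routing fan-out factors (default 2 x 32 x 2 x 256 = 32768
#' synapses).
#'
#' @param spec A [chip_spec()].
#' @return Integer fan-out bound.
#' @export
max_fanout <- function(spec = chip_spec()) {
  stopifnot(inherits(spec, "chip_spec"))
  as.integer(prod(spec$fanout_factors))
}

#' Maximum signed fan-in of one logical neuron using the whole chip
#'
#' `n_circuits * fan_in_per_circuit / synapses_per_signed_weight`: combining
#' every circuit into one logical neuron, each signed weight costing
#' `synapses_per_signed_weight` hardware synapses.
#'
#' @param spec A [chip_spec()].
#' @return Integer signed fan-in bound.
#' @export
max_signed_fan_in <- function(spec = chip_spec()) {
  stopifnot(inherits(spec, "chip_spec"))
  as.integer(spec$n_circuits * spec$fan_in_per_circuit /
               spec$synapses_per_signed_weight)
}
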