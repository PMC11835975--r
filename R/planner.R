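#' Plan one layer onto the substrate
#'
#' Computes how many sequential runs a fully connected layer needs: the signed
#' fan-in fixes the circuits combined per logical neuron (powers of two, see
#' [circuits_per_neuron()]), which fixes the logical neurons available per run;
#' the layer is then split into `ceil(size / neurons_per_run)` parts.
#' `parts_override` forces extra splitting beyond the capacity minimum, e.g.
#' to lower the per-run input event rate when the event link would otherwise
#' saturate.
#'
#' @param size Layer size (neurons).
#' @param fan_in_signed Signed synaptic inputs per neuron.
#' @param spec A [chip_spec()].
#' @param parts_override Optional count forcing at least this many runs; must
#'   not be below the capacity minimum.
#' @param name Optional layer name used in printing.
#' @return An object of class `layer_plan`.
#' @examples
#' plan_layer(256, 784)      # 4 runs of 64 neurons
#' plan_layer(10, 256)       # readout fits one run
#' @export
plan_layer <- function(size, fan_in_signed, spec = chip_spec(),
                       parts_override = NULL, name = "layer") {
  stopifnot(is_count(size), is_count(fan_in_signed))
  cpn <- circuits_per_neuron(fan_in_signed, spec)
  npr <- neurons_per_run(cpn, spec)
  n_min <- as.integer(ceiling(size / npr))
  n_runs <- n_min
  if (!is.null(parts_override)) {
    stopifnot(is_count(parts_override))
    if (parts_override < n_min)
      stop(sprintf("parts_override = %d below the capacity minimum of %d runs",
                   as.integer(parts_override), n_min))
    n_runs <- as.integer(parts_override)
  }
  structure(list(name = name,
                 size = as.integer(size),
                 fan_in_signed = as.integer(fan_in_signed),
                 circuits_per_neuron = cpn,
                 neurons_per_run = npr,
                 n_runs = n_runs,
                 parts_override = if (is.null(parts_override)) NA_integer_
                                  else as.integer(parts_override)),
            class = "layer_plan")
}

#' @export
print.layer_plan <- function(x, ...) {
  cat(sprintf("<layer_plan> %s: %d neurons, fan-in %d -> %d circuits/neuron, %d neurons/run, %d run(s)\n",
              x$name, x$size, x$fan_in_signed, x$circuits_per_neuron,
              x$neurons_per_run, x$n_runs))
  invisible(x)
}

#' Plan a whole feed-forward network onto the substrate
#'
#' @param layers A data frame (or list of lists) with columns `name`, `size`,
#'   `fan_in` and optionally `parts_override` (NA where unused), one row per
#'   neuron layer in order. The input layer is not listed: it only supplies
#'   events and occupies no neuron circuits.
#' @param spec A [chip_spec()].
#' @return An object of class `partition_plan` with per-layer plans and
#'   `total_runs`.
#' @examples
#' # 28x28 -> 256 LIF -> 10 LI readout: five sequential runs
#' plan_network(data.frame(name = c("hidden", "readout"),
#'                         size = c(256, 10), fan_in = c(784, 256)))
#' @export
plan_network <- function(layers, spec = chip_spec()) {
  if (is.data.frame(layers)) {
    layers <- lapply(seq_len(nrow(layers)), function(i) as.list(layers[i, ]))
  }
  plans <- lapply(layers, function(l) {
    ov <- l$parts_override
    if (!is.null(ov) && (length(ov) != 1L || is.na(ov))) ov <- NULL
    plan_layer(l$size, l$fan_in, spec, parts_override = ov,
               name = l$name %||% "layer")
  })
  structure(list(layers = plans,
                 total_runs = sum(vapply(plans, `[[`, integer(1), "n_runs"))),
            class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat("<partition_plan>\n")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  cat(sprintf("total runs: %d\n", x$total_runs))
  invisible(x)
}

#' @export
as.data.frame.partition_plan <- function(x, ...) {
  do.call(rbind, lapply(x$layers, function(l) {
    data.frame(layer = l$name, size = l$size, fan_in = l$fan_in_signed,
               circuits_per_neuron = l$circuits_per_neuron,
               neurons_per_run = l$neurons_per_run, runs = l$n_runs)
  }))
}

#' Fit a sparse receptive-field projection via row labels
#'
#' A synapse row distinguishes `labels_per_row` event labels, so up to that
#' many neurons can be addressed through the same physical row. A layer whose
#' neurons each read a disjoint receptive field of `receptive_field_size`
#' inputs can therefore be packed in blocks of
#' `receptive_field_size x labels_per_row` signed synapses. The layout is
#' feasible in a single run when the blocks fit the synapse rows of one
#' circuit column set and the neurons fit the available circuits.
#'
#' @param receptive_field_size Inputs per neuron (block row count).
#' @param n_neurons Layer size.
#' @param spec A [chip_spec()].
#' @return List with `rows_per_block`, `neurons_per_block`, `n_blocks`,
#'   `rows_used`, and logical `feasible` (single-run feasibility; infeasible
#'   layouts are flagged, not an error).
#' @examples
#' sparse_label_fit(27, 484)  # 8 blocks of 27 x 64, one run
#' @export
sparse_label_fit <- function(receptive_field_size, n_neurons,
                             spec = chip_spec()) {
  stopifnot(is_count(receptive_field_size), is_count(n_neurons),
            inherits(spec, "chip_spec"))
  npb <- spec$labels_per_row
  n_blocks <- as.integer(ceiling(n_neurons / npb))
  rows_used <- as.integer(n_blocks * receptive_field_size)
  feasible <- n_neurons <= spec$n_circuits &&
    rows_used <= spec$fan_in_per_circuit
  list(rows_per_block = as.integer(receptive_field_size),
       neurons_per_block = as.integer(npb),
       n_blocks = n_blocks,
       rows_used = rows_used,
       feasible = feasible)
}

#' Receptive-field tiling of an image
#'
#' Tiles an `H x W x C` input with `h x w x c` kernels moved over the spatial
#' coordinates with stride `s`. Borders are zero-padded, i.e. the grid side is
#' `ceil(H / s)` (and `ceil(W / s)`); padded positions simply contribute no
#' input. Each neuron reads the full channel depth of its window, so with
#' stride >= kernel the per-neuron input sets are disjoint.
#'
#' @param input_shape Integer vector `c(H, W, C)`.
#' @param kernel Integer vector `c(h, w, c)`; `c` must equal `C`.
#' @param stride Positive integer spatial stride.
#' @return List with `grid` (`c(rows, cols)`), `n_neurons`,
#'   `inputs_per_neuron` (kernel volume), and `indices`: per neuron, the
#'   linear indices (into the `H x W x C` array, H fastest) of its in-bounds
#'   input pixels.
#' @examples
#' g <- receptive_field_grid(c(64, 64, 3), c(3, 3, 3), 3)
#' g$n_neurons          # 484
#' g$inputs_per_neuron  # 27
#' @export
receptive_field_grid <- function(input_shape, kernel, stride) {
  stopifnot(length(input_shape) == 3L, length(kernel) == 3L)
  if (!is_count(stride)) stop("stride must be a positive integer")
  if (any(kernel > input_shape))
    stop("kernel dimensions must not exceed input dimensions")
  if (kernel[3] != input_shape[3])
    stop("kernel must span the full channel depth")
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  gh <- ceiling(H / stride); gw <- ceiling(W / stride)
  idx <- vector("list", gh * gw)
  n <- 0L
  for (gc in seq_len(gw)) {
    for (gr in seq_len(gh)) {
      n <- n + 1L
      rows <- (gr - 1L) * stride + seq_len(kernel[1])
      cols <- (gc - 1L) * stride + seq_len(kernel[2])
      rows <- rows[rows <= H]
      cols <- cols[cols <= W]
      # linear index into H x W x C, H fastest
      idx[[n]] <- as.integer(outer(outer(rows, (cols - 1L) * H, `+`),
                                   (seq_len(C) - 1L) * H * W, `+`))
    }
  }
  list(grid = c(as.integer(gh), as.integer(gw)),
       n_neurons = as.integer(gh * gw),
       inputs_per_neuron = as.integer(prod(kernel)),
       indices = idx)
}

#' Spatially unroll a convolutional layer
#'
#' On a substrate with dedicated synapse circuits, convolutions are unrolled:
#' every output pixel of every output channel becomes one logical neuron with
#' fan-in `h x w x C_in` (the kernel volume). The output grid uses the same
#' zero-padded ceiling-division convention as [receptive_field_grid()].
#'
#' @param input_shape `c(H, W, C_in)`.
#' @param kernel `c(h, w)` spatial kernel size.
#' @param stride Spatial stride.
#' @param out_channels Number of output feature planes.
#' @return List with `size` (unrolled neuron count), `fan_in` (kernel volume),
#'   and `out_shape` (`c(H_out, W_out, out_channels)`).
#' @export
unroll_conv <- function(input_shape, kernel, stride, out_channels) {
  stopifnot(length(input_shape) == 3L, length(kernel) == 2L,
            is_count(stride), is_count(out_channels))
  gh <- as.integer(ceiling(input_shape[1] / stride))
  gw <- as.integer(ceiling(input_shape[2] / stride))
  list(size = as.integer(gh * gw * out_channels),
       fan_in = as.integer(prod(kernel) * input_shape[3]),
       out_shape = c(gh, gw, as.integer(out_channels)))
}

#' Project single-substrate run counts for a topology
#'
#' Takes a topology as a sequence of layers -- dense layers given directly as
#' `(size, fan_in)`, convolutional layers given as
#' `(conv = TRUE, input_shape, kernel, stride, out_channels)` and unrolled via
#' [unroll_conv()] -- and returns the partition plan, i.e. the number of
#' sequential single-chip runs the topology needs.
#'
#' @param topology List of layer descriptions (see Details above). An empty
#'   topology plans to zero runs.
#' @param spec A [chip_spec()].
#' @return A `partition_plan`.
#' @export
project_runs <- function(topology, spec = chip_spec()) {
  if (length(topology) == 0L)
    return(structure(list(layers = list(), total_runs = 0L),
                     class = "partition_plan"))
  layers <- lapply(seq_along(topology), function(i) {
    l <- topology[[i]]
    if (isTRUE(l$conv)) {
      u <- unroll_conv(l$input_shape, l$kernel, l$stride, l$out_channels)
      list(name = l$name %||% paste0("conv", i), size = u$size,
           fan_in = u$fan_in, parts_override = l$parts_override)
    } else {
      list(name = l$name %||% paste0("layer", i), size = l$size,
           fan_in = l$fan_in, parts_override = l$parts_override)
    }
  })
  plan_network(layers, spec)
}
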