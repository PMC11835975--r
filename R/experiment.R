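#' Load an experiment configuration
#'
#' Reads a YAML (or JSON) experiment description and materializes all objects:
#' the chip spec, the encoder and training configurations, the layer table
#' used by the planner, and a fully constructed [snn_network()] with
#' seeded-random initial weights, layer populations split into their
#' partition parts, and execution instances assigned. Unknown keys at any
#' level are an error.
#'
#' Config schema (top level): `name`, `seed`, `input` (`size` or `shape`,
#' optional `receptive_field` with `kernel`/`stride`), `layers` (list of
#' `name`, `size`, `type` (`lif`/`li`), optional `parts`,
#' optional `connectivity: receptive_field`), `encoder`, `training`, `chip`.
#' Two packaged presets reproduce the full-scale study setups:
#' `snnpart_preset("mnist")` (28x28 dense, 256 LIF + 10 LI, five runs) and
#' `snnpart_preset("eurosat")` (64x64x3, receptive-field 484 + 128 LIF +
#' 10 LI, ten runs with the 8-part first layer).
#'
#' @param path Path to the config file.
#' @return List of class `snn_experiment`: `name`, `seed`, `chip`, `encoder`,
#'   `training`, `layer_table` (data frame for [plan_network()]), `plan`
#'   (the [plan_network()] result), and `network`.
#' @export
load_experiment <- function(path) {
  cfg <- read_config(path)
  check_names(cfg, c("name", "seed", "input", "layers", "encoder",
                     "training", "chip", "augment"), "experiment")
  if (is.null(cfg$layers) || !length(cfg$layers))
    stop("experiment config must define at least one layer")
  seed <- cfg$seed %||% 1L
  spec <- if (is.null(cfg$chip)) chip_spec() else chip_spec_from_list(cfg$chip)

  inp <- cfg$input %||% stop("experiment config must define input")
  check_names(inp, c("size", "shape", "receptive_field"), "input")
  rf <- NULL
  if (!is.null(inp$receptive_field)) {
    check_names(inp$receptive_field, c("kernel", "stride"), "receptive_field")
    rf <- receptive_field_grid(unlist(inp$shape),
                               unlist(inp$receptive_field$kernel),
                               inp$receptive_field$stride)
  }
  input_size <- if (!is.null(inp$size)) as.integer(inp$size)
                else as.integer(prod(unlist(inp$shape)))

  enc <- if (is.null(cfg$encoder)) encoder_config() else {
    check_names(cfg$encoder, names(formals(encoder_config)), "encoder")
    do.call(encoder_config, cfg$encoder)
  }
  trn <- if (is.null(cfg$training)) train_config() else {
    check_names(cfg$training, names(formals(train_config)), "training")
    do.call(train_config, cfg$training)
  }

  # layer table for the planner
  prev_size <- input_size
  rows <- list()
  for (l in cfg$layers) {
    check_names(l, c("name", "size", "type", "parts", "connectivity"),
                "layer")
    fan_in <- if (identical(l$connectivity, "receptive_field")) {
      if (is.null(rf)) stop("receptive_field layer needs input receptive_field")
      rf$inputs_per_neuron
    } else prev_size
    rows[[length(rows) + 1L]] <- list(name = l$name, size = l$size,
                                      fan_in = fan_in,
                                      parts_override = l$parts %||% NA)
    prev_size <- l$size
  }
  layer_table <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r$name, size = r$size, fan_in = r$fan_in,
               parts_override = r$parts_override)))
  plan <- plan_network(rows, spec)

  network <- build_network_from_config(cfg$layers, input_size, rf, plan,
                                       seed)
  structure(list(name = cfg$name %||% basename(path), seed = seed,
                 chip = spec, encoder = enc, training = trn,
                 layer_table = layer_table, plan = plan, network = network,
                 augment = cfg$augment),
            class = "snn_experiment")
}

#' @export
print.snn_experiment <- function(x, ...) {
  cat(sprintf("<snn_experiment> %s (seed %d)\n", x$name, x$seed))
  print(x$plan)
  invisible(x)
}

# Construct the snn_network: each layer split into its planned parts, each
# part its own population on its own execution instance.
build_network_from_config <- function(layers, input_size, rf, plan, seed) {
  set.seed(derive_seed(seed, "init"))
  pops <- list(population("in", input_size, is_input = TRUE))
  projs <- list()
  prev_parts <- list(list(name = "in", size = input_size, offset = 0L))
  prev_is_input <- TRUE
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    lp <- plan$layers[[li]]
    n_parts <- lp$n_runs
    li_only <- identical(l$type, "li")
    params <- lif_params(leaky_integrate_only = li_only)
    part_sizes <- rep(lp$size %/% n_parts, n_parts)
    extra <- lp$size - sum(part_sizes)
    if (extra > 0) part_sizes[seq_len(extra)] <- part_sizes[seq_len(extra)] + 1L
    parts <- list()
    off <- 0L
    rf_sparse <- identical(l$connectivity, "receptive_field")
    for (pi in seq_len(n_parts)) {
      nm <- if (n_parts == 1L) l$name else sprintf("%s_p%d", l$name, pi)
      inst <- sprintf("inst_%s", nm)
      pops[[length(pops) + 1L]] <- population(
        nm, part_sizes[pi], params, instance = inst,
        record_membrane = li_only)
      for (src in prev_parts) {
        if (rf_sparse) {
          # connect only the receptive-field inputs of this part's neurons
          pr <- do.call(rbind, lapply(seq_len(part_sizes[pi]), function(j) {
            ids <- rf$indices[[off + j]]
            data.frame(i = ids, j = j,
                       w = stats::rnorm(length(ids),
                                        0, 1 / sqrt(rf$inputs_per_neuron)))
          }))
          projs[[length(projs) + 1L]] <- projection(src$name, nm, pr,
                                                    connectivity = "explicit")
        } else {
          W <- matrix(stats::rnorm(src$size * part_sizes[pi], 0,
                                   1 / sqrt(lp$fan_in_signed)),
                      src$size, part_sizes[pi])
          projs[[length(projs) + 1L]] <- projection(src$name, nm, W)
        }
      }
      parts[[pi]] <- list(name = nm, size = part_sizes[pi], offset = off)
      off <- off + part_sizes[pi]
    }
    prev_parts <- parts
    prev_is_input <- FALSE
  }
  snn_network(pops, projs)
}

#' Path to a packaged experiment preset
#'
#' @param name `"mnist"` or `"eurosat"`.
#' @return Path to the installed preset YAML, loadable with
#'   [load_experiment()].
#' @export
snnpart_preset <- function(name = c("mnist", "eurosat")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".yaml"), package = "snnpart",
              mustWork = TRUE)
}

#' Run manifest
#'
#' Summarizes one executed experiment for reproducibility: a hash of the
#' configuration, the seed, the schedule, per-instance output file paths and
#' dropped-event counts, and component versions. Manifests round-trip
#' losslessly through JSON.
#'
#' @param run An `snn_run` from [run_network()].
#' @param seed Experiment seed.
#' @param config Arbitrary configuration list hashed into `config_hash`.
#' @param files Named character vector of output file paths.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(run, seed, config = list(), files = character()) {
  stopifnot(inherits(run, "snn_run"))
  structure(list(
    config_hash = config_hash(config),
    seed = as.integer(seed),
    schedule = run$schedule,
    mode = run$mode, T = run$T, dt = run$dt,
    files = as.list(files),
    n_dropped = as.list(run$n_dropped),
    versions = list(snnpart = as.character(utils::packageVersion("snnpart")),
                    R = paste(R.version$major, R.version$minor, sep = "."))),
    class = "run_manifest")
}

# order-stable FNV-1a hash over the canonical JSON serialization
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$schedule <- lapply(m$schedule, as.character)
  m$files <- as.list(m$files)
  m$n_dropped <- as.list(m$n_dropped)
  structure(m, class = "run_manifest")
}
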