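#' Spike event batches
#'
#' An `event_batch` is a data frame of timestamped spike events for a batch of
#' samples, with columns `sample_id` (1-based sample index), `time_us`
#' (microseconds), `population` (character) and `neuron_id` (1-based neuron
#' index within the population). Events are kept sorted by
#' (sample, time, population, neuron) so merged streams from several source
#' executions have a stable, documented order.
#'
#' @param sample_id,time_us,population,neuron_id Event columns (recycled to a
#'   common length).
#' @param n_samples Number of samples in the batch (defaults to
#'   `max(sample_id)`, 0 for an empty batch).
#' @return An object of classes `event_batch` and `data.frame`.
#' @export
event_batch <- function(sample_id = integer(), time_us = numeric(),
                        population = character(), neuron_id = integer(),
                        n_samples = NULL) {
  df <- data.frame(sample_id = as.integer(sample_id),
                   time_us = as.numeric(time_us),
                   population = as.character(population),
                   neuron_id = as.integer(neuron_id),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(!is.finite(df$time_us)) || any(df$time_us < 0))
      stop("event times must be finite and >= 0")
    if (any(df$sample_id < 1L) || any(df$neuron_id < 1L))
      stop("sample_id and neuron_id are 1-based")
    df <- df[order(df$sample_id, df$time_us, df$population, df$neuron_id), ,
             drop = FALSE]
    rownames(df) <- NULL
  }
  if (is.null(n_samples)) n_samples <- if (nrow(df)) max(df$sample_id) else 0L
  attr(df, "n_samples") <- as.integer(n_samples)
  class(df) <- c("event_batch", "data.frame")
  df
}

n_samples <- function(ev) attr(ev, "n_samples") %||% 0L

#' @export
print.event_batch <- function(x, ...) {
  cat(sprintf("<event_batch> %d events, %d sample(s), population(s): %s\n",
              nrow(x), n_samples(x),
              if (nrow(x)) paste(unique(x$population), collapse = ", ")
              else "-"))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# Combine batches over the same sample set (stable re-sort on construction).
rbind_events <- function(..., n_samples = NULL) {
  parts <- Filter(Negate(is.null), list(...))
  df <- do.call(rbind, lapply(parts, as.data.frame))
  ns <- n_samples %||%
    max(c(0L, vapply(parts, function(e) attr(e, "n_samples") %||% 0L,
                     integer(1))))
  event_batch(df$sample_id, df$time_us, df$population, df$neuron_id,
              n_samples = ns)
}

#' Write / read spike events as CSV
#'
#' The on-disk schema is a plain CSV with header
#' `sample_id,time_us,population,neuron_id`; times are microseconds in a
#' half-open window `[0, T)`. `read_events()` normalizes ordering, so
#' write-then-read is the identity up to row order.
#'
#' @param events An [event_batch()].
#' @param path File path.
#' @return `read_events()` returns an [event_batch()]; `write_events()`
#'   returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_batch"))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param n_samples Batch size; defaults to the largest sample id in the file.
#' @export
read_events <- function(path, n_samples = NULL) {
  if (!file.exists(path)) stop("event file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_us", "population", "neuron_id")
  if (!all(need %in% names(df)))
    stop("event CSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$time_us) | df$time_us < 0 |
                 df$sample_id < 1 | df$neuron_id < 1)
  if (length(bad))
    stop(sprintf("malformed event row (data line %d): %s", bad[1],
                 paste(unlist(df[bad[1], need]), collapse = ",")))
  event_batch(df$sample_id, df$time_us, df$population, df$neuron_id,
              n_samples = n_samples)
}

# Events of one population -> per-bin spike-count array (n_samples x bins x n).
# An event at time t lands in bin floor(t / dt) + 1; events at or beyond
# bins * dt fall outside the window and are dropped (a spike emitted in the
# last bin carries timestamp T and can no longer influence this window).
bin_events <- function(events, population, size, bins, dt, n_samples) {
  arr <- array(0, dim = c(n_samples, bins, size))
  ev <- events[events$population == population, , drop = FALSE]
  if (!nrow(ev)) return(arr)
  if (any(ev$neuron_id > size))
    stop(sprintf("event neuron_id exceeds population '%s' size %d",
                 population, size))
  k <- floor(ev$time_us / dt + 1e-9) + 1
  keep <- k <= bins
  if (any(keep)) {
    ii <- cbind(ev$sample_id[keep], k[keep], ev$neuron_id[keep])
    # accumulate duplicates (several events in one bin) one by one
    for (r in seq_len(nrow(ii))) {
      arr[ii[r, 1], ii[r, 2], ii[r, 3]] <- arr[ii[r, 1], ii[r, 2], ii[r, 3]] + 1
    }
  }
  arr
}

#' Write / read membrane traces as CSV
#'
#' Traces are stored long: `sample_id,time_us,population,neuron_id,v`. This is
#' a plain-text, diff-able format; [read_traces()] reshapes back to the
#' `(samples x bins x neurons)` array.
#'
#' @param traces A 3-d array `(samples, bins, neurons)` with attribute `dt`.
#' @param path File path.
#' @param population Population name stored with the rows.
#' @param dt Grid step in microseconds (defaults to `attr(traces, "dt")`).
#' @export
write_traces <- function(traces, path, population = "readout",
                         dt = attr(traces, "dt")) {
  stopifnot(length(dim(traces)) == 3L, !is.null(dt))
  d <- dim(traces)
  df <- data.frame(
    sample_id = rep(seq_len(d[1]), times = d[2] * d[3]),
    time_us = rep(rep(seq_len(d[2]) * dt, each = d[1]), times = d[3]),
    population = population,
    neuron_id = rep(seq_len(d[3]), each = d[1] * d[2]),
    v = as.vector(traces))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ns <- max(df$sample_id); nn <- max(df$neuron_id)
  ts <- sort(unique(df$time_us)); nb <- length(ts)
  arr <- array(NA_real_, dim = c(ns, nb, nn))
  kk <- match(df$time_us, ts)
  arr[cbind(df$sample_id, kk, df$neuron_id)] <- df$v
  attr(arr, "dt") <- if (nb > 1) ts[2] - ts[1] else ts[1]
  arr
}
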