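#' Leaky integrate-and-fire parameter set
#'
#' Parameters of the current-based (CUBA) LIF dynamics
#' `tau_m dv/dt = -(v - E_l) + I / g_l`, where each presynaptic spike at time
#' `t_i` adds `w_i` to the synaptic current `I`, which decays with `tau_s`.
#' When `v` crosses the threshold `v_th` the neuron emits a spike, `v` is reset
#' to `v_reset` and held there for `tau_ref`. Readout neurons are leaky
#' integrators (`leaky_integrate_only = TRUE`): same membrane dynamics, never
#' thresholded.
#'
#' Times are microseconds; potentials and conductance are dimensionless but
#' mutually consistent units.
#'
#' @param tau_m Membrane time constant (us).
#' @param g_l Leak conductance.
#' @param E_l Leak potential.
#' @param v_th Spike threshold.
#' @param v_reset Reset potential.
#' @param tau_s Synaptic time constant (us).
#' @param tau_ref Refractory time (us); default 0.
#' @param leaky_integrate_only If `TRUE` the neuron never spikes.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(tau_m = 10, g_l = 1, E_l = 0, v_th = 1, v_reset = 0,
                       tau_s = 5, tau_ref = 0,
                       leaky_integrate_only = FALSE) {
  if (tau_m <= 0 || tau_s <= 0) stop("tau_m and tau_s must be > 0")
  if (tau_ref < 0) stop("tau_ref must be >= 0")
  if (!leaky_integrate_only && v_th <= v_reset)
    stop("spiking neurons need v_th > v_reset")
  structure(list(tau_m = tau_m, g_l = g_l, E_l = E_l, v_th = v_th,
                 v_reset = v_reset, tau_s = tau_s, tau_ref = tau_ref,
                 leaky_integrate_only = isTRUE(leaky_integrate_only)),
            class = "lif_params")
}

#' Quantize signed weights to hardware resolution
#'
#' A signed weight is represented by a pair of limited-resolution hardware
#' synapses, giving integer weights in `[-(weight_levels - 1),
#' weight_levels - 1]` (default 6 bit: -63..63). Quantization is
#' `round(w * scale)` (round half to even) clipped to that range; the value
#' used in the dynamics is the clipped integer divided by `scale`.
#'
#' @param w Numeric matrix (or vector) of signed weights.
#' @param scale Positive scale factor mapping model weights to integer levels.
#' @param weight_levels Levels per hardware synapse (default 64).
#' @return Integer-valued matrix of quantized levels, with attributes `scale`
#'   and `weight_levels`. Use [dequantize_weights()] to map back.
#' @export
quantize_weights <- function(w, scale, weight_levels = 64L) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a single positive number")
  if (any(!is.finite(w))) stop("weights must be finite")
  lim <- weight_levels - 1L
  q <- pmin(pmax(round(w * scale), -lim), lim)
  attr(q, "scale") <- scale
  attr(q, "weight_levels") <- as.integer(weight_levels)
  q
}

#' @rdname quantize_weights
#' @param q Quantized weights from [quantize_weights()].
#' @export
dequantize_weights <- function(q) {
  sc <- attr(q, "scale")
  if (is.null(sc)) stop("q does not carry a quantization scale")
  out <- q / sc
  attributes(out) <- attributes(q)["dim"]
  out
}

# Default quantization scale: put the largest |w| on the top level.
auto_scale <- function(w, weight_levels = 64L) {
  m <- max(abs(w))
  if (m == 0) 1 else (weight_levels - 1L) / m
}

#' Event-link bandwidth limiting
#'
#' The event link processes at most `max_events_per_cycle` spikes per clock
#' cycle; simultaneous excess events are delayed into following cycles through
#' a bounded FIFO, and events that do not fit the queue are dropped. Samples
#' in a batch are independent (each sample is its own hardware run).
#'
#' @param events An [event_batch()]; all populations in it share the link.
#' @param spec A [chip_spec()] (provides `max_events_per_cycle`).
#' @param cycle Link clock cycle duration in microseconds (default 0.008 us,
#'   i.e. two events per 8 ns cycle = 250 MHz sustained).
#' @param queue_depth Bounded FIFO depth for delayed events.
#' @return List with `events` (kept events; delayed ones re-stamped to the
#'   start of the cycle in which they are sent), `n_dropped`, and `n_delayed`.
#'   Kept + dropped always equals the input count.
#' @export
apply_bandwidth_limit <- function(events, spec = chip_spec(), cycle = 0.008,
                                  queue_depth = 4L) {
  stopifnot(inherits(events, "event_batch"), inherits(spec, "chip_spec"))
  if (cycle <= 0) stop("cycle must be > 0")
  queue_depth <- as.integer(queue_depth)
  cap <- spec$max_events_per_cycle
  if (!nrow(events))
    return(list(events = events, n_dropped = 0L, n_delayed = 0L))

  keep_rows <- integer(0)
  keep_time <- numeric(0)
  n_dropped <- 0L
  n_delayed <- 0L
  df <- as.data.frame(events)
  df$.row <- seq_len(nrow(df))
  for (s in unique(df$sample_id)) {
    ds <- df[df$sample_id == s, , drop = FALSE]
    cyc <- floor(ds$time_us / cycle)
    ord <- order(cyc, ds$time_us, ds$population, ds$neuron_id)
    ds <- ds[ord, , drop = FALSE]
    cyc <- cyc[ord]
    queue <- integer(0)          # row indices into ds, FIFO
    i <- 1L
    n <- nrow(ds)
    c_now <- cyc[1]
    while (i <= n || length(queue)) {
      if (i > n && length(queue)) c_now <- max(c_now, 0)
      arrivals <- integer(0)
      while (i <= n && cyc[i] == c_now) {
        arrivals <- c(arrivals, i)
        i <- i + 1L
      }
      slots <- cap
      # queued events (earlier arrivals) are sent first, re-stamped
      if (length(queue)) {
        nsend <- min(slots, length(queue))
        if (nsend) {
          sent <- queue[seq_len(nsend)]
          queue <- queue[-seq_len(nsend)]
          keep_rows <- c(keep_rows, ds$.row[sent])
          keep_time <- c(keep_time, rep(c_now * cycle, nsend))
          n_delayed <- n_delayed + nsend
          slots <- slots - nsend
        }
      }
      if (length(arrivals)) {
        nsend <- min(slots, length(arrivals))
        if (nsend) {
          sent <- arrivals[seq_len(nsend)]
          keep_rows <- c(keep_rows, ds$.row[sent])
          keep_time <- c(keep_time, ds$time_us[sent])  # on time
          arrivals <- arrivals[-seq_len(nsend)]
        }
        if (length(arrivals)) {
          room <- queue_depth - length(queue)
          nq <- min(room, length(arrivals))
          if (nq > 0) queue <- c(queue, arrivals[seq_len(nq)])
          n_dropped <- n_dropped + length(arrivals) - max(nq, 0L)
        }
      }
      # advance to next cycle with work
      if (length(queue)) {
        c_now <- c_now + 1
      } else if (i <= n) {
        c_now <- cyc[i]
      } else break
    }
  }
  kept <- df[keep_rows, , drop = FALSE]
  kept$time_us <- keep_time
  out <- event_batch(kept$sample_id, kept$time_us, kept$population,
                     kept$neuron_id, n_samples = n_samples(events))
  list(events = out, n_dropped = as.integer(n_dropped),
       n_delayed = as.integer(n_delayed))
}

#' Least-squares factor scaling hardware traces onto reference dynamics
#'
#' For hardware-in-the-loop gradient estimation, recorded membrane traces are
#' rescaled onto the idealized software dynamics by the scalar `a` minimizing
#' `||a * hw - ref||^2` over unclipped bins.
#'
#' @param hw Numeric array of hardware-like traces.
#' @param ref Numeric array of reference traces, same shape.
#' @param clipped Optional logical array marking clipped bins to exclude.
#' @return The scalar factor `a`.
#' @export
itl_scale_factor <- function(hw, ref, clipped = NULL) {
  if (!identical(dim(hw) %||% length(hw), dim(ref) %||% length(ref)))
    stop("hw and ref must have matching shapes")
  use <- rep(TRUE, length(hw))
  if (!is.null(clipped)) use <- !as.vector(clipped)
  h <- as.vector(hw)[use]
  r <- as.vector(ref)[use]
  denom <- sum(h * h)
  if (!length(h) || denom == 0)
    stop("scale undefined: no unclipped bins with signal")
  sum(h * r) / denom
}

# --- lattice executor -------------------------------------------------------

# Extract bin k of (B x bins x n) as a (B x n) matrix without dropping dims.
slice_bin <- function(arr, k) {
  d <- dim(arr)
  matrix(arr[, k, ], nrow = d[1], ncol = d[3])
}

grid_bins <- function(T, dt) as.integer(ceiling(T / dt - 1e-9))

# Core multi-population lattice integrator for one execution instance.
#
# pops: named list; each entry list(size, params, is_input, record_spikes,
#   record_membrane). Input ("driver") populations are pure spike sources fed
#   by ext_events; integrated populations evolve LIF/LI state.
# projs: ordered list of list(source, target, W) with W (n_src x n_tgt).
#   Projection order is part of the arithmetic contract: drive is accumulated
#   in list order so partitioned and monolithic runs sum identically.
# Timing: an external event at time t lands in bin floor(t/dt)+1; a spike
# emitted in bin k is stamped k*dt and reaches its intra-instance targets in
# bin k+1 -- identical to replaying the stamped event into another run.
integrate_populations <- function(pops, projs, ext_events, n_samples, T, dt,
                                  mode = c("ideal", "constrained"),
                                  spec = chip_spec(), cycle = 0.008,
                                  queue_depth = 4L) {
  mode <- match.arg(mode)
  bins <- grid_bins(T, dt)
  B <- as.integer(n_samples)
  stopifnot(B >= 1)

  n_dropped <- 0L
  if (mode == "constrained") {
    bw <- apply_bandwidth_limit(ext_events, spec, cycle, queue_depth)
    ext_events <- bw$events
    n_dropped <- bw$n_dropped
    projs <- lapply(projs, function(pr) {
      sc <- attr(pr$W, "w_scale") %||% auto_scale(pr$W, spec$weight_levels)
      q <- quantize_weights(pr$W, sc, spec$weight_levels)
      pr$W <- matrix(dequantize_weights(q), nrow(pr$W), ncol(pr$W))
      pr
    })
  }

  driver <- names(pops)[vapply(pops, function(p) isTRUE(p$is_input),
                               logical(1))]
  integ <- setdiff(names(pops), driver)
  for (pr in projs) {
    if (!is.null(pr$W) && any(!is.finite(pr$W)))
      stop("projection weights must be finite")
  }

  drive_counts <- lapply(driver, function(nm)
    bin_events(ext_events, nm, pops[[nm]]$size, bins, dt, B))
  names(drive_counts) <- driver

  st <- lapply(integ, function(nm) {
    p <- pops[[nm]]$params
    list(v = matrix(p$E_l, B, pops[[nm]]$size),
         I = matrix(0, B, pops[[nm]]$size),
         refrac = matrix(0L, B, pops[[nm]]$size))
  })
  names(st) <- integ
  prev_z <- lapply(integ, function(nm) matrix(0, B, pops[[nm]]$size))
  names(prev_z) <- integ

  traces <- lapply(integ, function(nm) {
    if (isTRUE(pops[[nm]]$record_membrane))
      array(NA_real_, dim = c(B, bins, pops[[nm]]$size)) else NULL
  })
  names(traces) <- integ
  sp_s <- sp_n <- sp_k <- lapply(integ, function(nm) list())
  names(sp_s) <- names(sp_n) <- names(sp_k) <- integ

  lo <- spec$readout_range[1]; hi <- spec$readout_range[2]

  for (k in seq_len(bins)) {
    inj <- lapply(integ, function(nm) matrix(0, B, pops[[nm]]$size))
    names(inj) <- integ
    for (pr in projs) {
      src <- if (pr$source %in% driver) slice_bin(drive_counts[[pr$source]], k)
             else prev_z[[pr$source]]
      inj[[pr$target]] <- inj[[pr$target]] + src %*% pr$W
    }
    new_z <- prev_z
    for (nm in integ) {
      p <- pops[[nm]]$params
      lm <- exp(-dt / p$tau_m); ls <- exp(-dt / p$tau_s)
      s <- st[[nm]]
      s$I <- s$I * ls + inj[[nm]]
      active <- s$refrac == 0L
      vnew <- p$E_l + (s$v - p$E_l) * lm + (s$I / p$g_l) * (1 - lm)
      vnew[!active] <- p$v_reset
      if (!is.null(traces[[nm]])) {
        rec <- vnew
        if (mode == "constrained") rec <- pmin(pmax(rec, lo), hi)
        traces[[nm]][, k, ] <- rec
      }
      if (p$leaky_integrate_only) {
        z <- matrix(0, nrow(vnew), ncol(vnew))
      } else {
        z <- (vnew >= p$v_th) & active
        if (any(z)) {
          vnew[z] <- p$v_reset
          s$refrac[z] <- as.integer(ceiling(p$tau_ref / dt))
          idx <- which(z, arr.ind = TRUE)
          sp_s[[nm]][[length(sp_s[[nm]]) + 1L]] <- idx[, 1]
          sp_n[[nm]][[length(sp_n[[nm]]) + 1L]] <- idx[, 2]
          sp_k[[nm]][[length(sp_k[[nm]]) + 1L]] <- rep.int(k, nrow(idx))
        }
        z <- z * 1
      }
      s$refrac[!active] <- s$refrac[!active] - 1L
      s$v <- vnew
      st[[nm]] <- s
      new_z[[nm]] <- z
    }
    prev_z <- new_z
  }

  out_events <- lapply(integ, function(nm) {
    if (!length(sp_s[[nm]]))
      return(event_batch(n_samples = B))
    event_batch(sample_id = unlist(sp_s[[nm]]),
                time_us = unlist(sp_k[[nm]]) * dt,
                population = nm,
                neuron_id = unlist(sp_n[[nm]]),
                n_samples = B)
  })
  names(out_events) <- integ
  for (nm in integ) {
    if (!is.null(traces[[nm]])) attr(traces[[nm]], "dt") <- dt
  }
  list(events = out_events, traces = traces, n_dropped = n_dropped,
       bins = bins, dt = dt)
}

#' Integrate one projection + neuron layer on the time lattice
#'
#' Exponential-Euler integration of CUBA LIF (or LI) dynamics driven by input
#' spike events through a weight matrix: per bin, the synaptic current decays
#' by `exp(-dt/tau_s)` and accumulates the weights of the bin's input events;
#' the membrane decays toward `E_l` with `tau_m` and integrates `I/g_l`;
#' neurons at or above threshold after the update fire (all simultaneous
#' crossings fire), are reset and held for the refractory time. In
#' `constrained` mode, weights are first quantized to hardware resolution,
#' input events pass the event-link bandwidth limit, and recorded traces are
#' clipped to the readout range.
#'
#' @param events Input [event_batch()] (population name "in").
#' @param weights Weight matrix, `(fan_in, n_neurons)`.
#' @param params A [lif_params()].
#' @param T Window length (us).
#' @param dt Lattice step (us), default 0.5.
#' @param mode `"ideal"` or `"constrained"`.
#' @param spec A [chip_spec()] (constrained mode).
#' @param w_scale Optional fixed quantization scale (constrained mode);
#'   default scales the largest weight to the top level.
#' @param cycle,queue_depth Bandwidth-limit parameters, see
#'   [apply_bandwidth_limit()].
#' @return List with `events` (output spikes, population "out"), `traces`
#'   (`(samples, bins, n_neurons)` membrane array with attribute `dt`), and
#'   `n_dropped` input events lost to the bandwidth limit.
#' @examples
#' ev <- event_batch(1, 0, "in", 1)
#' r <- integrate_instance(ev, matrix(0.1), lif_params(), T = 30)
#' max(r$traces)  # subthreshold PSP peak
#' @export
integrate_instance <- function(events, weights, params, T, dt = 0.5,
                               mode = c("ideal", "constrained"),
                               spec = chip_spec(), w_scale = NULL,
                               cycle = 0.008, queue_depth = 4L) {
  mode <- match.arg(mode)
  if (!is.matrix(weights)) weights <- as.matrix(weights)
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (!is.null(w_scale)) attr(weights, "w_scale") <- w_scale
  B <- max(1L, n_samples(events))
  pops <- list(
    `in` = list(size = nrow(weights), is_input = TRUE),
    out = list(size = ncol(weights), params = params, is_input = FALSE,
               record_spikes = TRUE, record_membrane = TRUE))
  res <- integrate_populations(pops,
                               list(list(source = "in", target = "out",
                                         W = weights)),
                               events, B, T, dt, mode, spec, cycle,
                               queue_depth)
  list(events = res$events$out, traces = res$traces$out,
       n_dropped = res$n_dropped)
}
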