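#' Surrogate spike nonlinearity
#'
#' The spike threshold is a step function with no useful derivative; during
#' the backward pass it is replaced by the fast-sigmoid surrogate: the
#' forward value is `step(x)`, the backward derivative is
#' `1 / (beta * |x| + 1)^2` -- the derivative of the smooth relaxation
#' `x / (1 + beta * |x|)`. `beta` controls the sharpness (larger = closer to
#' the step, smaller = more gradient far from threshold).
#'
#' @param x Membrane distance to threshold, `v - v_th`.
#' @param beta Surrogate steepness (> 0).
#' @return `surrogate_spike()`: the step forward value (0/1);
#'   `surrogate_grad()`: the surrogate derivative;
#'   `surrogate_smooth()`: the smooth relaxation whose exact derivative is
#'   `surrogate_grad()` (used for gradient checking).
#' @export
surrogate_spike <- function(x, beta = 10) {
  if (beta <= 0) stop("beta must be > 0")
  (x >= 0) * 1
}

#' @rdname surrogate_spike
#' @export
surrogate_grad <- function(x, beta = 10) {
  if (beta <= 0) stop("beta must be > 0")
  1 / (beta * abs(x) + 1)^2
}

#' @rdname surrogate_spike
#' @export
surrogate_smooth <- function(x, beta = 10) {
  if (beta <= 0) stop("beta must be > 0")
  x / (1 + beta * abs(x))
}

#' Decode class scores from readout membrane traces
#'
#' `decode_max_over_time()` scores each class by the maximum of its readout
#' membrane trace over the window; `decode_last()` by the final membrane
#' value.
#'
#' @param traces `(samples, bins, classes)` membrane array.
#' @return `(samples, classes)` score matrix.
#' @export
decode_max_over_time <- function(traces) {
  stopifnot(length(dim(traces)) == 3L, dim(traces)[2] >= 1L)
  apply(traces, c(1, 3), max)
}

#' @rdname decode_max_over_time
#' @export
decode_last <- function(traces) {
  stopifnot(length(dim(traces)) == 3L, dim(traces)[2] >= 1L)
  d <- dim(traces)
  matrix(traces[, d[2], ], d[1], d[3])
}

# cross-entropy of softmaxed scores; returns loss and gradient
cross_entropy <- function(scores, labels) {
  B <- nrow(scores)
  if (any(labels < 1L | labels > ncol(scores)))
    stop("label out of range")
  m <- apply(scores, 1, max)
  ex <- exp(scores - m)
  p <- ex / rowSums(ex)
  ll <- -mean(log(pmax(p[cbind(seq_len(B), labels)], 1e-300)))
  g <- p
  g[cbind(seq_len(B), labels)] <- g[cbind(seq_len(B), labels)] - 1
  list(value = ll, grad = g / B)
}

relu <- function(x) pmax(x, 0)

#' Training loss: cross-entropy plus substrate regularizers
#'
#' Cross-entropy of softmaxed class scores, plus three penalties that keep
#' the model within substrate capabilities: hidden firing rate (event-link
#' load), readout membrane magnitude (ADC saturation) and weight magnitude
#' (limited hardware weight range). Functional forms:
#' `rate * mean_j(c_j^2)` with `c_j` the batch-mean spike count of hidden
#' neuron `j`; `sat * mean(relu(|v| - sat_bound)^2)` over readout traces;
#' `weight * mean(relu(|w| - weight_bound)^2)` over each weight matrix.
#'
#' @param scores `(samples, classes)` score matrix.
#' @param labels Integer class labels (1-based).
#' @param hidden_spikes Optional list of `(samples, bins, n)` hidden spike
#'   arrays.
#' @param readout_traces Optional `(samples, bins, classes)` trace array.
#' @param weights Optional list of weight matrices.
#' @param reg Named numeric: `rate`, `sat`, `weight` penalty coefficients.
#' @param sat_bound,weight_bound Penalty-free magnitude bounds.
#' @return The scalar loss.
#' @export
snn_loss <- function(scores, labels, hidden_spikes = NULL,
                     readout_traces = NULL, weights = NULL,
                     reg = c(rate = 0, sat = 0, weight = 0),
                     sat_bound = 1, weight_bound = 1) {
  loss <- cross_entropy(scores, labels)$value
  defaults <- c(rate = 0, sat = 0, weight = 0)
  if (is.null(names(reg))) names(reg) <- names(defaults)[seq_along(reg)]
  defaults[intersect(names(reg), names(defaults))] <-
    reg[intersect(names(reg), names(defaults))]
  reg <- defaults
  if (reg["rate"] > 0 && !is.null(hidden_spikes)) {
    for (z in hidden_spikes) {
      cj <- apply(z, 3, sum) / dim(z)[1]
      loss <- loss + reg["rate"] * mean(cj^2)
    }
  }
  if (reg["sat"] > 0 && !is.null(readout_traces)) {
    loss <- loss + reg["sat"] * mean(relu(abs(readout_traces) - sat_bound)^2)
  }
  if (reg["weight"] > 0 && !is.null(weights)) {
    for (W in weights) {
      loss <- loss + reg["weight"] * mean(relu(abs(W) - weight_bound)^2)
    }
  }
  unname(loss)
}

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param betas Adam first/second moment decays.
#' @param eps Adam epsilon.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param dropout_p Hidden spike dropout probability (spikes withheld from the
#'   downstream layer during training); `0 <= p < 1`.
#' @param lr_schedule `"none"`, `"exponential"` (multiply by `lr_decay` each
#'   epoch) or `"halving"` (halve after each epoch in `halve_at`).
#' @param lr_decay Exponential decay factor per epoch.
#' @param halve_at Epochs after which the rate is halved.
#' @param reg_rate,reg_sat,reg_weight Regularizer coefficients, see
#'   [snn_loss()].
#' @param sat_bound,weight_bound Regularizer bounds.
#' @param patience Early stopping: stop after this many epochs without
#'   validation-accuracy improvement (`Inf` = never).
#' @param decoding `"max_over_time"` or `"last_value"`.
#' @param beta Surrogate steepness, see [surrogate_spike()].
#' @param seeds Integer vector of training seeds; the fit is repeated per
#'   seed and metrics averaged.
#' @param w_init_sd Weight init scale: `N(0, (w_init_sd / sqrt(fan_in))^2)`.
#'   The default is fluctuation-driven: large enough that hidden LIF units
#'   are active at initialization under sparse TTFS input (a silent hidden
#'   layer yields no readout signal and hence no usable gradient).
#' @param val_fraction Fraction of training data held out for validation when
#'   no validation set is supplied.
#' @param itl_rescale If `TRUE` (constrained backends), rescale recorded
#'   readout traces onto an idealized forward via [itl_scale_factor()] before
#'   decoding.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, betas = c(0.9, 0.999), eps = 1e-8,
                         epochs = 50, batch_size = 32, dropout_p = 0,
                         lr_schedule = c("none", "exponential", "halving"),
                         lr_decay = 0.97,
                         halve_at = c(10, 20, 30, 40, 50, 60),
                         reg_rate = 0, reg_sat = 0, reg_weight = 0,
                         sat_bound = 1, weight_bound = 1, patience = Inf,
                         decoding = c("max_over_time", "last_value"),
                         beta = 10, seeds = 1L, w_init_sd = 8,
                         val_fraction = 0.2, itl_rescale = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  decoding <- match.arg(decoding)
  if (dropout_p < 0 || dropout_p >= 1) stop("need 0 <= dropout_p < 1")
  if (patience < 1) stop("patience must be >= 1")
  if (beta <= 0) stop("beta must be > 0")
  structure(list(lr = as.numeric(lr), betas = as.numeric(betas),
                 eps = as.numeric(eps), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 dropout_p = as.numeric(dropout_p),
                 lr_schedule = lr_schedule, lr_decay = as.numeric(lr_decay),
                 halve_at = as.numeric(halve_at),
                 reg_rate = as.numeric(reg_rate),
                 reg_sat = as.numeric(reg_sat),
                 reg_weight = as.numeric(reg_weight),
                 sat_bound = as.numeric(sat_bound),
                 weight_bound = as.numeric(weight_bound),
                 patience = as.numeric(patience),
                 decoding = decoding, beta = as.numeric(beta),
                 seeds = as.integer(seeds),
                 w_init_sd = as.numeric(w_init_sd),
                 val_fraction = as.numeric(val_fraction),
                 itl_rescale = isTRUE(itl_rescale)),
            class = "train_config")
}

# --- differentiable lattice chain ------------------------------------------
#
# Forward/backward over the unrolled time lattice for a feed-forward chain of
# LIF hidden layers and one LI readout. Update per bin k (layer l):
#   I_k  = ls * I_{k-1} + X_k W
#   v_k  = E_l + lm * (v'_{k-1} - E_l) + (1 - lm) * I_k / g_l
#   z_k  = step(v_k - v_th)            (smooth: surrogate_smooth)
#   v'_k = v_k (1 - z_k) + v_reset z_k (LI: v'_k = v_k, z == 0)
# with X_k the input spike counts for l = 1 and the previous layer's
# (dropout-masked) spikes of bin k-1 for l > 1 (one-bin transmission delay,
# identical to the event executor's timing). The hand-derived adjoint runs
# the same recurrences in reverse; in smooth mode it is the exact gradient of
# the relaxed model, in spiking mode the surrogate gradient.

chain_forward <- function(W, X, ph, po, dt, beta, smooth = FALSE,
                          masks = NULL, clip = NULL) {
  L <- length(W)
  B <- dim(X)[1]; bins <- dim(X)[2]
  layers <- vector("list", L)
  Xl <- X
  for (l in seq_len(L)) {
    p <- if (l == L) po else ph
    lm <- exp(-dt / p$tau_m); ls <- exp(-dt / p$tau_s)
    n <- ncol(W[[l]])
    v <- array(0, dim = c(B, bins, n))
    z <- array(0, dim = c(B, bins, n))
    I <- matrix(0, B, n)
    vp <- matrix(p$E_l, B, n)
    li <- p$leaky_integrate_only
    for (k in seq_len(bins)) {
      xk <- slice_bin(Xl, k)
      I <- I * ls + xk %*% W[[l]]
      vk <- p$E_l + (vp - p$E_l) * lm + (I / p$g_l) * (1 - lm)
      v[, k, ] <- vk
      if (li) {
        vp <- vk
      } else {
        zk <- if (smooth) surrogate_smooth(vk - p$v_th, beta)
              else (vk >= p$v_th) * 1
        z[, k, ] <- zk
        vp <- vk * (1 - zk) + p$v_reset * zk
      }
    }
    layers[[l]] <- list(v = v, z = z, X = Xl)
    if (l < L) {
      # shift one bin forward; mask withheld (dropout) spikes
      m <- if (!is.null(masks) && !is.null(masks[[l]])) masks[[l]] else NULL
      nxt <- array(0, dim = c(B, bins, n))
      if (bins > 1) {
        zs <- z[, seq_len(bins - 1L), , drop = FALSE]
        if (!is.null(m)) {
          zs <- sweep(zs, c(1, 3), m, `*`)
        }
        nxt[, 2:bins, ] <- zs
      }
      Xl <- nxt
    }
  }
  out_v <- layers[[L]]$v
  clipped <- NULL
  if (!is.null(clip)) {
    clipped <- out_v < clip[1] | out_v > clip[2]
    out_v <- pmin(pmax(out_v, clip[1]), clip[2])
  }
  list(layers = layers, readout = out_v, clipped = clipped)
}

chain_backward <- function(fw, W, ph, po, dt, beta, smooth = FALSE,
                           masks = NULL, GV_out, GZ_extra = NULL) {
  L <- length(W)
  d <- dim(fw$layers[[1]]$X)
  B <- d[1]; bins <- d[2]
  gW <- lapply(W, function(w) matrix(0, nrow(w), ncol(w)))
  GZ_next <- NULL  # gradient w.r.t. this layer's z from the layer above
  for (l in rev(seq_len(L))) {
    p <- if (l == L) po else ph
    lm <- exp(-dt / p$tau_m); ls <- exp(-dt / p$tau_s)
    li <- p$leaky_integrate_only
    lay <- fw$layers[[l]]
    n <- ncol(W[[l]]); n_in <- nrow(W[[l]])
    GV <- if (l == L) GV_out else NULL
    GZ <- GZ_next
    if (!is.null(GZ_extra) && l < L && !is.null(GZ_extra[[l]]))
      GZ <- if (is.null(GZ)) GZ_extra[[l]] else GZ + GZ_extra[[l]]
    carry_gvp <- matrix(0, B, n)
    carry_gI <- matrix(0, B, n)
    GX <- array(0, dim = c(B, bins, n_in))
    Wt <- t(W[[l]])
    for (k in rev(seq_len(bins))) {
      vk <- slice_bin(lay$v, k)
      gvk_direct <- if (!is.null(GV)) slice_bin(GV, k)
                    else matrix(0, B, n)
      if (li) {
        gv <- gvk_direct + carry_gvp
      } else {
        zk <- slice_bin(lay$z, k)
        gzk <- if (!is.null(GZ)) slice_bin(GZ, k) else matrix(0, B, n)
        hp <- surrogate_grad(vk - p$v_th, beta)
        gv <- gvk_direct + carry_gvp * (1 - zk) +
          (gzk + carry_gvp * (p$v_reset - vk)) * hp
      }
      gI <- carry_gI + gv * (1 - lm) / p$g_l
      xk <- slice_bin(lay$X, k)
      gW[[l]] <- gW[[l]] + crossprod(xk, gI)
      GX[, k, ] <- gI %*% Wt
      carry_gvp <- gv * lm
      carry_gI <- gI * ls
    }
    if (l > 1) {
      # X_k = z_{k-1} * mask  ->  route GX_k back one bin, through the mask
      GZ_next <- array(0, dim = c(B, bins, n_in))
      if (bins > 1) {
        gx <- GX[, 2:bins, , drop = FALSE]
        m <- if (!is.null(masks) && !is.null(masks[[l - 1L]]))
          masks[[l - 1L]] else NULL
        if (!is.null(m)) gx <- sweep(gx, c(1, 3), m, `*`)
        GZ_next[, seq_len(bins - 1L), ] <- gx
      }
    }
  }
  gW
}

# score gradient routed back onto the readout trace array
decode_grad <- function(traces, decoding, gs) {
  d <- dim(traces)
  GV <- array(0, dim = d)
  if (decoding == "max_over_time") {
    for (j in seq_len(d[3])) {
      tr <- matrix(traces[, , j], d[1], d[2])
      kmax <- max.col(tr, ties.method = "first")
      GV[cbind(seq_len(d[1]), kmax, j)] <- gs[, j]
    }
  } else {
    GV[, d[2], ] <- gs
  }
  GV
}
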