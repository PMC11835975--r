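#' Train a spiking classifier with surrogate-gradient BPTT
#'
#' Fits a feed-forward spiking network (LIF hidden layers, leaky-integrator
#' readout decoded into class scores) to labeled images. Images are TTFS
#' encoded, the network is unrolled on the time lattice, and weights are
#' trained by backpropagation through time with a fast-sigmoid surrogate in
#' place of the spike threshold, using Adam, optional hidden-spike dropout,
#' learning-rate schedules, substrate regularizers, early stopping on
#' validation accuracy, and a best-on-validation checkpoint.
#'
#' With `backend = "constrained"` the forward pass emulates the substrate:
#' weights are quantized to hardware resolution, input events pass the
#' event-link bandwidth limit, and readout traces are clipped to the ADC
#' range; the backward pass runs through the idealized dynamics with the
#' recorded forward observables substituted (straight-through,
#' hardware-in-the-loop style). `backend = "mixed"` constrains only the
#' layers named in `constrained_layers`. The lattice kernel used here
#' computes the same dynamics as the event-driven executor [run_network()]
#' (the equivalence is part of the test suite), so a constrained forward is a
#' faithful stand-in for a partitioned emulation run.
#'
#' @param x Training images, `(samples, pixels)` matrix.
#' @param y Class labels (factor or integer).
#' @param hidden Integer vector of hidden layer sizes.
#' @param encoder An [encoder_config()].
#' @param control A [train_config()].
#' @param backend `"ideal"`, `"constrained"` or `"mixed"`.
#' @param constrained_layers For `"mixed"`: indices (1 = first hidden) of
#'   layers run constrained.
#' @param spec A [chip_spec()] (constrained modes).
#' @param params_hidden [lif_params()] for hidden layers.
#' @param params_out [lif_params()] for the readout (forced to
#'   leaky-integrate-only).
#' @param x_val,y_val Optional validation set; otherwise `val_fraction` of
#'   the training data is held out.
#' @param cycle,queue_depth Bandwidth-limit parameters (constrained modes).
#' @return An object of class `snn_fit` with the best-on-validation weights,
#'   per-epoch metric history (per seed and averaged), and everything needed
#'   by [predict.snn_fit()].
#' @seealso [predict.snn_fit()], [snn_loss()], [train_config()]
#' @export
snn_fit <- function(x, y, hidden = 24, encoder = encoder_config(),
                    control = train_config(),
                    backend = c("ideal", "constrained", "mixed"),
                    constrained_layers = NULL, spec = chip_spec(),
                    params_hidden = lif_params(),
                    params_out = lif_params(leaky_integrate_only = TRUE),
                    x_val = NULL, y_val = NULL, cycle = 0.008,
                    queue_depth = 4L) {
  backend <- match.arg(backend)
  x <- as.matrix(x)
  yf <- as.factor(y)
  classes <- levels(yf)
  yi <- as.integer(yf)
  C <- length(classes)
  if (C < 2) stop("need at least two classes")
  params_out$leaky_integrate_only <- TRUE
  sizes <- c(ncol(x), hidden, C)
  L <- length(sizes) - 1L
  constrained <- switch(backend,
                        ideal = rep(FALSE, L),
                        constrained = rep(TRUE, L),
                        mixed = seq_len(L) %in% constrained_layers)
  bins <- grid_bins(encoder$T, encoder$dt)

  # held-out validation split (before any training randomness)
  if (is.null(x_val)) {
    set.seed(derive_seed(control$seeds[1], "valsplit"))
    nv <- max(1L, round(control$val_fraction * nrow(x)))
    vi <- sample(nrow(x), nv)
    x_val <- x[vi, , drop = FALSE]; yv <- yi[vi]
    x <- x[-vi, , drop = FALSE]; yi <- yi[-vi]
  } else {
    yv <- as.integer(factor(as.factor(y_val), levels = classes))
  }

  enc_bin <- function(xx, jseed = NULL) {
    ev <- encode_images(xx, encoder, seed = jseed)
    if (constrained[1]) {
      ev <- apply_bandwidth_limit(ev, spec, cycle, queue_depth)$events
    }
    bin_events(ev, "in", ncol(xx), bins, encoder$dt, nrow(xx))
  }
  Xval <- enc_bin(x_val)
  Xtrain0 <- if (encoder$sigma_in > 0) NULL else enc_bin(x)

  clip <- if (constrained[L]) spec$readout_range else NULL
  eff_W <- function(W) {
    lapply(seq_len(L), function(l) {
      if (!constrained[l]) return(W[[l]])
      sc <- auto_scale(W[[l]], spec$weight_levels)
      matrix(dequantize_weights(
        quantize_weights(W[[l]], sc, spec$weight_levels)),
        nrow(W[[l]]), ncol(W[[l]]))
    })
  }
  eval_acc <- function(W, X, yy) {
    fwd <- chain_forward(eff_W(W), X, params_hidden, params_out, encoder$dt,
                         control$beta, clip = clip)
    s <- if (control$decoding == "max_over_time")
      decode_max_over_time(fwd$readout) else decode_last(fwd$readout)
    mean(max.col(s, ties.method = "first") == yy)
  }

  per_seed <- list()
  for (sd_i in seq_along(control$seeds)) {
    s0 <- control$seeds[sd_i]
    set.seed(derive_seed(s0, "init"))
    W <- lapply(seq_len(L), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0,
                          control$w_init_sd / sqrt(sizes[l])),
             sizes[l], sizes[l + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- lapply(W, function(w) w * 0)
    tstep <- 0L
    best <- list(acc = -Inf, W = W, epoch = 0L)
    wait <- 0L
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       train_acc = numeric(), val_acc = numeric(),
                       lr = numeric())
    set.seed(derive_seed(s0, "train"))
    for (ep in seq_len(control$epochs)) {
      lr <- switch(control$lr_schedule,
                   none = control$lr,
                   exponential = control$lr * control$lr_decay^(ep - 1L),
                   halving = control$lr /
                     2^sum(control$halve_at < ep))
      Xtrain <- if (is.null(Xtrain0))
        enc_bin(x, derive_seed(s0, paste0("jitter", ep))) else Xtrain0
      ord <- sample(nrow(x))
      ep_loss <- 0; ep_hits <- 0L
      nb <- ceiling(length(ord) / control$batch_size)
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1L) * control$batch_size + 1L):
                     min(bi * control$batch_size, length(ord))]
        Xb <- Xtrain[idx, , , drop = FALSE]
        yb <- yi[idx]
        masks <- NULL
        if (control$dropout_p > 0 && L > 1L) {
          masks <- lapply(seq_len(L - 1L), function(l)
            matrix(stats::rbinom(length(idx) * sizes[l + 1L], 1,
                                 1 - control$dropout_p),
                   length(idx), sizes[l + 1L]))
        }
        Wu <- eff_W(W)
        fwd <- chain_forward(Wu, Xb, params_hidden, params_out, encoder$dt,
                             control$beta, masks = masks, clip = clip)
        tr <- fwd$readout
        a_itl <- 1
        if (control$itl_rescale && any(constrained)) {
          fwd_ref <- chain_forward(W, Xb, params_hidden, params_out,
                                   encoder$dt, control$beta, masks = masks)
          a_itl <- itl_scale_factor(tr, fwd_ref$readout, fwd$clipped)
          tr <- tr * a_itl
        }
        scores <- if (control$decoding == "max_over_time")
          decode_max_over_time(tr) else decode_last(tr)
        ce <- cross_entropy(scores, yb)
        if (!is.finite(ce$value))
          stop(sprintf("training diverged at epoch %d (non-finite loss)", ep))
        GT <- decode_grad(tr, control$decoding, ce$grad)
        loss <- ce$value
        # readout saturation penalty (on the recorded, possibly clipped trace)
        if (control$reg_sat > 0) {
          pen <- relu(abs(tr) - control$sat_bound)
          loss <- loss + control$reg_sat * mean(pen^2)
          GT <- GT + control$reg_sat * 2 * pen * sign(tr) / length(tr)
        }
        GV <- GT * a_itl
        if (!is.null(fwd$clipped)) GV[fwd$clipped] <- 0
        # hidden firing-rate penalty
        GZx <- NULL
        if (control$reg_rate > 0 && L > 1L) {
          GZx <- vector("list", L - 1L)
          for (l in seq_len(L - 1L)) {
            z <- fwd$layers[[l]]$z
            cj <- apply(z, 3, sum) / dim(z)[1]
            loss <- loss + control$reg_rate * mean(cj^2)
            gz_per <- control$reg_rate * 2 * cj / (length(cj) * dim(z)[1])
            GZx[[l]] <- array(rep(gz_per, each = dim(z)[1] * dim(z)[2]),
                              dim = dim(z))
          }
        }
        gW <- chain_backward(fwd, Wu, params_hidden, params_out, encoder$dt,
                             control$beta, masks = masks, GV_out = GV,
                             GZ_extra = GZx)
        if (control$reg_weight > 0) {
          for (l in seq_len(L)) {
            over <- relu(abs(W[[l]]) - control$weight_bound)
            loss <- loss + control$reg_weight * mean(over^2)
            gW[[l]] <- gW[[l]] + control$reg_weight * 2 * over *
              sign(W[[l]]) / length(W[[l]])
          }
        }
        tstep <- tstep + 1L
        b1 <- control$betas[1]; b2 <- control$betas[2]
        for (l in seq_len(L)) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
          mhat <- mW[[l]] / (1 - b1^tstep)
          vhat <- vW[[l]] / (1 - b2^tstep)
          W[[l]] <- W[[l]] - lr * mhat / (sqrt(vhat) + control$eps)
          if (any(!is.finite(W[[l]])))
            stop(sprintf(
              "training diverged at epoch %d (non-finite weights)", ep))
        }
        ep_loss <- ep_loss + loss * length(idx)
        ep_hits <- ep_hits + sum(max.col(scores,
                                         ties.method = "first") == yb)
      }
      val_acc <- eval_acc(W, Xval, yv)
      hist <- rbind(hist, data.frame(
        epoch = ep, loss = ep_loss / length(ord),
        train_acc = ep_hits / length(ord), val_acc = val_acc, lr = lr))
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, W = W, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= control$patience) break
      }
    }
    per_seed[[sd_i]] <- list(seed = s0, weights = best$W,
                             best_val_acc = best$acc,
                             best_epoch = best$epoch, history = hist)
  }

  fit <- structure(list(
    weights = per_seed[[1]]$weights,
    per_seed = per_seed,
    mean_val_acc = mean(vapply(per_seed, `[[`, numeric(1), "best_val_acc")),
    classes = classes, sizes = sizes, encoder = encoder, control = control,
    backend = backend, constrained = constrained, spec = spec,
    params_hidden = params_hidden, params_out = params_out,
    cycle = cycle, queue_depth = queue_depth),
    class = "snn_fit")
  fit
}

#' Predict from a fitted spiking classifier
#'
#' @param object An [snn_fit()] object.
#' @param newdata `(samples, pixels)` image matrix.
#' @param type `"class"` for labels, `"scores"` for the decoded score
#'   matrix, `"traces"` for the raw readout membrane traces.
#' @param backend Override the forward backend (defaults to the one the model
#'   was trained with).
#' @param ... Unused.
#' @export
predict.snn_fit <- function(object, newdata, type = c("class", "scores",
                                                      "traces"),
                            backend = object$backend, ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  enc <- object$encoder
  bins <- grid_bins(enc$T, enc$dt)
  L <- length(object$weights)
  constrained <- switch(backend,
                        ideal = rep(FALSE, L),
                        constrained = rep(TRUE, L),
                        object$constrained)
  ev <- encode_images(x, enc)
  if (constrained[1])
    ev <- apply_bandwidth_limit(ev, object$spec, object$cycle,
                                object$queue_depth)$events
  X <- bin_events(ev, "in", ncol(x), bins, enc$dt, nrow(x))
  W <- lapply(seq_len(L), function(l) {
    if (!constrained[l]) return(object$weights[[l]])
    sc <- auto_scale(object$weights[[l]], object$spec$weight_levels)
    matrix(dequantize_weights(quantize_weights(object$weights[[l]], sc,
                                               object$spec$weight_levels)),
           nrow(object$weights[[l]]), ncol(object$weights[[l]]))
  })
  clip <- if (constrained[L]) object$spec$readout_range else NULL
  fwd <- chain_forward(W, X, object$params_hidden, object$params_out,
                       enc$dt, object$control$beta, clip = clip)
  if (type == "traces") return(fwd$readout)
  s <- if (object$control$decoding == "max_over_time")
    decode_max_over_time(fwd$readout) else decode_last(fwd$readout)
  colnames(s) <- object$classes
  if (type == "scores") return(s)
  factor(object$classes[max.col(s, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.snn_fit <- function(x, ...) {
  cat(sprintf("<snn_fit> %s -> %s -> %d classes, backend %s\n",
              x$sizes[1],
              paste(x$sizes[-c(1, length(x$sizes))], collapse = " -> "),
              x$sizes[length(x$sizes)], x$backend))
  cat(sprintf("  decoding %s, %d seed(s), best val accuracy %.3f\n",
              x$control$decoding, length(x$per_seed), x$mean_val_acc))
  invisible(x)
}

#' @export
summary.snn_fit <- function(object, ...) {
  h <- object$per_seed[[1]]$history
  cat(sprintf("Spiking classifier: layers %s, %s decoding, backend %s\n",
              paste(object$sizes, collapse = " -> "),
              object$control$decoding, object$backend))
  cat(sprintf("Trained %d epoch(s); best val acc %.3f at epoch %d\n",
              nrow(h), object$per_seed[[1]]$best_val_acc,
              object$per_seed[[1]]$best_epoch))
  invisible(utils::tail(h, 5))
}

#' @export
coef.snn_fit <- function(object, ...) object$weights

#' @export
plot.snn_fit <- function(x, ...) {
  h <- x$per_seed[[1]]$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "loss")
  graphics::plot(h$epoch, h$val_acc, type = "l", col = "darkblue",
                 xlab = "epoch", ylab = "accuracy", ylim = c(0, 1),
                 main = "accuracy")
  graphics::lines(h$epoch, h$train_acc, lty = 2)
  graphics::legend("bottomright", c("validation", "training"),
                   lty = c(1, 2), col = c("darkblue", "black"), bty = "n")
  invisible(x)
}
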