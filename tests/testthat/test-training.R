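test_that("surrogate derivative peaks at threshold and matches its relaxation", {
  expect_identical(surrogate_grad(0, beta = 10), 1)
  expect_lt(surrogate_grad(-5, beta = 10), 1e-3)
  expect_identical(surrogate_spike(c(-1, 0, 2)), c(0, 1, 1))
  # finite differences of the smooth relaxation reproduce the derivative
  xs <- seq(-2, 2, by = 0.07)
  eps <- 1e-6
  fd <- (surrogate_smooth(xs + eps, 10) - surrogate_smooth(xs - eps, 10)) /
    (2 * eps)
  expect_equal(fd, surrogate_grad(xs, 10), tolerance = 1e-4)
})

test_that("score decodings match brute-force oracles", {
  set.seed(31)
  tr <- array(rnorm(4 * 25 * 6), dim = c(4, 25, 6))
  s_max <- decode_max_over_time(tr)
  s_last <- decode_last(tr)
  for (b in 1:4) {
    for (j in 1:6) {
      expect_identical(s_max[b, j], max(tr[b, , j]))
      expect_identical(s_last[b, j], tr[b, 25, j])
    }
  }
  const <- array(0.7, dim = c(2, 10, 3))
  expect_true(all(decode_max_over_time(const) == 0.7))
  expect_true(all(decode_last(const) == 0.7))
})

test_that("loss is cross-entropy plus penalties active only out of bounds", {
  # uniform scores over C classes -> ln C
  expect_equal(snn_loss(matrix(0, 3, 5), c(1L, 3L, 5L)), log(5))
  # confident correct scores drive the loss toward zero
  s <- matrix(-50, 2, 3)
  s[cbind(1:2, 1:2)] <- 50
  expect_lt(snn_loss(s, 1:2), 1e-10)
  expect_error(snn_loss(matrix(0, 2, 3), c(1L, 4L)), "label")
  # penalties vanish when activity and weights sit inside the bounds
  z <- array(0, dim = c(2, 10, 4))
  v <- array(0.5, dim = c(2, 10, 3))
  W <- list(matrix(0.3, 2, 2))
  base <- snn_loss(matrix(0, 2, 3), c(1L, 2L))
  expect_equal(snn_loss(matrix(0, 2, 3), c(1L, 2L), hidden_spikes = list(z),
                        readout_traces = v, weights = W,
                        reg = c(rate = 1, sat = 1, weight = 1)), base)
  # and grow once they leave them
  expect_gt(snn_loss(matrix(0, 2, 3), c(1L, 2L),
                     readout_traces = v * 10,
                     reg = c(rate = 0, sat = 1, weight = 0)), base)
})

test_that("BPTT gradients match central differences of the relaxed model", {
  set.seed(7)
  # 3-neuron toy with fixed events, both decodings, through two layers
  W <- list(matrix(rnorm(4 * 3, 0, 0.6), 4, 3),
            matrix(rnorm(3 * 2, 0, 0.6), 3, 2))
  ph <- lif_params(tau_m = 10, tau_s = 5, v_th = 0.4)
  po <- lif_params(leaky_integrate_only = TRUE)
  X <- array(0, dim = c(2, 20, 4))
  X[1, 1, 1] <- 1; X[1, 3, 2] <- 1; X[2, 2, 3] <- 1
  X[2, 5, 4] <- 1; X[1, 8, 1] <- 1
  y <- c(1L, 2L)
  beta <- 10; dt <- 0.5; eps <- 1e-6
  for (decoding in c("last_value", "max_over_time")) {
    lossfun <- function(Wl) {
      fw <- snnpart:::chain_forward(Wl, X, ph, po, dt, beta, smooth = TRUE)
      s <- if (decoding == "max_over_time") decode_max_over_time(fw$readout)
           else decode_last(fw$readout)
      snnpart:::cross_entropy(s, y)$value
    }
    fw <- snnpart:::chain_forward(W, X, ph, po, dt, beta, smooth = TRUE)
    s <- if (decoding == "max_over_time") decode_max_over_time(fw$readout)
         else decode_last(fw$readout)
    ce <- snnpart:::cross_entropy(s, y)
    GV <- snnpart:::decode_grad(fw$readout, decoding, ce$grad)
    gW <- snnpart:::chain_backward(fw, W, ph, po, dt, beta, smooth = TRUE,
                                   GV_out = GV)
    max_rel <- 0
    for (l in 1:2) {
      for (i in seq_along(W[[l]])) {
        Wp <- W; Wp[[l]][i] <- Wp[[l]][i] + eps
        Wm <- W; Wm[[l]][i] <- Wm[[l]][i] - eps
        fd <- (lossfun(Wp) - lossfun(Wm)) / (2 * eps)
        den <- max(abs(fd), abs(gW[[l]][i]), 1e-8)
        if (den > 1e-8) {
          max_rel <- max(max_rel, abs(fd - gW[[l]][i]) / den)
        }
      }
    }
    expect_lt(max_rel, 1e-4)
  }
})

test_that("dropout at p = 0 is the identity and withholds spikes at p > 0", {
  set.seed(41)
  W <- list(matrix(rnorm(6 * 8, 0.3, 0.5), 6, 8),
            matrix(rnorm(8 * 2, 0.2, 0.4), 8, 2))
  ph <- lif_params(v_th = 0.4)
  po <- lif_params(leaky_integrate_only = TRUE)
  X <- array(rbinom(3 * 30 * 6, 1, 0.1), dim = c(3, 30, 6))
  full <- matrix(1, 3, 8)
  f0 <- snnpart:::chain_forward(W, X, ph, po, 0.5, 10)
  f1 <- snnpart:::chain_forward(W, X, ph, po, 0.5, 10, masks = list(full))
  expect_identical(f0$readout, f1$readout)
  # a masked-out neuron contributes nothing downstream
  none <- matrix(0, 3, 8)
  f2 <- snnpart:::chain_forward(W, X, ph, po, 0.5, 10, masks = list(none))
  expect_true(all(f2$readout == 0))
  expect_identical(f2$layers[[1]]$z, f0$layers[[1]]$z)  # hidden untouched
})

test_that("training is reproducible, inert at zero learning rate, and aborts on divergence", {
  task <- generate_synthetic_images(synthetic_task_spec(n_samples = 60,
                                                        seed = 2))
  enc <- encoder_config("linear", T = 30, dt = 0.5)
  ctrl0 <- train_config(lr = 0, epochs = 2, batch_size = 30, seeds = 7L)
  f0 <- snn_fit(task$x, task$y, hidden = 8, encoder = enc, control = ctrl0)
  set.seed(derive_seed(7L, "init"))
  W1 <- matrix(rnorm(64 * 8, 0, 8 / sqrt(64)), 64, 8)
  expect_equal(f0$weights[[1]], W1)  # untouched by zero-lr updates

  ctrl <- train_config(lr = 5e-3, epochs = 3, batch_size = 30, seeds = 7L,
                       dropout_p = 0.2)
  fa <- snn_fit(task$x, task$y, hidden = 8, encoder = enc, control = ctrl)
  fb <- snn_fit(task$x, task$y, hidden = 8, encoder = enc, control = ctrl)
  expect_identical(fa$weights, fb$weights)
  expect_identical(fa$per_seed[[1]]$history, fb$per_seed[[1]]$history)

  ctrl_bad <- train_config(lr = Inf, epochs = 3, batch_size = 30,
                           seeds = 7L)
  expect_error(snn_fit(task$x, task$y, hidden = 8, encoder = enc,
                       control = ctrl_bad), "diverged")
})

test_that("the separable synthetic task is learned end to end", {
  task <- generate_synthetic_images(synthetic_task_spec(n_samples = 240,
                                                        seed = 11))
  itr <- seq_len(200); ite <- 201:240
  ctrl <- train_config(lr = 5e-3, epochs = 35, batch_size = 50,
                       decoding = "max_over_time", beta = 5, seeds = 101L)
  fit <- snn_fit(task$x[itr, ], task$y[itr], hidden = 24,
                 encoder = encoder_config("linear", T = 30, dt = 0.5),
                 control = ctrl)
  acc <- mean(predict(fit, task$x[ite, ]) == task$y[ite])
  expect_gte(acc, 0.9)
  sc <- predict(fit, task$x[ite, ], type = "scores")
  expect_identical(dim(sc), c(40L, 3L))
})
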