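test_that("single-event subthreshold response matches the closed form at first order", {
  w <- 0.1
  p <- lif_params(tau_m = 10, tau_s = 5, g_l = 1)
  ev <- event_batch(1, 0, "in", 1)
  errs <- vapply(c(0.5, 0.25, 0.125), function(dt) {
    r <- integrate_instance(ev, matrix(w), p, T = 30, dt = dt)
    tt <- seq_len(dim(r$traces)[2]) * dt
    closed <- (w / p$g_l) * p$tau_s / (p$tau_m - p$tau_s) *
      (exp(-tt / p$tau_m) - exp(-tt / p$tau_s))
    max(abs(r$traces[1, , 1] - closed))
  }, numeric(1))
  expect_lt(errs[1], 2e-3)
  # first-order convergence: error roughly halves with the step
  expect_gt(errs[1] / errs[2], 1.6)
  expect_gt(errs[2] / errs[3], 1.6)
  expect_lt(errs[1] / errs[2], 2.6)
})

test_that("spike times agree with a 100x finer reference integrator", {
  p <- lif_params(tau_m = 10, tau_s = 5, v_th = 1)
  dt <- 0.5
  for (w in c(6, 10, 25)) {
    ev <- event_batch(1, 0, "in", 1)
    coarse <- integrate_instance(ev, matrix(w), p, T = 30, dt = dt)
    fine <- integrate_instance(ev, matrix(w), p, T = 30, dt = dt / 100)
    t1 <- coarse$events$time_us[1]
    t2 <- fine$events$time_us[1]
    expect_false(is.na(t1))
    expect_false(is.na(t2))
    expect_lte(abs(t1 - t2), dt)
  }
})

test_that("zero weights leave the membrane at the leak potential", {
  p <- lif_params(E_l = -0.2)
  ev <- random_stimuli(6, 2, seed = 4)
  r <- integrate_instance(ev, matrix(0, 6, 3), p, T = 30)
  expect_identical(nrow(r$events), 0L)
  expect_true(all(r$traces == p$E_l))
})

test_that("refractory neurons hold at reset and re-arm afterwards", {
  p <- lif_params(tau_m = 10, tau_s = 5, v_th = 0.5, tau_ref = 5)
  ev <- event_batch(1, 0, "in", 1)
  r <- integrate_instance(ev, matrix(20), p, T = 30, dt = 0.5)
  st <- r$events$time_us
  expect_gte(min(diff(st)), 5)  # no two spikes closer than tau_ref
})

test_that("weight quantization rounds, saturates, and round-trips the scale", {
  q <- quantize_weights(matrix(c(0, 0.5, -0.2, 2)), scale = 100)
  expect_identical(as.vector(q), c(0, 50, -20, 63))
  expect_identical(attr(q, "scale"), 100)
  dq <- dequantize_weights(q)
  expect_equal(as.vector(dq), c(0, 0.5, -0.2, 0.63))
  # saturation at +/- (levels - 1)
  expect_identical(as.vector(quantize_weights(c(-5, 5), 100)), c(-63, 63))
  # round-half-to-even at the .5 boundary: both half-cases land on 62
  expect_identical(as.vector(quantize_weights(c(0.625, 0.615), 100)),
                   c(62, 62))
  expect_error(quantize_weights(matrix(NaN), 1), "finite")
  expect_error(quantize_weights(matrix(1), -1), "positive")
})

test_that("bandwidth limiting keeps, delays and drops per the FIFO model", {
  spec <- chip_spec()
  # under the per-cycle cap: untouched
  ev <- event_batch(1, c(0, 0.004, 0.016, 0.02), "in", 1:4)
  r <- apply_bandwidth_limit(ev, spec, cycle = 0.008, queue_depth = 4)
  expect_identical(as.data.frame(r$events), as.data.frame(ev))
  expect_identical(r$n_dropped, 0L)

  # 10 simultaneous events, queue depth 4: 2 on time, 4 delayed, 4 dropped
  ev10 <- event_batch(rep(1, 10), rep(0, 10), "in", 1:10)
  r10 <- apply_bandwidth_limit(ev10, spec, cycle = 0.008, queue_depth = 4)
  expect_identical(nrow(r10$events), 6L)
  expect_identical(r10$n_dropped, 4L)
  expect_identical(r10$n_delayed, 4L)
  expect_identical(sum(r10$events$time_us == 0), 2L)
  expect_identical(sort(unique(r10$events$time_us)), c(0, 0.008, 0.016))

  # empty batch passes through
  r0 <- apply_bandwidth_limit(event_batch(), spec)
  expect_identical(nrow(r0$events), 0L)
  expect_identical(r0$n_dropped, 0L)
})

test_that("bandwidth limiting conserves events: kept + dropped == input", {
  spec <- chip_spec()
  set.seed(9)
  for (i in 1:5) {
    n <- sample(5:60, 1)
    ev <- event_batch(sample(1:2, n, TRUE), round(runif(n, 0, 1), 3), "in",
                      sample(1:8, n, TRUE), n_samples = 2)
    r <- apply_bandwidth_limit(ev, spec, cycle = 0.01,
                               queue_depth = sample(1:5, 1))
    expect_identical(nrow(r$events) + r$n_dropped, nrow(ev))
    # no event is created earlier than it occurred
    expect_true(all(r$events$time_us >=
                      tapply(ev$time_us, ev$sample_id, min)[
                        as.character(r$events$sample_id)] - 1e-9))
  }
})

test_that("constrained mode converges to ideal as weight resolution grows", {
  set.seed(12)
  W <- matrix(rnorm(10 * 6, 0.2, 0.6), 10, 6)
  p <- lif_params(v_th = 0.7)
  ev <- random_stimuli(10, 2, seed = 13)
  ideal <- integrate_instance(ev, W, p, T = 30)
  fine <- integrate_instance(ev, W, p, T = 30, mode = "constrained",
                             spec = chip_spec(weight_levels = 2^24,
                                              readout_range = c(-100, 100)))
  expect_identical(as.data.frame(fine$events), as.data.frame(ideal$events))
  expect_lt(max(abs(fine$traces - ideal$traces)), 1e-4)
  # at 6 bit the spike count is similar but traces differ measurably
  coarse <- integrate_instance(ev, W, p, T = 30, mode = "constrained")
  expect_gt(max(abs(coarse$traces - ideal$traces)), 1e-6)
})

test_that("trace scaling recovers proportionality factors", {
  set.seed(3)
  ref <- array(rnorm(2 * 30 * 4), dim = c(2, 30, 4))
  expect_equal(itl_scale_factor(ref, ref), 1.0)
  expect_equal(itl_scale_factor(0.5 * ref, ref), 2.0)
  noisy <- 0.25 * ref + array(rnorm(length(ref), 0, 1e-3), dim = dim(ref))
  expect_equal(itl_scale_factor(noisy, ref), 4.0, tolerance = 0.02)
  expect_error(itl_scale_factor(ref * 0, ref), "undefined")
  expect_error(
    itl_scale_factor(ref, ref, clipped = array(TRUE, dim = dim(ref))),
    "undefined")
})
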