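test_that("inter-execution projections are derived from instance crossings", {
  # single instance: nothing crosses
  net1 <- make_split_net(c(10, 8, 3), parts = c(1, 1), monolithic = TRUE,
                         seed = 1)
  expect_length(derive_inter_execution(net1), 0L)

  # 3-layer chain, one instance per layer: 2 crossings
  net2 <- make_split_net(c(10, 8, 6, 3), parts = c(1, 1, 1),
                         monolithic = FALSE, seed = 1)
  expect_length(derive_inter_execution(net2), 3L - 1L)

  # digit-net shape: 4 hidden parts + readout -> 4 projections into readout
  net3 <- make_split_net(c(10, 16, 3), parts = c(4, 1), monolithic = FALSE,
                         seed = 1)
  iep <- derive_inter_execution(net3)
  expect_length(iep, 4L)
  expect_identical(unique(vapply(iep, `[[`, character(1),
                                 "target_instance")), "I_l2_p1")

  # unassigned population is a configuration error
  bad <- snn_network(list(population("in", 4, is_input = TRUE),
                          population("h", 4, lif_params())),
                     list(projection("in", "h", matrix(0, 4, 4))))
  expect_error(derive_inter_execution(bad), "not assigned")
})

test_that("scheduling is layered, topological, and rejects cross-instance recurrence", {
  net3 <- make_split_net(c(10, 16, 3), parts = c(4, 1), monolithic = FALSE,
                         seed = 1)
  st <- schedule(net3)
  expect_length(st, 2L)            # hidden stage, then readout stage
  expect_length(st[[1]], 4L)       # four concurrent hidden parts
  expect_length(st[[2]], 1L)
  expect_identical(sort(unlist(st)),
                   sort(unique(stats::na.omit(vapply(net3$populations,
                                                     `[[`, character(1),
                                                     "instance")))))

  expect_length(schedule(make_split_net(c(6, 4, 2), c(1, 1), TRUE, 1)), 1L)

  # stage count equals the longest dependency-path length
  chain <- make_split_net(c(8, 6, 6, 6, 2), parts = c(2, 1, 2, 1),
                          monolithic = FALSE, seed = 2)
  expect_length(schedule(chain), 4L)

  # recurrence across two instances is an error
  p <- lif_params(v_th = 0.5)
  rec <- snn_network(
    list(population("in", 2, is_input = TRUE),
         population("a", 2, p, instance = "A"),
         population("b", 2, p, instance = "B")),
    list(projection("in", "a", matrix(0.2, 2, 2)),
         projection("a", "b", matrix(0.2, 2, 2)),
         projection("b", "a", matrix(0.2, 2, 2))))
  expect_error(schedule(rec), "confined to one execution instance")
})

test_that("recurrence inside one instance is integrated, not rejected", {
  p <- lif_params(v_th = 0.3, tau_m = 10, tau_s = 5)
  net <- snn_network(
    list(population("in", 2, is_input = TRUE),
         population("a", 2, p, instance = "A"),
         population("b", 2, p, instance = "A")),
    list(projection("in", "a", diag(2) * 2),
         projection("a", "b", diag(2) * 2),
         projection("b", "a", diag(2) * 2)))
  expect_length(schedule(net), 1L)
  ev <- event_batch(1, 0, "in", 1)
  r <- run_network(net, ev, T = 30)
  # the loop keeps both populations spiking well past the single input event
  expect_gt(nrow(r$events$a), 3)
  expect_gt(nrow(r$events$b), 3)
})

test_that("zero weights propagate no spikes and silent runs stay silent", {
  p <- lif_params()
  net <- snn_network(
    list(population("in", 5, is_input = TRUE),
         population("h", 4, p, instance = "A", record_membrane = TRUE),
         population("o", 2, lif_params(leaky_integrate_only = TRUE),
                    instance = "B", record_membrane = TRUE)),
    list(projection("in", "h", matrix(0, 5, 4)),
         projection("h", "o", matrix(0, 4, 2))))
  ev <- random_stimuli(5, 2, seed = 3)
  r <- run_network(net, ev, T = 30)
  expect_identical(nrow(r$events$h), 0L)
  expect_identical(nrow(r$events$o), 0L)
  expect_true(all(r$traces$h == p$E_l))
  expect_true(all(r$traces$o == 0))
})

test_that("running requires stimuli for every consumed input population", {
  net <- make_split_net(c(10, 8, 3), parts = c(1, 1), monolithic = FALSE,
                        seed = 1)
  ev <- event_batch(1, 1, "not_the_input", 1)
  expect_error(run_network(net, ev, T = 30), "missing stimulus")
})

test_that("partitioned and monolithic execution agree bit-exactly", {
  # study-shaped case first: 4 hidden parts + readout
  widths <- c(20, 32, 4)
  mono <- make_split_net(widths, c(4, 1), monolithic = TRUE, seed = 10)
  part <- make_split_net(widths, c(4, 1), monolithic = FALSE, seed = 10)
  ev <- random_stimuli(20, 3, seed = 11)
  r1 <- run_network(mono, ev, T = 30)
  r2 <- run_network(part, ev, T = 30)
  expect_gt(nrow(run_signature(r1)), 50)  # dynamics actually active
  expect_identical(run_signature(r1), run_signature(r2))
  for (nm in names(r1$traces)) {
    expect_identical(r1$traces[[nm]], r2$traces[[nm]])
  }
})

test_that("event replay between instances is lossless before bandwidth limiting", {
  net <- make_split_net(c(12, 10, 3), parts = c(2, 1), monolithic = FALSE,
                        seed = 5)
  ev <- random_stimuli(12, 2, seed = 6)
  r <- run_network(net, ev, T = 30)
  # everything the hidden parts emitted lands in the readout's input window,
  # except spikes stamped at T which can no longer act within [0, T)
  for (nm in c("l1_p1", "l1_p2")) {
    src <- r$events[[nm]]
    arr <- snnpart:::bin_events(src, nm, net$populations[[nm]]$size,
                                snnpart:::grid_bins(30, 0.5), 0.5, 2)
    expect_equal(sum(arr), sum(src$time_us < 30))
  }
})
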