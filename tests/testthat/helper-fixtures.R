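# Shared test fixtures: random feed-forward networks built twice -- once with
# every population in a single execution instance (monolithic) and once with
# each part on its own instance (partitioned) -- plus small event utilities.

# A random feed-forward chain: `widths` neurons per layer (last layer is the
# LI readout), each layer split into `parts[l]` populations. Weights are
# drawn once and sliced identically for both variants, scaled so hidden
# layers actually spike.
make_split_net <- function(widths, parts, monolithic, seed,
                           v_th = 0.6, w_mu = 0.15, w_sd = 0.5) {
  set.seed(seed)
  ph <- lif_params(tau_m = 10, tau_s = 5, v_th = v_th)
  po <- lif_params(leaky_integrate_only = TRUE)
  n_in <- widths[1]
  L <- length(widths) - 1L
  pops <- list(population("in", n_in, is_input = TRUE))
  projs <- list()
  prev <- list(list(name = "in", size = n_in))
  for (l in seq_len(L)) {
    w <- widths[l + 1L]
    np <- parts[l]
    sz <- rep(w %/% np, np)
    sz[seq_len(w - sum(sz))] <- sz[seq_len(w - sum(sz))] + 1L
    sz <- sz[sz > 0]
    li <- l == L
    cur <- list()
    for (pi in seq_along(sz)) {
      nm <- sprintf("l%d_p%d", l, pi)
      inst <- if (monolithic) "M" else paste0("I_", nm)
      pops[[length(pops) + 1L]] <- population(
        nm, sz[pi], if (li) po else ph, instance = inst,
        record_membrane = li)
      for (src in prev) {
        W <- matrix(rnorm(src$size * sz[pi], w_mu, w_sd), src$size, sz[pi])
        projs[[length(projs) + 1L]] <- projection(src$name, nm, W)
      }
      cur[[pi]] <- list(name = nm, size = sz[pi])
    }
    prev <- cur
  }
  snn_network(pops, projs)
}

random_stimuli <- function(n_in, n_samp, T = 30, dt = 0.5, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n_samp * n_in), n_samp, n_in)
  encode_images(x, encoder_config("linear", T = T, dt = dt))
}

# concatenate all recorded events of a run into one canonical data frame
run_signature <- function(run) {
  ev <- do.call(rbind, lapply(names(run$events), function(nm)
    as.data.frame(run$events[[nm]])))
  ev <- ev[order(ev$population, ev$sample_id, ev$time_us, ev$neuron_id), ]
  rownames(ev) <- NULL
  ev
}
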