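# snnpart

Partitioned emulation and training of spiking neural networks on
resource-constrained neuromorphic substrates.

## The problem

Analog neuromorphic accelerators emulate spiking neural networks (SNNs) on
physical neuron and synapse circuits, so a single chip bounds the model that
can run at once — typically a few hundred neurons, a fixed synaptic fan-in
per neuron circuit, limited-resolution signed weights, and an event link
that sustains only a couple of spikes per clock cycle. Deep SNNs are much
larger than that. For feed-forward topologies (and networks whose recurrent
subgraphs individually fit the chip) the substrate can be *virtualized*:
split the network into execution instances, run them sequentially on the
same chip, record every spike an instance emits, and play the recorded
events back into dependent instances. Spikes are events in time that can be
recorded and replayed exactly, so partitioning does not change the emulated
dynamics.

`snnpart` implements this workflow for modelers and hardware architects who
want to size networks against present or planned substrates without the
hardware in hand:

* **Substrate model** — `chip_spec()` with the single-chip constants
  (512 neuron circuits, fan-in 256 per circuit, two 6-bit synapses per
  signed weight, 64 event labels per row, 2 events/cycle) and the
  capacity arithmetic: combining 2^k neuron circuits multiplies fan-in,
  `circuits_per_neuron()`, `neurons_per_run()`, `max_fanout()` (32 768),
  `max_signed_fan_in()` (65 536).
* **Planner** — `plan_layer()` / `plan_network()` map layers to sequential
  runs; `receptive_field_grid()` and `sparse_label_fit()` handle sparse
  receptive-field layers packed through row labels; `project_runs()` unrolls
  convolutions and projects run counts for whole topologies.
* **Executor** — `snn_network()` of populations/projections annotated with
  execution instances; `derive_inter_execution()`, `schedule()` (layered
  topological stages; cross-instance recurrence is rejected), and
  `run_network()` with lossless inter-instance event record/playback.
* **Emulator** — exponential-Euler CUBA LIF/LI dynamics on a δt lattice
  (`integrate_instance()`), with an ideal mode and a constrained mode that
  quantizes weights (`quantize_weights()`), applies the event-link FIFO
  bandwidth model (`apply_bandwidth_limit()`) and clips readout traces.
* **Encoders** — two time-to-first-spike schemes (`ttfs_linear()`,
  `ttfs_lif_current()`), pixel jitter, and per-bin event-load statistics.
* **Training** — `snn_fit()`: surrogate-gradient backpropagation through
  time (fast-sigmoid surrogate `1/(β|v−ϑ|+1)²`), Adam, dropout, schedules,
  substrate regularizers, early stopping, and ideal / constrained / mixed
  per-layer backends (hardware-in-the-loop style straight-through
  gradients).

The membrane dynamics are

    τ_m dv/dt = −(v − E_l) + I/g_l,   I(t) = Σ_i w_i Θ(t − t_i) exp(−(t − t_i)/τ_s),

with spike and reset at threshold ϑ; readout units are leaky integrators
decoded by max-over-time or last-value into class scores.

## Worked example

Plan the classic 28×28 → 256 → 10 digit classifier onto a single chip:

```r
library(snnpart)
plan_network(data.frame(name = c("hidden", "readout"),
                        size = c(256, 10), fan_in = c(784, 256)))
#> <partition_plan>
#>    layer size fan_in circuits_per_neuron neurons_per_run runs
#>   hidden  256    784                   8              64    4
#>  readout   10    256                   2             256    1
#> total runs: 5
```

Each 784-input neuron needs 8 combined circuits (2 × 784 = 1568 hardware
synapses), leaving 64 logical neurons per run, so the 256-unit hidden layer
splits into 4 parts; with the readout run that is 5 sequential executions of
one chip.

Encode images to spikes and train a classifier on the packaged synthetic
task (3 classes, latency-separable by construction):

```r
task <- generate_synthetic_images(synthetic_task_spec(n_classes = 3,
                                                      n_samples = 360,
                                                      seed = 11))
train <- 1:300; test <- 301:360
fit <- snn_fit(task$x[train, ], task$y[train], hidden = 24,
               encoder = encoder_config("linear", T = 30, dt = 0.5),
               control = train_config(lr = 5e-3, epochs = 50,
                                      batch_size = 50, beta = 5,
                                      patience = 15, seeds = 101L))
fit
#> <snn_fit> 64 -> 24 -> 3 classes, backend ideal
#>   decoding max_over_time, 1 seed(s), best val accuracy 1.000
mean(predict(fit, task$x[test, ]) == task$y[test])
#> [1] 1
```

Brighter pixels spike earlier; the class blob produces the earliest events
and the readout's max-over-time score picks the class. Re-running with
`backend = "constrained"` trains through 6-bit weights, the bandwidth limit
and readout clipping, and stays within a few points of the ideal backend.

A thin CLI wraps the same functions
(`Rscript inst/cli/snnpart.R plan --config inst/extdata/eurosat.yaml`,
plus `encode`, `run`, `train` subcommands); `inst/extdata/` ships presets
for the full-scale 28×28 digit and 64×64×3 land-cover experiments, which
document the published large-scale runs (those need dataset downloads and
long training and are not reproduced by the test suite).

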