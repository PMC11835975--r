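---
title: "Partitioned emulation and training of spiking networks on an undersized substrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned emulation and training of spiking networks on an undersized substrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snnpart)
```

## The problem

Analog neuromorphic accelerators emulate spiking neural networks (SNNs) in
continuous time on dedicated circuits, so the network that can run *at once*
is bounded by the physical resources: neuron circuits, synapse rows, event
labels, and the event-link bandwidth. Feed-forward networks (and networks
whose recurrent subgraphs individually fit the chip) admit a way out: split
the network into **execution instances**, run the instances sequentially on
the same substrate, record every spike an instance emits, and play those
spikes back into the instances that depend on them. Because spikes are
discrete events in time that can be recorded and replayed exactly, this
partitioning does not change the emulated dynamics — a property this package
turns into a machine-checked invariant.

`snnpart` implements the whole workflow in software: a substrate resource
model, a partition planner, an execution-instance scheduler and executor
with inter-execution record/playback, a leaky integrate-and-fire (LIF)
emulator standing in for the analog chip, two time-to-first-spike (TTFS)
image encoders, and surrogate-gradient training through the emulated
substrate.

## The substrate model

A `chip_spec()` collects the resource constants of one substrate allocation.
The defaults describe a single-chip system with 512 neuron circuits, 256
hardware synapses (unsigned weights) per circuit, two 6-bit synapses per
signed weight, 64 event labels per synapse row, a routing fan-out bound of
2 × 32 × 2 × 256 = 32 768, and an event link that processes two spikes per
clock cycle.

Neuron circuits can be *combined* to multiply the fan-in of one logical
neuron. Combining happens in powers of two: `circuits_per_neuron(f)` returns
the smallest power of two `p` with `p * 256 >= 2 * f`. Pure ceiling
arithmetic would allocate 7 circuits for a signed fan-in of 784
(`ceiling(1568/256)`), but the hardware's worked mappings use 8 circuits for
784 inputs and 4 for 484, which pins down the power-of-two rule; it also
keeps `neurons_per_run(p) * p == 512` exact for every admissible `p`.
Combining every circuit yields the full-chip bound of 65 536 signed
(131 072 unsigned) weights.

The membrane ADC range is not a published constant; `readout_range` defaults
to the symmetric dimensionless interval [−1, 1] and is configurable.

## Neuron dynamics and the time lattice

Neurons follow current-based (CUBA) LIF dynamics,

$$\tau_m \dot v = -(v - E_l) + I/g_l, \qquad
I(t) = \sum_{\{t_i^s\}} w_i\,\Theta(t - t_i^s)\, e^{-(t - t_i^s)/\tau_s},$$

with a spike and reset to $E_r$ when $v \ge \vartheta$; readout units are
leaky integrators (LI) — the same membrane without a threshold. Integration
uses exponential Euler on a lattice of step $\delta t$ (default 0.5 µs,
configurable): per bin the synaptic current decays by $e^{-\delta t/\tau_s}$
and absorbs the weights of the bin's input events as impulses, then the
membrane decays toward $E_l$ by $e^{-\delta t/\tau_m}$ and integrates
$I/g_l\,(1 - e^{-\delta t/\tau_m})$, treating $I$ as constant over the bin.
This keeps the two exponential decays exact on the grid and is first-order
accurate overall, which the test suite verifies against the closed-form
single-event response and a 100× finer reference integrator. The spike
condition is checked after the membrane update; all simultaneous crossings
fire (there is no intra-bin arbitration), and a refractory time (default 0)
holds the membrane at reset.

Timing conventions are chosen so that replay is exact: an input event at
time $t$ lands in bin $\lfloor t/\delta t \rfloor + 1$, and a spike emitted
in bin $k$ is stamped $k\,\delta t$ — the grid time at which the crossing
was detected — so it reaches intra-instance targets in bin $k+1$, exactly
the bin its recorded-and-replayed copy lands in. A spike stamped at the
window end $T$ can no longer act within the window in either path. This is
what makes partitioned and monolithic execution *bit-identical*, not merely
close: the executor also accumulates projection drive in declared projection
order, so floating-point summation order is the same in both paths. The
acceptance suite asserts bit-equality of all spike trains and membrane
traces on 20 random feed-forward networks.

When several source instances feed one target, the merged replayed stream is
ordered by (sample, time, source population, neuron). Within-bin drive
accumulation is commutative, so this order only matters as the deterministic
tie-break for bandwidth limiting.

Recurrence *within* one instance is integrated normally (spikes feed back
with one-bin transmission delay). Recurrence *across* instances is rejected
by the scheduler: sequential record/playback cannot close a loop between
runs, so cross-instance cycles would need concurrent hardware and are out of
scope. The schedule itself is a layered topological order — instances in a
stage are mutually independent (they could run concurrently on a large
enough multi-chip system), stages run sequentially, and instances are sorted
by id within a stage for reproducibility.

## Constrained mode: standing in for the hardware

`mode = "constrained"` adds the three substrate artifacts that matter for
training:

* **Weight quantization.** Signed weights are rounded (half to even) to
  integer levels in ±63 (6 bit) and used as level/scale. Unless a fixed
  scale is supplied, the scale puts the largest weight magnitude on the top
  level. Quantization error vanishes as the resolution grows, which is
  tested by raising `weight_levels`.
* **Bandwidth limiting.** The event link serves at most 2 events per clock
  cycle; excess simultaneous events are delayed through a bounded FIFO
  (default depth 4) and dropped when the queue is full. The cycle defaults
  to 8 ns — two events per cycle at the 250 MHz sustained event rate — and
  is configurable since the exact link clock is an implementation detail.
  Kept + dropped always equals the input count.
* **Readout clipping.** Recorded membrane traces are clipped to
  `readout_range`, modeling the ADC. Gradients are masked at clipped bins.

The least-squares factor scaling recorded traces onto idealized reference
dynamics (`itl_scale_factor()`) supports hardware-in-the-loop gradient
estimation; in this software emulator the two share units, so the factor is
≈1 and rescaling is off by default in `snn_fit()`.

## TTFS encoders

Both encoders emit at most one spike per pixel, earlier for brighter pixels,
inside the half-open window $[0, T)$:

* **Linear**: $t = T - \operatorname{round}(\tfrac{T}{\delta t}\,
  \tfrac{x - x_{\min}}{x_{\max} - x_{\min}})\,\delta t$, with
  $x_{\min/\max}$ dataset-global bounds. Rounding is half-to-even (exact
  half-cases are rare; the convention is documented rather than load-
  bearing). A pixel at $x_{\min}$ maps to $t = T$, which falls outside the
  observed window, so it emits nothing — the natural reading of a boundary
  the scheme itself leaves open.
* **Constant-current LIF**: the biased intensity $a = x + x_{\min}^{bias}$
  drives $\dot v = -v/\tau_{en} + a$; the spike time is the closed-form
  threshold crossing $t = -\tau_{en}\ln(1 - \vartheta_{en}/(\tau_{en} a))$,
  or nothing when $\tau_{en} a \le \vartheta_{en}$. Times are kept at
  continuous (link-clock-like) resolution rather than snapped to
  $\delta t$, which spreads ties; the closed form is cross-checked against
  adaptive-step numerical integration to 10⁻⁶ relative error. Defaults
  ($\tau_{en} = 10$ µs, $\vartheta_{en} = 1$, bias 0.05) spread unit-range
  pixels over roughly the first third of a 64 µs window and silence
  near-zero pixels.

Pixel jitter (seeded Gaussian noise, clamped to [0, 1] before the
current-driven scheme, whose derivation assumes that range) breaks spike-time
ties that would otherwise stress the event link; `spike_stats()` reports the
sustained and peak per-bin event load that motivates it.

## The planner

`plan_layer()` converts (layer size, signed fan-in) into circuits per
neuron, neurons per run, and run count; `plan_network()` sums layers. Two
conventions matter:

* **Receptive-field grids use ceiling division with zero padding**: tiling a
  64 × 64 × 3 image with 3 × 3 × 3 kernels at stride 3 gives a 22 × 22 grid,
  i.e. 484 neurons with 27 inputs each — floor division would give 441 and
  contradict the hardware mapping this reproduces. Padded positions simply
  contribute no input.
* **`parts_override` models bandwidth-motivated splitting.** Splitting a
  layer reduces the input events each run must absorb. The planner does not
  predict when the event link would saturate — the published 8-part split of
  the sparse 484-neuron layer was chosen empirically — so the override is an
  explicit input, validated against the capacity minimum.

Sparse receptive-field layers map through row labels: one synapse row
addresses up to 64 neurons, so a 27-input receptive field packs in blocks of
27 × 64 signed synapses; 484 neurons need 8 blocks = 216 rows and 484
circuit columns, feasible in a single run. Readout layers always occupy
their own run(s); co-placing them with hidden parts is a mapping
optimization this package does not attempt, matching both reference
mappings. `project_runs()` extends the arithmetic to spatially unrolled
convolutions (each output pixel × channel becomes one logical neuron with
kernel-volume fan-in).

## Training

`snn_fit()` trains a chain of LIF hidden layers plus an LI readout by
backpropagation through time on the same lattice the emulator uses. The
spike threshold's backward pass uses the fast-sigmoid surrogate
$1/(\beta|v-\vartheta|+1)^2$ (the derivative of $x/(1+\beta|x|)$); $\beta$
defaults to 10. The adjoint recursion is hand-derived and runs the forward
recurrences in reverse, including the reset's dependence on the spike; on
the *smoothed* relaxation of the model (threshold replaced by the surrogate's
antiderivative) the same code is the exact gradient, which is how the test
suite validates it against central finite differences to 10⁻⁴.

Scores come from max-over-time or last-value decoding of the readout traces;
the loss is cross-entropy plus three penalties that keep the model inside
substrate capabilities — hidden firing rate (mean squared per-neuron count),
readout saturation (squared excursion beyond the ADC bound), and weight
range (squared excursion beyond the representable range). The penalty
*targets* are dictated by the hardware; their quadratic forms are this
package's choice. Adam (defaults lr 10⁻³, betas 0.9/0.999) with exponential
or halving learning-rate schedules, hidden-spike dropout (spikes withheld
from the downstream layer, no rescaling, so expected downstream drive scales
by $1-p$), early stopping on validation accuracy, and a best-on-validation
checkpoint complete the loop. All randomness fans out from named sub-seeds
(`derive_seed()`), making training bitwise reproducible; metrics can be
averaged over a seed set.

Weight initialization is fluctuation-driven: $N(0, (8/\sqrt{fan\_in})^2)$ by
default. TTFS input is sparse — a handful of informative early spikes per
sample — and a smaller scale leaves hidden units silent, the readout flat,
and the surrogate gradient with nothing to route; the default makes hidden
units active at initialization, which is what gets gradient flowing.

With `backend = "constrained"` the forward pass quantizes weights,
bandwidth-limits the input events and clips readout traces, while the
backward pass runs through the idealized dynamics with the recorded forward
observables substituted (straight-through). `backend = "mixed"` constrains
only selected layers, reproducing mixed hardware/software execution. The
fit's lattice kernel computes identical dynamics to the event-driven
executor — the partition-invariance and instance-equivalence tests pin the
two together — so training through it is training through the (emulated)
substrate without re-serializing events every epoch.

## The synthetic task

`generate_synthetic_images()` produces the package's self-contained fixture:
small grayscale images whose class is a bright 2 × 2 blob at a
class-specific location with disjoint supports, plus low background noise.
After TTFS encoding the classes are separable by first-spike times by
construction. It emulates exactly the property the training loop needs
(latency-coded, linearly separable classes at realistic event sparsity) and
none of the properties of real image data — no intra-class variability in
shape, no correlated clutter, no label noise. A model reaching high accuracy
here demonstrates that encoding, emulation, gradients and optimization
compose correctly; it says nothing about accuracy on natural benchmarks,
which is why the full-scale presets exist separately and their published
accuracies are documented, not asserted.

The packaged presets (`snnpart_preset("mnist")`, `snnpart_preset("eurosat")`)
reproduce the full-scale topologies and training settings: 784→256→10 with
linear encoding over 30 µs, max-over-time decoding, 15 % dropout and
exponential decay; and 12288→484(sparse)→128→10 with current-driven encoding
over 64 µs, last-value decoding, rate halving after epochs {10,…,60} and
patience 25. They plan to 5 and 10 sequential runs respectively. Running
them at full scale requires the datasets (downloads) and hours of training;
augmentation settings (±25° rotations at 50 %, flips) ship as declared
config for those runs.

## Numerical choices and problem sizes

* $\delta t$ defaults to 0.5 µs; windows of 30 µs (linear encoding) and
  64 µs (current encoding) give 60 and 128 bins.
* Hyperparameters whose published values are not available (Adam betas,
  initial rate, $\beta$, refractory time) are configurable defaults, not
  claims.
* The test suite exercises: 20 random feed-forward networks (2–4 layers,
  ≤ 64 neurons/layer, 2 samples) for partition invariance; 1000 random
  parameter draws for encoder fidelity; a 4→3→2 toy for gradient checking;
  and a 360-sample, 3-class synthetic task (300 train / 60 test, 24 hidden
  units, ≤ 50 epochs) for end-to-end learning — sizes chosen to exercise
  every code path at interactive runtimes.

## Limitations

Only current-based synapses and single-compartment LIF/LI dynamics are
modeled — no conductance synapses, adaptation/exponential terms, multi-
compartment neurons, plasticity, or analog parameter mismatch. Instances
run sequentially; real-time concurrent co-execution and inter-chip links
are not emulated. Partitioning is manual or planner-derived per layer;
automated graph partitioning is not attempted. Traces and weights serialize
to plain CSV tables; events to CSV with microsecond decimals over a
half-open window.
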