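# Full-scale land-cover preset: 64x64x3 inputs read through 3x3x3 stride-3
# receptive fields (484 first-layer neurons with 27 inputs each), a dense
# 128-unit second hidden layer (four combined circuits per neuron for the
# 484 fan-in), and a 10-class leaky-integrator readout. The first hidden
# layer is run in 8 parts to lower per-run input event rates, giving ten
# sequential single-chip runs in total.
name: eurosat
seed: 1
input:
  shape: [64, 64, 3]
  receptive_field:
    kernel: [3, 3, 3]
    stride: 3
layers:
  - name: hidden1
    size: 484
    type: lif
    parts: 8
    connectivity: receptive_field
  - name: hidden2
    size: 128
    type: lif
  - name: readout
    size: 10
    type: li
encoder:
  scheme: lif_current
  T: 64
  dt: 0.5
  x_min_bias: 0.05
  tau_en: 10
  theta_en: 1
  sigma_in: 0.01
training:
  epochs: 500
  batch_size: 64
  lr: 1.0e-3
  lr_schedule: halving
  halve_at: [10, 20, 30, 40, 50, 60]
  patience: 25
  decoding: last_value
augment:
  hflip_p: 0.5
  vflip_p: 0.5
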