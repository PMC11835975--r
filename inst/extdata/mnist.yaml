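# Full-scale handwritten-digit preset: 28x28 inputs, 256 LIF hidden units,
# 10 leaky-integrator readouts, linear TTFS encoding over a 30 us window.
# The planner maps this to five sequential single-chip runs (4 hidden parts
# + readout). Training at this scale needs the dataset downloaded separately;
# the packaged synthetic task covers desk-scale testing.
name: mnist
seed: 1
input:
  shape: [28, 28]
layers:
  - name: hidden
    size: 256
    type: lif
  - name: readout
    size: 10
    type: li
encoder:
  scheme: linear
  T: 30
  dt: 0.5
  x_min: 0
  x_max: 1
training:
  epochs: 100
  batch_size: 100
  dropout_p: 0.15
  lr: 1.0e-3
  lr_schedule: exponential
  lr_decay: 0.97
  decoding: max_over_time
  reg_rate: 1.0e-4
  reg_sat: 1.0e-4
  reg_weight: 1.0e-4
augment:
  rotation_deg: 25
  rotation_p: 0.5
  normalize: true
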