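# Integral-controller working point: CV2_X = 0.5, k_z = gamma_y,
# zbar/ybar = 1, gamma_y = 3*gamma_x, CV2_int = 0.2, CV2_Z = 0.1.
# Realized with geometric bursts at y_set = 100, zbar = z_c = 100
# (h = 1 gives f_i = 0.5). The sensor gamma is a nominal timescale only:
# the integrator decays at the constant zero-order propensity k_z*y_set.
topology: integral
disturbance:
  mode: bursty
  k: 0.6666666666666666
  gamma: 0.3333333333333333
  burst: {kind: shifted_geometric, mean: 10}
target:
  k: 10
  gamma: 1
  burst: {kind: shifted_geometric, mean: 20}
sensor:
  k: 1
  gamma: 1
  burst: {kind: shifted_geometric, mean: 10}
regulation:
  variant: zero_order_integral
  z_c: 100
  h: 1
  y_set: 100
design: zero_order
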