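# Proportional-controller working point: CV2_Z = 0.4, CV2_int = CV2_X = 0.2,
# gamma_z = 5*gamma_y = 15*gamma_x. Realized with geometric bursts at
# ybar = 100, zbar = z_c = 50, xbar = 100; gain swept via the Hill
# coefficient h at this fixed working point (h = 1 gives f_p = 0.5).
topology: proportional
disturbance:
  mode: bursty
  k: 1.6666666666666667
  gamma: 0.3333333333333333
  burst: {kind: shifted_geometric, mean: 20}
target:
  k: 10
  gamma: 1
  burst: {kind: shifted_geometric, mean: 20}
sensor:
  k: 0.125
  gamma: 5
  burst: {kind: shifted_geometric, mean: 20}
regulation:
  variant: hill_repression
  z_c: 50
  h: 1
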