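# Derivative-controller SSA validation circuit: k_y = 2, gamma_y = 0.2,
# <B_y> = 20, <B_z> = 1, k_z = gamma_z, h = 1, no external disturbance
# (x = xbar with probability one). Burst sizes shifted geometric.
# gamma_z (with k_z = gamma_z) is the swept knob: f_d = gamma_y/gamma_z.
# ybar = zbar = 200, CV2_int = 0.1, CV2_Z = 0.005.
topology: derivative
disturbance:
  mode: none
  xbar: 1
target:
  k: 2
  gamma: 0.2
  burst: {kind: shifted_geometric, mean: 20}
sensor:
  k: 1
  gamma: 1
  burst: {kind: shifted_geometric, mean: 1}
regulation:
  variant: ratio_derivative
  h: 1
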