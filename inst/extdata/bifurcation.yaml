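# Variant point of the bifurcation branching mode: receptor decay halved
# (delta_p = 0.8 instead of 1.6); all other values as in reference.yaml.
geometry:
  rc: 1.0
  Rc: 2.0
  we: 0.2
  h0: 2.0
  Lfar: 2.0
params:
  Df: 1.0
  Ds: 5.0
  Dp: 0.02
  D_cavity: 40.0
  nu_f: 5.0
  nu_s: 1600.0
  rho0: 0.6
  rho1: 3.5
  delta_f: 5.0
  delta_s: 0.2
  delta_p: 0.8
  delta_c: 1.0
  gamma: 1.0
  Kf: 1.0
  Ks: 1.0
  "n": 2
  nS: 1
  mP: 2
bc: open_farfield
hmax: 0.2
dt: 0.02
t_end: 400.0
tol: 1.0e-06
seed: 1
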