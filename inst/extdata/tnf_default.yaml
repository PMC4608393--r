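# Calibrated default parameter set, TNF variant. The receptor layer
# replaces TLR4/TRAF6 with a non-cooperative module (hill_n = 1), giving a
# shallower fraction-active response than LPS; the core IKK-IkBa-A20
# module is shared with the LPS variant.
variant: TNF
units: rates per minute; concentrations normalized (median total NF-kB = 1); ligand in ng/ml
rates:
  kb: 0.04
  kdb: 0.2
  kt: 0.026
  kdt: 0.1
  aT: 2.0
  hill_n: 1.0
  hill_K: 0.3
  ka: 0.12
  ki: 0.03
  kr: 0.012
  aI: 6.0
  c1: 0.02
  c3: 0.02
  c4: 0.35
  c5: 0.01
  d_ikba: 1.5
  kin_i: 0.1
  kex_i: 0.05
  a1: 20.0
  a1n: 20.0
  kin_n: 0.3
  kex_c: 0.35
  d_nic: 0.09
  c6: 0.001
  c1a: 0.015
  c3a: 0.02
  c4a: 0.06
  c5a: 0.008
  kdep0: 0.002
  kdep1: 0.0005
  kself: 0.0
population:
  sigma_tlr4: 1.1
  mu_tlr4: 0.0
  sigma_nfkb: 0.15
  mu_nfkb: 0.0
classifier:
  theta: 0.102
  smooth_window: 3
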