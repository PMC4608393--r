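# Calibrated default parameter set, LPS variant.
# Units: rates per minute; ligand in ng/ml; species in normalized
# copy-number units (median total NF-kB = 1, total IKK = TRAF6 = 1,
# receptor scale R relative to the population median).
variant: LPS
units: rates per minute; concentrations normalized (median total NF-kB = 1); ligand in ng/ml
rates:
  kb: 5.0e-05     # ligand-receptor binding, per (ng/ml) per min
  kdb: 0.008        # receptor complex turnover
  kt: 23.4         # TRAF6 activation by active receptor (x R)
  kdt: 5.0       # TRAF6 deactivation
  aT: 8.0         # A20 inhibition of TRAF6 (fold-boost of kdt per A20)
  hill_n: 4.0     # cooperativity of TRAF6 -> IKK activation (clustering)
  hill_K: 0.3     # half-saturation of TRAF6 -> IKK activation
  ka: 0.12         # IKK activation (x Hill multiplier)
  ki: 0.03        # IKK inactivation
  kr: 0.012       # IKK recycling (inactive -> neutral)
  aI: 6.0         # A20 boost of IKK inactivation
  c1: 0.02        # IkBa transcription per nuclear NF-kB
  c3: 0.02        # IkBa mRNA degradation
  c4: 0.35         # IkBa translation
  c5: 0.01       # free IkBa degradation (basal)
  d_ikba: 1.5     # IKKa-mediated degradation of free IkBa
  kin_i: 0.1     # IkBa nuclear import
  kex_i: 0.05     # IkBa nuclear export
  a1: 20.0        # NF-kB:IkBa association, cytoplasm
  a1n: 20.0       # NF-kB:IkBa association, nucleus
  kin_n: 0.3      # free NF-kB nuclear import
  kex_c: 0.35      # NF-kB:IkBa complex nuclear export
  d_nic: 0.09      # IKKa-mediated IkBa degradation in complex (frees NF-kB)
  c6: 0.001      # basal complex turnover
  c1a: 0.015       # A20 transcription per nuclear NF-kB
  c3a: 0.02       # A20 mRNA degradation
  c4a: 0.06        # A20 translation
  c5a: 0.008      # A20 degradation
  kdep0: 0.00325    # sealed-chamber ligand depletion, chamber-level
  kdep1: 0.0013   # sealed-chamber ligand depletion, per receptor scale R
  kself: 100.0      # autocatalytic TRAF6/Myddosome lattice self-assembly
population:
  sigma_tlr4: 0.985
  mu_tlr4: 0.0
  sigma_nfkb: 0.15
  mu_nfkb: 0.0
classifier:
  theta: 0.1378
  smooth_window: 3
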