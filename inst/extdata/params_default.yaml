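unk: unk
level_boundaries:
- 60
- 70
- 80
- 90
p_match_a:
  '0': 0.0
  '1': 0.45
  '2': 0.6
  '3': 0.72
  '4': 0.82
  '5': 0.9
p_a:
  ala: 0.02936170212766
  arg: 0.009787234042553
  asn: 0.02936170212766
  asp: 0.02936170212766
  cys: 0.009787234042553
  gln: 0.02936170212766
  glu: 0.02936170212766
  gly: 0.02936170212766
  his: 0.009787234042553
  ile: 0.02936170212766
  leu: 0.02936170212766
  lys: 0.02936170212766
  met: 0.009787234042553
  phe: 0.02936170212766
  pro: 0.02936170212766
  ser: 0.02936170212766
  thr: 0.02936170212766
  trp: 0.009787234042553
  tyr: 0.02936170212766
  val: 0.02936170212766
  orn: 0.02936170212766
  dab: 0.02936170212766
  dap: 0.009787234042553
  hpg: 0.02936170212766
  dhpg: 0.009787234042553
  pgl: 0.009787234042553
  bht: 0.009787234042553
  hty: 0.009787234042553
  hse: 0.009787234042553
  pip: 0.009787234042553
  hyp: 0.009787234042553
  mpro: 0.009787234042553
  aad: 0.009787234042553
  abu: 0.009787234042553
  aib: 0.009787234042553
  dhb: 0.009787234042553
  sal: 0.009787234042553
  kyn: 0.009787234042553
  cit: 0.009787234042553
  cap: 0.009787234042553
  end: 0.009787234042553
  ival: 0.009787234042553
  nva: 0.009787234042553
  nle: 0.009787234042553
  bala: 0.009787234042553
  blys: 0.009787234042553
  ahp: 0.009787234042553
  choi: 0.009787234042553
  adda: 0.009787234042553
  dha: 0.009787234042553
  dhab: 0.009787234042553
  hleu: 0.009787234042553
  hasn: 0.009787234042553
  horn: 0.009787234042553
  allothr: 0.009787234042553
  alloile: 0.009787234042553
  cysa: 0.009787234042553
  3mglu: 0.009787234042553
  unk: 0.08
p_m:
  '-1': 0.82
  '1': 0.18
p_e:
  '-1': 0.62
  '1': 0.38
p_match_m:
  '-1': 0.68
  '1': 0.12
p_mismatch_m:
  '-1': 0.14
  '1': 0.06
p_match_e:
  '-1': 0.47
  '1': 0.3
p_mismatch_e:
  '-1': 0.16
  '1': 0.07
p_insertion: 0.05
p_deletion: 0.04

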