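# example cohort spec for `usefactor generate`
mix:
  3D-CRT: 0.3
  IMRT: 0.2
  VMAT: 0.5
site_mix:
  breast: 0.3
  pelvis: 0.3
  other: 0.4
n_plans: 10
seed: 7
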