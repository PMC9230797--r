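# Tegoprazan + M1 coupled PBPK/PD model configuration (model-final values)
compound:
  mw: 387.38
  logp: 2.323
  pka: 5.1
  bp: 0.792
  fu: 0.087
  papp_caco2: 1.253e-05
  peff: 1.0e-04
  vss_target: 1.0
  clint_cyp:
    CYP3A4: 1.920
    CYP2C19: 0.710
    CYP2C8: 0.060
    CYP2C9: 0.140
    CYP2D6: 0.020
    CYP2E1: 0.030
  clint_hlm_additional: 15.96
  biliary_clint: 1.29
  cl_renal: 1.1
  cl_additional: 1.43
metabolite:
  mw: 373.36
  logp: 2.1
  pka: 5.35
  bp: 1.116
  fu: 0.257
  vss: 1.72
  k_in_sac: 40
  k_out_sac: 7.76
  v_sac: 1.23
  clint_hlm: 2.353
  clint_hlc: 3.15
  cl_renal: 1.1
  cl_additional: 1.44
formulation:
  dose_mg: 100
  particle_radius_um: 30
  particle_density: 1.2
  diffusion_coeff: 9.0e-06
  supersaturation_ratio: 10
  precipitation_rate: 4
pd:
  emax: 6.0
  ec50: 10
  gamma: 1.2
  k_in: 0.2
  k_out: 0.2
  mode: reduced
baseline:
  a0: 1.49
simulation:
  seed: 20220618
  n_subjects: 100
  n_trials: 10
  scenario: single_100
  feedback: true
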