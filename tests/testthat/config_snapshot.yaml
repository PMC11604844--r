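seed: 1
output_dir: '.'
fov_cm: 40.0
sequence:
  te_ms:
  - 0.57
  - 1.27
  - 1.97
  - 2.67
  tr_ms: 15.0
  flip_dissolved_deg: 22.0
  flip_gas_deg: 0.22
  n_dummy: 20
  bandwidth_hz: 31250.0
resonances:
  compartments:
  - gas
  - membrane
  - rbc
  delta_ppm:
  - 0.0
  - 197.699999999999989
  - 217.199999999999989
  reference_mhz: 17.66
  t2star_ms:
  - 20.0
  - 2.0
  - 2.0
trajectory:
  n_spokes: 934
  samples_per_spoke: 32
  spoke_style: center_out
  direction_method: phyllotaxis
phantom:
  matrix: 32
  rbc_to_m: 0.41
  m_to_gas: 0.0098
  texture_amp: 0.08
  defects: []
simulation:
  noise_sigma: auto
  target_rbc_snr: 9.199999999999999
  depolarization: 'off'
  depolarization_deg: 7.5
  t1_decay_s: .na.real
gridding:
  oversampling: 1.2
  kernel_width: 8
  matrix: 32
  dcf_mode: analytic_r2
cs:
  lambda1: 0.003
  lambda2: 0.0003
  max_iter: 40
  admm_rho: 1.0
  cg_iter: 8
  tol: 0.0001
  normalize_data: yes
  data_term: squared
  oversampling: 1.5
  kernel_width: 5
undersampling:
  af: 2.0
  mode: first_n
metrics:
  noise_slices: 3
  nmae_normalizer: mean
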