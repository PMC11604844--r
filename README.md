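# xecs — compressed-sensing reconstruction for dissolved-phase ¹²⁹Xe gas-exchange MRI

Hyperpolarized ¹²⁹Xe dissolved-phase lung MRI quantifies pulmonary gas
exchange from the signals of xenon in the alveolar airspace (Gas), the
alveolar membrane (M) and capillary red blood cells (RBC), read out as
the voxelwise ratio maps **RBC:M**, **RBC:Gas** and **M:Gas**. The
acquisition — a four-echo 3D radial spectroscopic sequence — suffers
from low SNR and a ~14 s breath-hold that many patients cannot
complete.

`xecs` is an R package for researchers developing and validating such
reconstructions. It implements the full chain on synthetic digital
lung phantoms:

* **Trajectory** — spiral-phyllotaxis 3D radial spokes, randomized
  acquisition order, retrospective undersampling (round-half-up spoke
  retention: 934 → 467/311/234 at AF 2/3/4).
* **Simulator** — four-echo k-space forward model with
  compartment-specific chemical shift and T2\*, per-spoke
  magnetization decay, and complex Gaussian noise calibrated to a
  target image-domain SNR.
* **Decomposition** — per-sample matrix inversion of
  `Φ[e,c] = exp(2πi Δf_c TE_e) · exp(−TE_e/T2*_c)` separating the
  three resonances in k-space; time-domain calibration-spectrum
  fitting.
* **Gridding** — Kaiser–Bessel convolution gridding (oversampling 1.2,
  kernel width 8) with r² density compensation, inverse FFT,
  deapodization.
* **Compressed sensing** — ADMM solution of

  `x = argmin_x ‖Ax − y‖₂² + λ₁‖x‖₁ + λ₂‖Tx‖₁,  A = PF`

  with image-domain sparsity (Ψ = I), anisotropic total variation `T`,
  and the published weights λ₁ = 0.003, λ₂ = 0.0003 applied after
  operator/data normalization.
* **Gas-exchange mapping** — flip-angle (and optional readout-decay)
  gas-signal correction, noise-threshold lung masking, guarded ratio
  maps.
* **Metrics** — SNR, NMAE, CV, pixelwise regression with adjusted R²,
  Bland–Altman, and the power law `NMAE = a · SNR^k`.

## Worked example

Simulate a small healthy-lung study (16³ grid, 250 spokes), reconstruct
it conventionally and with CS at acceleration factor 2, and compare:

```r
library(xecs)
cfg <- defaultRunConfig(seed = 42)
cfg$phantom$matrix <- cfg$gridding$matrix <- 16L
cfg$trajectory$n_spokes <- 250L
cfg$trajectory$samples_per_spoke <- 16L
cfg$metrics$noise_slices <- 2L

study <- simulateStudy(cfg)
study$kdata
#> KSpaceData: 4 echoes x 250 spokes x 16 samples (TEs 0.57/1.27/1.97/2.67 ms)

grd <- reconstructStudy(study$kdata, study$model, "gridding", af = 1, config = cfg)
gx  <- gasExchangeMaps(grd, seq = study$seq, model = study$model, config = cfg)
gx$mask
#> LungMask (membrane_gridding): 581 voxels (14.2%), threshold 0.002246
gx$maps
#> RatioMaps on 581 voxels: RBC:M 0.411, RBC:Gas 0.00403, M:Gas 0.00984 (excluded: rbc_m=0, rbc_gas=0, m_gas=0)

cs  <- reconstructStudy(study$kdata, study$model, "cs", af = 2, config = cfg)
gxc <- gasExchangeMaps(cs, mask = gx$mask, seq = study$seq,
                       model = study$model, config = cfg)
evaluateRecon(gxc$maps, gx$maps, cs, grd, mask = gx$mask, noiseSlices = 2)
#> MetricsReport
#>   SNR: test_gas=30.9, test_membrane=31.8, test_rbc=33.2, ref_gas=11.5, ref_membrane=10.3, ref_rbc=7.43
#>   NMAE (%): rbc_m=9.1, rbc_gas=9.33, m_gas=4.23
#>   voxels: 581
```

Reading the output: the noise-threshold mask recovers the phantom lung;
the mean ratios reproduce the phantom's healthy targets (RBC:M 0.41,
RBC:Gas 0.0040, M:Gas 0.0098); CS from half the spokes preserves those
means while raising RBC SNR from 7.4 to 33 by suppressing background
noise, at the price of ~9% voxelwise NMAE against the (noisy) gridding
reference.

A command-line front end with `simulate`, `recon`, `maps`, `evaluate`
and `sweep` subcommands is installed at `inst/cli/xecs` (see
`?runCli`); raw data travel in a self-describing directory container
(`writeRawData()`), volumes as NIfTI.

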