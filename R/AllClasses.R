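# Central S4 containers for the dissolved-phase 129Xe reconstruction
# pipeline. Validity methods enforce the geometric and physical
# invariants each object carries; user code should go through the
# exported constructors and accessors rather than slots.

#' RadialTrajectory: a 3D radial k-space trajectory
#'
#' Holds near-equidistant unit spoke directions, the temporal
#' acquisition order, and the per-spoke/per-sample k-space coordinates
#' in normalized units (Nyquist at +/- 0.5).
#'
#' @slot directions numeric matrix (nSpokes x 3) of unit vectors.
#' @slot order integer permutation; `order[i]` is the temporal
#'   acquisition index of spoke `i`.
#' @slot samplesPerSpoke integer, readout samples per spoke.
#' @slot kCoords numeric array (nSpokes x samplesPerSpoke x 3),
#'   normalized spatial frequency in `[-0.5, 0.5]`.
#' @slot spokeStyle `"center_out"` or `"full_diameter"`.
#' @exportClass RadialTrajectory
setClass("RadialTrajectory",
  representation(
    directions = "matrix",
    order = "integer",
    samplesPerSpoke = "integer",
    kCoords = "array",
    spokeStyle = "character"
  )
)

setValidity("RadialTrajectory", function(object) {
  msg <- character()
  d <- object@directions
  if (ncol(d) != 3L) msg <- c(msg, "directions must be an n x 3 matrix")
  nrm <- sqrt(rowSums(d^2))
  if (any(abs(nrm - 1) > 1e-12)) {
    msg <- c(msg, "all spoke directions must have unit norm (tol 1e-12)")
  }
  if (!identical(sort(object@order), seq_len(nrow(d)))) {
    msg <- c(msg, "order must be a permutation of spoke indices")
  }
  k <- object@kCoords
  if (!identical(dim(k), c(nrow(d), object@samplesPerSpoke, 3L))) {
    msg <- c(msg, "kCoords must be nSpokes x samplesPerSpoke x 3")
  } else {
    if (max(abs(k)) > 0.5 + 1e-12) {
      msg <- c(msg, "k-space coordinates must lie in [-0.5, 0.5]")
    }
    if (object@spokeStyle == "center_out" &&
        max(abs(k[, 1L, , drop = FALSE])) > 1e-12) {
      msg <- c(msg, "center_out spokes must start at the k-space origin")
    }
  }
  if (!object@spokeStyle %in% c("center_out", "full_diameter")) {
    msg <- c(msg, "spokeStyle must be 'center_out' or 'full_diameter'")
  }
  if (length(msg)) msg else TRUE
})

#' UndersamplingPlan: retrospective spoke selection
#'
#' @slot af numeric acceleration factor (>= 1).
#' @slot mode `"first_n"` (temporally first spokes) or `"random"`.
#' @slot seed integer seed used for random selection.
#' @slot retained sorted integer indices of retained spokes.
#' @slot nSpokes integer, total spokes in the parent trajectory.
#' @exportClass UndersamplingPlan
setClass("UndersamplingPlan",
  representation(
    af = "numeric",
    mode = "character",
    seed = "integer",
    retained = "integer",
    nSpokes = "integer"
  )
)

setValidity("UndersamplingPlan", function(object) {
  msg <- character()
  if (object@af < 1) msg <- c(msg, "af must be >= 1")
  expected <- floor(object@nSpokes / object@af + 0.5)
  if (length(object@retained) != expected) {
    msg <- c(msg, sprintf(
      "retained count %d does not match round-half-up(S/af) = %d",
      length(object@retained), expected
    ))
  }
  if (anyDuplicated(object@retained)) {
    msg <- c(msg, "retained spoke indices must be unique")
  }
  if (length(object@retained) &&
      (min(object@retained) < 1L || max(object@retained) > object@nSpokes)) {
    msg <- c(msg, "retained spoke indices out of range")
  }
  if (is.unsorted(object@retained)) {
    msg <- c(msg, "retained spoke indices must be sorted")
  }
  if (length(msg)) msg else TRUE
})

#' ResonanceModel: chemical shift and T2* per 129Xe compartment
#'
#' Frequency offsets are relative to the gaseous-phase resonance
#' (gas = 0 Hz by convention).
#'
#' @slot compartments character, compartment names.
#' @slot deltaFHz named numeric, frequency offset (Hz).
#' @slot t2starMs named numeric, apparent transverse decay (ms).
#' @exportClass ResonanceModel
setClass("ResonanceModel",
  representation(
    compartments = "character",
    deltaFHz = "numeric",
    t2starMs = "numeric"
  )
)

setValidity("ResonanceModel", function(object) {
  msg <- character()
  cp <- object@compartments
  if (!all(cp %in% names(object@deltaFHz)) ||
      !all(cp %in% names(object@t2starMs))) {
    msg <- c(msg, "deltaFHz and t2starMs must be named for every compartment")
  } else {
    if (any(object@t2starMs[cp] <= 0)) msg <- c(msg, "t2starMs must be > 0")
    if ("gas" %in% cp && abs(object@deltaFHz[["gas"]]) > 1e-9) {
      msg <- c(msg, "gas frequency offset must be 0 by convention")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SequenceParams: multi-echo radial EPSI sequence timing
#'
#' Defaults follow a four-echo 3D radial spectroscopic acquisition:
#' TEs 0.57/1.27/1.97/2.67 ms, TR 15 ms, flip angles 22 deg on the
#' dissolved phase and 0.22 deg on the gas phase, 20 dummy pulses,
#' 31.25 kHz receiver bandwidth.
#'
#' @slot teMs numeric, echo times (ms), strictly increasing.
#' @slot trMs numeric, repetition time (ms).
#' @slot flipDissolvedDeg,flipGasDeg numeric flip angles (degrees).
#' @slot nDummy integer, initial dummy RF pulses.
#' @slot bandwidthHz numeric receiver bandwidth (Hz).
#' @exportClass SequenceParams
setClass("SequenceParams",
  representation(
    teMs = "numeric",
    trMs = "numeric",
    flipDissolvedDeg = "numeric",
    flipGasDeg = "numeric",
    nDummy = "integer",
    bandwidthHz = "numeric"
  )
)

setValidity("SequenceParams", function(object) {
  msg <- character()
  if (any(object@teMs <= 0) || is.unsorted(object@teMs, strictly = TRUE)) {
    msg <- c(msg, "teMs must be positive and strictly increasing")
  }
  if (object@trMs <= 0) msg <- c(msg, "trMs must be > 0")
  if (object@bandwidthHz <= 0) msg <- c(msg, "bandwidthHz must be > 0")
  if (length(msg)) msg else TRUE
})

#' SimulationParams: measurement-noise and decay settings
#'
#' @slot noiseSigma numeric >= 0, per-component SD of the additive
#'   complex Gaussian measurement noise.
#' @slot depolarization `"off"` or `"per_spoke"` magnetization decay
#'   over the acquisition.
#' @slot depolarizationDeg numeric, effective per-excitation
#'   depolarization angle (degrees) of the shared hyperpolarized
#'   reservoir; the spoke acquired at temporal position n carries the
#'   factor `cos(depolarizationDeg)^(n-1)`.
#' @slot t1DecayS numeric, optional longitudinal decay constant in
#'   seconds (`NA` disables the T1 term).
#' @slot seed integer RNG seed for the noise realization.
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(
    noiseSigma = "numeric",
    depolarization = "character",
    depolarizationDeg = "numeric",
    t1DecayS = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (!object@depolarization %in% c("off", "per_spoke")) {
    msg <- c(msg, "depolarization must be 'off' or 'per_spoke'")
  }
  if (length(msg)) msg else TRUE
})

#' DigitalLungPhantom: per-compartment 129Xe source densities
#'
#' Two ellipsoidal lungs with smoothly varying gas density; membrane
#' and RBC densities are fixed multiples of the gas density inside the
#' lung (outside of any focal defects), so the ground-truth ratio maps
#' are known exactly.
#'
#' @slot matrixSize integer grid size per axis.
#' @slot rhoGas,rhoM,rhoRbc numeric 3D arrays of non-negative densities
#'   (arbitrary units), zero outside `lungMask`.
#' @slot lungMask logical 3D array.
#' @slot defects list of defect specs (center, radius, compartment,
#'   attenuation).
#' @slot rbcToM,mToGas numeric target density ratios.
#' @exportClass DigitalLungPhantom
setClass("DigitalLungPhantom",
  representation(
    matrixSize = "integer",
    rhoGas = "array",
    rhoM = "array",
    rhoRbc = "array",
    lungMask = "array",
    defects = "list",
    rbcToM = "numeric",
    mToGas = "numeric"
  )
)

setValidity("DigitalLungPhantom", function(object) {
  msg <- character()
  for (nm in c("rhoGas", "rhoM", "rhoRbc")) {
    rho <- slot(object, nm)
    if (any(rho < 0)) msg <- c(msg, paste(nm, "must be non-negative"))
    if (any(rho[!object@lungMask] != 0)) {
      msg <- c(msg, paste(nm, "must vanish outside the lung mask"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' KSpaceData: multi-echo radial k-space samples
#'
#' @slot data complex array (nEcho x nSpokes x samplesPerSpoke).
#' @slot teMs numeric echo times (ms).
#' @slot trajectory the [RadialTrajectory-class] the data live on.
#' @slot meta list of simulation/provenance metadata.
#' @exportClass KSpaceData
setClass("KSpaceData",
  representation(
    data = "array",
    teMs = "numeric",
    trajectory = "RadialTrajectory",
    meta = "list"
  )
)

setValidity("KSpaceData", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) {
    msg <- c(msg, "data must be a 3D array (echo x spoke x sample)")
  } else {
    if (d[1] != length(object@teMs)) {
      msg <- c(msg, "echo dimension must match length(teMs)")
    }
    if (d[2] != nrow(object@trajectory@directions) ||
        d[3] != object@trajectory@samplesPerSpoke) {
      msg <- c(msg, "spoke/sample dimensions must match the trajectory")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PhaseMatrix: echo-time evolution matrix for component separation
#'
#' Entries are `exp(2i*pi*deltaF_c*TE_e) * exp(-TE_e/T2*_c)`; the
#' per-sample least-squares inversion of this matrix separates the
#' spectral compartments in k-space.
#'
#' @slot entries complex matrix (nEcho x nCompartment).
#' @slot teMs numeric echo times used (ms).
#' @slot compartments character column names.
#' @slot conditionNumber numeric, 2-norm condition number.
#' @exportClass PhaseMatrix
setClass("PhaseMatrix",
  representation(
    entries = "matrix",
    teMs = "numeric",
    compartments = "character",
    conditionNumber = "numeric"
  )
)

setValidity("PhaseMatrix", function(object) {
  msg <- character()
  if (nrow(object@entries) != length(object@teMs)) {
    msg <- c(msg, "row count must match number of echo times")
  }
  if (ncol(object@entries) != length(object@compartments)) {
    msg <- c(msg, "column count must match number of compartments")
  }
  if (any(abs(object@entries) > 1 + 1e-9)) {
    msg <- c(msg, "entry magnitudes must be <= 1 (T2* attenuation)")
  }
  if (length(msg)) msg else TRUE
})

#' ComponentKSpace: separated per-compartment k-space channels
#'
#' @slot channels named list of complex matrices
#'   (nSpokes x samplesPerSpoke), one per compartment.
#' @slot residual numeric matrix of per-sample least-squares residual
#'   norms.
#' @slot trajectory the parent [RadialTrajectory-class].
#' @exportClass ComponentKSpace
setClass("ComponentKSpace",
  representation(
    channels = "list",
    residual = "matrix",
    trajectory = "RadialTrajectory"
  )
)

setValidity("ComponentKSpace", function(object) {
  msg <- character()
  dims <- lapply(object@channels, dim)
  if (length(unique(dims)) != 1L) {
    msg <- c(msg, "all channels must share one shape")
  }
  if (length(msg)) msg else TRUE
})

#' GriddingConfig: Kaiser-Bessel gridding reconstruction settings
#'
#' Defaults follow the conventional dissolved-phase protocol:
#' oversampling ratio 1.2, kernel width 8 grid cells, 32^3 output
#' matrix. The kernel shape parameter defaults to the Beatty
#' minimal-aliasing formula.
#'
#' @slot oversampling numeric >= 1.
#' @slot kernelWidth integer, even, >= 2 (grid cells).
#' @slot kbBeta numeric Kaiser-Bessel shape parameter.
#' @slot matrix integer output matrix size per axis (>= 8).
#' @slot dcfMode `"analytic_r2"` or `"voronoi"`.
#' @exportClass GriddingConfig
setClass("GriddingConfig",
  representation(
    oversampling = "numeric",
    kernelWidth = "integer",
    kbBeta = "numeric",
    matrix = "integer",
    dcfMode = "character"
  )
)

setValidity("GriddingConfig", function(object) {
  msg <- character()
  if (object@oversampling < 1) msg <- c(msg, "oversampling must be >= 1")
  if (object@kernelWidth < 2L || object@kernelWidth %% 2L != 0L) {
    msg <- c(msg, "kernelWidth must be even and >= 2")
  }
  if (object@matrix < 8L) msg <- c(msg, "matrix must be >= 8")
  if (!object@dcfMode %in% c("analytic_r2", "voronoi")) {
    msg <- c(msg, "dcfMode must be 'analytic_r2' or 'voronoi'")
  }
  if (length(msg)) msg else TRUE
})

#' EncodingModel: the non-uniform encoding operator A = PF
#'
#' Bundles the trajectory, the undersampling plan P, and the
#' Kaiser-Bessel interpolation settings used to evaluate the
#' non-uniform Fourier transform F and its exact adjoint.
#'
#' @slot trajectory a [RadialTrajectory-class].
#' @slot plan an [UndersamplingPlan-class] (the sampling operator P).
#' @slot matrix integer image matrix size per axis.
#' @slot oversampling,kernelWidth,kbBeta interpolation settings.
#' @exportClass EncodingModel
setClass("EncodingModel",
  representation(
    trajectory = "RadialTrajectory",
    plan = "UndersamplingPlan",
    matrix = "integer",
    oversampling = "numeric",
    kernelWidth = "integer",
    kbBeta = "numeric"
  )
)

#' CSConfig: compressed-sensing solver settings
#'
#' Regularization weights follow the optimized dissolved-phase values
#' lambda1 = 0.003 (image-domain L1) and lambda2 = 0.0003 (total
#' variation), applied after data normalization.
#'
#' @slot lambda1,lambda2 numeric >= 0 regularization weights.
#' @slot maxIter integer ADMM iterations.
#' @slot admmRho numeric ADMM penalty parameter.
#' @slot cgIter integer inner conjugate-gradient iterations.
#' @slot tol numeric relative-change stopping threshold.
#' @slot normalizeData logical, scale data so the adjoint image has
#'   unit maximum magnitude before applying lambda.
#' @slot dataTerm `"squared"` (solver practice) or `"unsquared"`
#'   (the printed L2 data term).
#' @exportClass CSConfig
setClass("CSConfig",
  representation(
    lambda1 = "numeric",
    lambda2 = "numeric",
    maxIter = "integer",
    admmRho = "numeric",
    cgIter = "integer",
    tol = "numeric",
    normalizeData = "logical",
    dataTerm = "character"
  )
)

setValidity("CSConfig", function(object) {
  msg <- character()
  if (object@lambda1 < 0 || object@lambda2 < 0) {
    msg <- c(msg, "lambda1 and lambda2 must be >= 0")
  }
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (object@admmRho <= 0) msg <- c(msg, "admmRho must be > 0")
  if (!object@dataTerm %in% c("squared", "unsquared")) {
    msg <- c(msg, "dataTerm must be 'squared' or 'unsquared'")
  }
  if (length(msg)) msg else TRUE
})

#' ComponentImages: reconstructed per-compartment volumes
#'
#' @slot gas,membrane,rbc complex 3D arrays on one grid.
#' @slot reconLabel `"gridding"` or `"cs"`.
#' @slot voxelMm numeric length-3 voxel dimensions (mm).
#' @exportClass ComponentImages
setClass("ComponentImages",
  representation(
    gas = "array",
    membrane = "array",
    rbc = "array",
    reconLabel = "character",
    voxelMm = "numeric"
  )
)

setValidity("ComponentImages", function(object) {
  msg <- character()
  if (!identical(dim(object@gas), dim(object@membrane)) ||
      !identical(dim(object@gas), dim(object@rbc))) {
    msg <- c(msg, "all component volumes must share one grid")
  }
  if (length(msg)) msg else TRUE
})

#' LungMask: noise-threshold lung segmentation
#'
#' @slot mask logical 3D array.
#' @slot thresholdValue numeric, the applied magnitude threshold.
#' @slot source `"membrane_gridding"`, `"membrane_cs"`, or `"truth"`.
#' @exportClass LungMask
setClass("LungMask",
  representation(
    mask = "array",
    thresholdValue = "numeric",
    source = "character"
  )
)

setValidity("LungMask", function(object) {
  msg <- character()
  if (!any(object@mask)) msg <- c(msg, "mask must be non-empty")
  if (mean(object@mask) >= 0.6) {
    msg <- c(msg, "mask fraction must be < 60% of the grid")
  }
  if (length(msg)) msg else TRUE
})

#' RatioMaps: voxelwise gas-exchange ratio maps
#'
#' Values are defined inside the lung mask; voxels dropped by the
#' low-denominator guard are `NA` and counted per map.
#'
#' @slot rbcM,rbcGas,mGas numeric 3D arrays (`NA` outside mask or
#'   excluded).
#' @slot mask logical 3D array the maps are defined on.
#' @slot exclusionCount named integer, voxels dropped per map.
#' @exportClass RatioMaps
setClass("RatioMaps",
  representation(
    rbcM = "array",
    rbcGas = "array",
    mGas = "array",
    mask = "array",
    exclusionCount = "integer"
  )
)

setValidity("RatioMaps", function(object) {
  msg <- character()
  for (nm in c("rbcM", "rbcGas", "mGas")) {
    v <- slot(object, nm)[object@mask]
    v <- v[!is.na(v)]
    if (length(v) && (any(!is.finite(v)) || any(v < 0))) {
      msg <- c(msg, paste(nm, "must be finite and >= 0 within the mask"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' PowerLawFit: NMAE ~ a * SNR^k fit
#'
#' @slot a numeric scaling constant.
#' @slot k numeric exponent (negative for decreasing error with SNR).
#' @slot rmse numeric residual RMSE (log space for the log-log fit).
#' @slot nPoints integer points used.
#' @slot method `"loglog"` or `"nls"`.
#' @exportClass PowerLawFit
setClass("PowerLawFit",
  representation(
    a = "numeric",
    k = "numeric",
    rmse = "numeric",
    nPoints = "integer",
    method = "character"
  )
)

#' MetricsReport: quantitative recon-comparison summary
#'
#' @slot snr named numeric, per component/recon SNR values.
#' @slot nmaePct named numeric, NMAE per ratio-map pair (%).
#' @slot cv list of named numeric CV values per recon.
#' @slot regression list of per-pair slope/intercept/adjusted R^2.
#' @slot blandAltman list of per-pair bias and limits of agreement.
#' @slot nVoxels integer voxels used.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    snr = "numeric",
    nmaePct = "numeric",
    cv = "list",
    regression = "list",
    blandAltman = "list",
    nVoxels = "integer"
  )
)
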