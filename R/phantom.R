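# Digital lung phantoms and the multi-echo radial k-space forward
# model (three spectral compartments, chemical shift, T2*, per-spoke
# magnetization decay, additive complex Gaussian noise).

#' Build a digital lung phantom
#'
#' Two ellipsoidal "lungs" with a smoothly varying gas density (radial
#' falloff, a gravity-like gradient, and low-frequency seeded texture).
#' Membrane and RBC densities are fixed multiples of the gas density,
#' so ground-truth ratio maps are known exactly: default targets follow
#' healthy-cohort gas-exchange values, RBC:M = 0.41 and M:Gas = 0.0098
#' (giving RBC:Gas = 0.0040). Spherical defects multiply the named
#' compartment's density by an attenuation factor.
#'
#' @param matrixSize grid size per axis (>= 8).
#' @param rbcToM target RBC-to-membrane density ratio (> 0).
#' @param mToGas target membrane-to-gas density ratio (> 0).
#' @param defects list of defects, each a list with elements `center`
#'   (voxel coordinates, length 3), `radius` (voxels), `compartment`
#'   (`"gas"`, `"membrane"`, `"rbc"`), `attenuation` (multiplier in
#'   `[0, 1]`).
#' @param seed seed for the texture field.
#' @param textureAmp amplitude of the low-frequency texture (fraction
#'   of the base density).
#' @return a [DigitalLungPhantom-class].
#' @examples
#' ph <- makeLungPhantom(32)
#' mean(phantomDensity(ph, "rbc")[maskArray(ph)] /
#'      phantomDensity(ph, "membrane")[maskArray(ph)])
#' @export
makeLungPhantom <- function(matrixSize = 32L, rbcToM = 0.41,
                            mToGas = 0.0098, defects = list(),
                            seed = 1L, textureAmp = 0.08) {
  .stopIf(matrixSize < 8, "matrixSize must be >= 8")
  .stopIf(rbcToM <= 0 || mToGas <= 0, "density ratios must be > 0")
  N <- as.integer(matrixSize)
  ax <- ((0:(N - 1)) - (N - 1) / 2) / (N / 2) # normalized [-1, 1)
  X <- array(rep(ax, times = N * N), c(N, N, N))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))

  ell <- function(cx) {
    ((X - cx) / 0.32)^2 + (Y / 0.55)^2 + ((Z + 0.05) / 0.75)^2
  }
  r2 <- pmin(ell(-0.45), ell(0.45))
  lungMask <- r2 < 1

  # smooth positive gas density: radial falloff, gravity gradient and
  # seeded low-frequency texture
  texture <- .withSeed(as.integer(seed), {
    tx <- array(0, c(N, N, N))
    for (i in 1:4) {
      f <- stats::runif(3, 0.5, 1.5)
      ph <- stats::runif(3, 0, 2 * pi)
      tx <- tx + cos(pi * f[1] * X + ph[1]) * cos(pi * f[2] * Y + ph[2]) *
        cos(pi * f[3] * Z + ph[3])
    }
    tx / 4
  })
  rhoGas <- (1 - 0.35 * pmin(r2, 1)) * (1 + 0.2 * Y) *
    (1 + textureAmp * texture)
  rhoGas[!lungMask] <- 0
  rhoGas[rhoGas < 0] <- 0

  rhoM <- mToGas * rhoGas
  rhoRbc <- rbcToM * rhoM

  for (d in defects) {
    ctr <- d$center
    .stopIf(any(ctr < 1) || any(ctr > N),
            "defect center outside the phantom grid")
    vox <- expand.grid(x = 1:N, y = 1:N, z = 1:N)
    inside <- (vox$x - ctr[1])^2 + (vox$y - ctr[2])^2 +
      (vox$z - ctr[3])^2 <= d$radius^2
    idx <- which(inside)
    att <- d$attenuation
    cp <- match.arg(d$compartment, c("gas", "membrane", "rbc"))
    if (cp == "gas") rhoGas[idx] <- rhoGas[idx] * att
    if (cp == "membrane") rhoM[idx] <- rhoM[idx] * att
    if (cp == "rbc") rhoRbc[idx] <- rhoRbc[idx] * att
  }

  new("DigitalLungPhantom",
    matrixSize = N, rhoGas = rhoGas, rhoM = rhoM, rhoRbc = rhoRbc,
    lungMask = lungMask, defects = defects, rbcToM = rbcToM,
    mToGas = mToGas
  )
}

# Direct (slow) evaluation of the DFT of a real density at arbitrary
# k-points; the oracle path for small grids.
.directDft <- function(rho, kmat) {
  N <- dim(rho)[1]
  idx <- which(rho != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(complex(length.out = nrow(kmat)))
  pos <- sweep(idx - 1L, 2L, N / 2) # p - c
  vals <- rho[idx]
  out <- complex(length.out = nrow(kmat))
  # chunk over k to bound memory
  chunk <- max(1L, floor(2e6 / nrow(idx)))
  for (s in seq(1L, nrow(kmat), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(kmat))
    phase <- tcrossprod(kmat[s:e, , drop = FALSE], pos) # (nk x nv)
    out[s:e] <- exp(-2i * pi * phase) %*% vals
  }
  out
}

# Per-spoke magnetization decay factors (temporal position via the
# acquisition order): cos(alpha_eff)^(pos-1), optionally times
# exp(-pos * TR / T1). The decay models depletion of the shared
# hyperpolarized reservoir, so it applies to every compartment
# (dissolved magnetization is replenished from the gas pool each TR).
.spokeDecay <- function(traj, seq, sim) {
  pos <- spokeOrder(traj)
  d <- cos(sim@depolarizationDeg * pi / 180)^(pos - 1)
  if (is.finite(sim@t1DecayS)) {
    d <- d * exp(-pos * seq@trMs / 1000 / sim@t1DecayS)
  }
  d
}

#' Simulate multi-echo radial k-space data from a phantom
#'
#' For echo `e` at k-point `j` the forward model is
#' `s_e(k_j) = d(spoke(j)) * sum_c DFT(w_c rho_c)(k_j) *
#' exp(2i*pi*deltaF_c*TE_e) * exp(-TE_e/T2*_c) + v`, with
#' `w_c = sin(flip_c)` the excitation weighting, `d` the per-spoke
#' reservoir-depletion factor (1 when depolarization is off), and `v`
#' i.i.d. complex Gaussian noise
#' of SD `noiseSigma` per component. The noise realization is
#' reproducible for a fixed seed.
#'
#' @param phantom a [DigitalLungPhantom-class].
#' @param traj a [RadialTrajectory-class].
#' @param model a [ResonanceModel-class] with compartments gas,
#'   membrane, rbc.
#' @param seq a [SequenceParams-class].
#' @param sim a [SimulationParams-class].
#' @param method off-grid evaluation: `"direct"` (slow exact DFT),
#'   `"nufft"` (oversampled FFT + Kaiser-Bessel interpolation), or
#'   `"auto"` (direct for grids up to 16^3).
#' @return a [KSpaceData-class].
#' @export
simulateKSpace <- function(phantom, traj, model = resonanceModel(),
                           seq = sequenceParams(),
                           sim = simulationParams(),
                           method = c("auto", "direct", "nufft")) {
  method <- match.arg(method)
  N <- phantom@matrixSize
  if (method == "auto") method <- if (N <= 16L) "direct" else "nufft"
  kmat <- .flatKCoords(traj)
  nS <- nSpokes(traj)
  nM <- samplesPerSpoke(traj)
  nE <- length(seq@teMs)

  wFlip <- c(
    gas = sin(seq@flipGasDeg * pi / 180),
    membrane = sin(seq@flipDissolvedDeg * pi / 180),
    rbc = sin(seq@flipDissolvedDeg * pi / 180)
  )
  rho <- list(
    gas = phantom@rhoGas, membrane = phantom@rhoM, rbc = phantom@rhoRbc
  )
  nufft <- if (method == "nufft") {
    .nufftPlan(N, oversampling = 2, kernelWidth = 8L)
  } else {
    NULL
  }
  base <- lapply(names(rho), function(cp) {
    r <- wFlip[[cp]] * rho[[cp]]
    if (method == "direct") {
      .directDft(r, kmat)
    } else {
      .nufftForwardRaw(array(as.complex(r), dim(r)), kmat, nufft)
    }
  })
  names(base) <- names(rho)

  decay <- if (sim@depolarization == "per_spoke") {
    rep(.spokeDecay(traj, seq, sim), times = nM) # spoke-major flatten
  } else {
    NULL
  }

  data <- array(0i, c(nE, nS, nM))
  for (e in seq_len(nE)) {
    te <- seq@teMs[e]
    acc <- complex(length.out = nS * nM)
    for (cp in names(base)) {
      fac <- exp(2i * pi * model@deltaFHz[[cp]] * te / 1000) *
        exp(-te / model@t2starMs[[cp]])
      contrib <- base[[cp]] * fac
      if (!is.null(decay)) contrib <- contrib * decay
      acc <- acc + contrib
    }
    data[e, , ] <- acc
  }

  if (sim@noiseSigma > 0) {
    noise <- .withSeed(sim@seed, {
      complex(
        real = rnorm(nE * nS * nM, 0, sim@noiseSigma),
        imaginary = rnorm(nE * nS * nM, 0, sim@noiseSigma)
      )
    })
    data <- data + array(noise, c(nE, nS, nM))
  }

  new("KSpaceData",
    data = data, teMs = seq@teMs, trajectory = traj,
    meta = list(
      noiseSigma = sim@noiseSigma, depolarization = sim@depolarization,
      t1DecayS = sim@t1DecayS, seed = sim@seed, method = method,
      flipWeights = wFlip
    )
  )
}

#' Simulate a calibration free-induction decay
#'
#' A sum of complex exponentials, one per compartment:
#' `s(t) = sum_c A_c exp(i phi_c) exp(2i*pi*deltaF_c t - t/T2*_c)`.
#' Used to exercise [fitCalibrationSpectra()].
#'
#' @param model a [ResonanceModel-class].
#' @param amplitudes named numeric amplitudes per compartment.
#' @param phases named numeric phases (radians), default 0.
#' @param dwellS dwell time between FID points (s).
#' @param n number of FID points.
#' @param noiseSigma complex Gaussian noise SD.
#' @param seed RNG seed for the noise.
#' @return complex vector of length `n`.
#' @export
simulateCalibrationFid <- function(model, amplitudes, phases = NULL,
                                   dwellS = 1e-4, n = 256L,
                                   noiseSigma = 0, seed = 1L) {
  cp <- model@compartments
  if (is.null(phases)) phases <- setNames(rep(0, length(cp)), cp)
  t <- (0:(n - 1)) * dwellS
  s <- complex(length.out = n)
  for (c1 in cp) {
    s <- s + amplitudes[[c1]] * exp(1i * phases[[c1]]) *
      exp(2i * pi * model@deltaFHz[[c1]] * t -
            t / (model@t2starMs[[c1]] / 1000))
  }
  if (noiseSigma > 0) {
    s <- s + .withSeed(as.integer(seed), {
      complex(real = rnorm(n, 0, noiseSigma),
              imaginary = rnorm(n, 0, noiseSigma))
    })
  }
  s
}
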