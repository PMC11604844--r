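# Gas-exchange mapping: gas-signal correction, noise-threshold lung
# masking, and RBC:M / RBC:Gas / M:Gas ratio maps.

#' Combine reconstructed component volumes
#'
#' @param gas,membrane,rbc complex 3D arrays on one grid.
#' @param reconLabel `"gridding"` or `"cs"`.
#' @param fovCm field of view (cm) used to derive the voxel size.
#' @return a [ComponentImages-class].
#' @export
componentImages <- function(gas, membrane, rbc,
                            reconLabel = c("gridding", "cs"),
                            fovCm = 40) {
  N <- dim(gas)[1]
  new("ComponentImages",
    gas = gas, membrane = membrane, rbc = rbc,
    reconLabel = match.arg(reconLabel),
    voxelMm = rep(10 * fovCm / N, 3L)
  )
}

# Mean T2* attenuation over a readout window [0, tau]:
# (T2/tau) * (1 - exp(-tau/T2)).
.meanReadoutAttenuation <- function(t2Ms, tauMs) {
  (t2Ms / tauMs) * (1 - exp(-tauMs / t2Ms))
}

#' Correct the gas signal for flip-angle and readout-decay differences
#'
#' The gas volume is multiplied by
#' `sin(flip_dissolved)/sin(flip_gas)` and, optionally, by the ratio of
#' mean T2* attenuation over the readout window (dissolved relative to
#' gas), so that dissolved-to-gas ratio maps are independent of the
#' flip angles and of the faster dissolved-phase decay during readout.
#' With the default window form the decay factor is
#' `[(T2d/tau)(1 - e^(-tau/T2d))] / [(T2g/tau)(1 - e^(-tau/T2g))]`;
#' `"point"` evaluates the attenuation at the window midpoint instead,
#' and `"none"` applies the flip-angle factor only.
#'
#' @param gas complex or numeric gas volume.
#' @param seq a [SequenceParams-class] (flip angles; the readout
#'   duration defaults to `samplesPerSpoke / bandwidth`).
#' @param model a [ResonanceModel-class] (T2* values; the dissolved
#'   value used is the mean of membrane and RBC).
#' @param t2starCorrection `"window"`, `"point"` or `"none"`.
#' @param readoutMs readout window length (ms); required unless
#'   `t2starCorrection = "none"` or `samplesPerSpoke` is given.
#' @param samplesPerSpoke convenience: derive `readoutMs` as
#'   `samplesPerSpoke / bandwidthHz`.
#' @return the corrected gas volume (same shape).
#' @examples
#' # flip factor alone: sin(22 deg)/sin(0.22 deg) ~ 97.56
#' correctGasSignal(array(1, c(2, 2, 2)), sequenceParams(),
#'                  resonanceModel(), t2starCorrection = "none")[1]
#' @export
correctGasSignal <- function(gas, seq = sequenceParams(),
                             model = resonanceModel(),
                             t2starCorrection = c("window", "point",
                                                  "none"),
                             readoutMs = NULL, samplesPerSpoke = NULL) {
  t2starCorrection <- match.arg(t2starCorrection)
  .stopIf(seq@flipGasDeg <= 0, "gas flip angle must be > 0")
  .stopIf(seq@flipDissolvedDeg <= 0, "dissolved flip angle must be > 0")
  fac <- sin(seq@flipDissolvedDeg * pi / 180) /
    sin(seq@flipGasDeg * pi / 180)
  if (t2starCorrection != "none") {
    if (is.null(readoutMs)) {
      .stopIf(is.null(samplesPerSpoke),
              "readoutMs (or samplesPerSpoke) required for T2* correction")
      readoutMs <- 1000 * samplesPerSpoke / seq@bandwidthHz
    }
    t2d <- mean(model@t2starMs[c("membrane", "rbc")])
    t2g <- model@t2starMs[["gas"]]
    decay <- if (t2starCorrection == "window") {
      .meanReadoutAttenuation(t2d, readoutMs) /
        .meanReadoutAttenuation(t2g, readoutMs)
    } else {
      exp(-readoutMs / 2 / t2d) / exp(-readoutMs / 2 / t2g)
    }
    fac <- fac * decay
  }
  gas * fac
}

#' Lung mask from a noise threshold on the membrane image
#'
#' Threshold `mu_bg + k * sigma_bg` on the magnitude image, with
#' background statistics taken from the six outer slices (three from
#' each end of the slice axis). Connected components smaller than
#' `keepFraction` of the largest are discarded.
#'
#' @param membrane complex or numeric membrane volume (conventionally
#'   from gridding reconstruction).
#' @param k threshold in background SDs above the background mean.
#' @param nBgSlices background slices taken from each end of the third
#'   axis.
#' @param keepFraction retain components at least this fraction of the
#'   largest component's size.
#' @param source label recorded on the mask.
#' @return a [LungMask-class]; errors if thresholding empties the
#'   volume.
#' @export
makeMask <- function(membrane, k = 3, nBgSlices = 3L,
                     keepFraction = 0.5, source = "membrane_gridding") {
  mag <- abs(membrane)
  d <- dim(mag)
  .stopIf(max(mag) == 0, "membrane image is identically zero")
  bgIdx <- c(seq_len(nBgSlices), (d[3] - nBgSlices + 1):d[3])
  bg <- mag[, , bgIdx]
  thr <- mean(bg) + k * sd(bg)
  raw <- mag > thr
  .stopIf(!any(raw), "noise threshold %.4g removed every voxel", thr)
  labels <- cpp_label_components(as.logical(raw), d)
  sizes <- tabulate(labels)
  keep <- which(sizes >= keepFraction * max(sizes))
  mask <- array(labels %in% keep & raw, d)
  new("LungMask", mask = mask, thresholdValue = thr, source = source)
}

#' Lung mask from the phantom ground truth
#'
#' @param phantom a [DigitalLungPhantom-class].
#' @return a [LungMask-class] with source `"truth"`.
#' @export
truthMask <- function(phantom) {
  new("LungMask",
    mask = maskArray(phantom), thresholdValue = NA_real_,
    source = "truth"
  )
}

#' Compute gas-exchange ratio maps
#'
#' Voxelwise magnitude ratios RBC:M, RBC:Gas and M:Gas inside the lung
#' mask, after gas-signal correction ([correctGasSignal()]). Voxels
#' whose denominator falls below `eps` times the in-mask mean
#' denominator are excluded (set `NA`) and counted per map.
#'
#' @param components a [ComponentImages-class].
#' @param mask a [LungMask-class] on the same grid.
#' @param seq a [SequenceParams-class].
#' @param model a [ResonanceModel-class].
#' @param eps low-denominator guard as a fraction of the in-mask mean.
#' @param t2starCorrection passed to [correctGasSignal()]; `"none"`
#'   applies the flip-angle factor only.
#' @param readoutMs,samplesPerSpoke passed to [correctGasSignal()].
#' @return a [RatioMaps-class].
#' @export
computeRatioMaps <- function(components, mask, seq = sequenceParams(),
                             model = resonanceModel(), eps = 0.01,
                             t2starCorrection = "none",
                             readoutMs = NULL, samplesPerSpoke = NULL) {
  m <- maskArray(mask)
  .stopIf(!identical(dim(m), dim(components@gas)),
          "mask grid does not match the component images")
  gasC <- abs(correctGasSignal(
    components@gas, seq, model, t2starCorrection = t2starCorrection,
    readoutMs = readoutMs, samplesPerSpoke = samplesPerSpoke
  ))
  mem <- abs(components@membrane)
  rbc <- abs(components@rbc)

  ratio <- function(num, den) {
    guard <- eps * mean(den[m])
    out <- array(NA_real_, dim(num))
    ok <- m & den > guard
    out[ok] <- num[ok] / den[ok]
    list(map = out, excluded = sum(m) - sum(ok))
  }
  rm_ <- ratio(rbc, mem)
  rg_ <- ratio(rbc, gasC)
  mg_ <- ratio(mem, gasC)
  new("RatioMaps",
    rbcM = rm_$map, rbcGas = rg_$map, mGas = mg_$map, mask = m,
    exclusionCount = c(
      rbc_m = as.integer(rm_$excluded),
      rbc_gas = as.integer(rg_$excluded),
      m_gas = as.integer(mg_$excluded)
    )
  )
}
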