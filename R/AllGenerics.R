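# Generics and accessor methods. Slot access from user code should go
# through these.

#' Number of spokes in a trajectory-like object
#' @param x a RadialTrajectory, UndersamplingPlan or KSpaceData.
#' @return integer spoke count.
#' @export
setGeneric("nSpokes", function(x) standardGeneric("nSpokes"))

#' @rdname nSpokes
#' @export
setMethod("nSpokes", "RadialTrajectory", function(x) nrow(x@directions))

#' @rdname nSpokes
#' @export
setMethod("nSpokes", "UndersamplingPlan", function(x) x@nSpokes)

#' @rdname nSpokes
#' @export
setMethod("nSpokes", "KSpaceData", function(x) nSpokes(x@trajectory))

#' Spoke direction unit vectors
#' @param x a RadialTrajectory.
#' @return numeric matrix (nSpokes x 3).
#' @export
setGeneric("spokeDirections", function(x) standardGeneric("spokeDirections"))

#' @rdname spokeDirections
#' @export
setMethod("spokeDirections", "RadialTrajectory", function(x) x@directions)

#' Temporal acquisition order
#' @param x a RadialTrajectory.
#' @return integer permutation; element i is the temporal index of
#'   spoke i.
#' @export
setGeneric("spokeOrder", function(x) standardGeneric("spokeOrder"))

#' @rdname spokeOrder
#' @export
setMethod("spokeOrder", "RadialTrajectory", function(x) x@order)

#' k-space sample coordinates
#' @param x a RadialTrajectory.
#' @return numeric array (nSpokes x samplesPerSpoke x 3) in normalized
#'   units (Nyquist at +/- 0.5).
#' @export
setGeneric("kCoords", function(x) standardGeneric("kCoords"))

#' @rdname kCoords
#' @export
setMethod("kCoords", "RadialTrajectory", function(x) x@kCoords)

#' Samples per spoke
#' @param x a RadialTrajectory.
#' @return integer.
#' @export
setGeneric("samplesPerSpoke", function(x) standardGeneric("samplesPerSpoke"))

#' @rdname samplesPerSpoke
#' @export
setMethod("samplesPerSpoke", "RadialTrajectory", function(x) x@samplesPerSpoke)

#' Retained spoke indices of an undersampling plan
#' @param x an UndersamplingPlan.
#' @return sorted integer vector.
#' @export
setGeneric("retainedSpokes", function(x) standardGeneric("retainedSpokes"))

#' @rdname retainedSpokes
#' @export
setMethod("retainedSpokes", "UndersamplingPlan", function(x) x@retained)

#' Complex k-space data array
#' @param x a KSpaceData or ComponentKSpace.
#' @param compartment for ComponentKSpace, which channel to return.
#' @return complex array.
#' @export
setGeneric("kSpaceArray", function(x, compartment) {
  standardGeneric("kSpaceArray")
})

#' @rdname kSpaceArray
#' @export
setMethod("kSpaceArray", "KSpaceData", function(x, compartment) x@data)

#' @rdname kSpaceArray
#' @export
setMethod("kSpaceArray", "ComponentKSpace", function(x, compartment) {
  if (missing(compartment)) return(x@channels)
  x@channels[[compartment]]
})

#' Echo times (ms)
#' @param x a KSpaceData, SequenceParams or PhaseMatrix.
#' @return numeric vector of echo times in milliseconds.
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))

#' @rdname echoTimes
#' @export
setMethod("echoTimes", "KSpaceData", function(x) x@teMs)

#' @rdname echoTimes
#' @export
setMethod("echoTimes", "SequenceParams", function(x) x@teMs)

#' @rdname echoTimes
#' @export
setMethod("echoTimes", "PhaseMatrix", function(x) x@teMs)

#' Trajectory carried by a data object
#' @param x a KSpaceData or ComponentKSpace.
#' @return the RadialTrajectory.
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname trajectory
#' @export
setMethod("trajectory", "KSpaceData", function(x) x@trajectory)

#' @rdname trajectory
#' @export
setMethod("trajectory", "ComponentKSpace", function(x) x@trajectory)

#' Condition number of a phase matrix
#' @param x a PhaseMatrix.
#' @return numeric 2-norm condition number.
#' @export
setGeneric("conditionNumber", function(x) standardGeneric("conditionNumber"))

#' @rdname conditionNumber
#' @export
setMethod("conditionNumber", "PhaseMatrix", function(x) x@conditionNumber)

#' Complex entries of a phase matrix
#' @param x a PhaseMatrix.
#' @return complex matrix (nEcho x nCompartment).
#' @export
setGeneric("phaseEntries", function(x) standardGeneric("phaseEntries"))

#' @rdname phaseEntries
#' @export
setMethod("phaseEntries", "PhaseMatrix", function(x) x@entries)

#' Logical mask array
#' @param x a LungMask or DigitalLungPhantom.
#' @return logical 3D array.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname maskArray
#' @export
setMethod("maskArray", "LungMask", function(x) x@mask)

#' @rdname maskArray
#' @export
setMethod("maskArray", "DigitalLungPhantom", function(x) {
  array(as.logical(x@lungMask), dim(x@lungMask))
})

#' Per-compartment density of a phantom
#' @param x a DigitalLungPhantom.
#' @param compartment `"gas"`, `"membrane"` or `"rbc"`.
#' @return numeric 3D array.
#' @export
setGeneric("phantomDensity", function(x, compartment) {
  standardGeneric("phantomDensity")
})

#' @rdname phantomDensity
#' @export
setMethod("phantomDensity", "DigitalLungPhantom", function(x, compartment) {
  switch(match.arg(compartment, c("gas", "membrane", "rbc")),
    gas = x@rhoGas, membrane = x@rhoM, rbc = x@rhoRbc
  )
})

#' Reconstructed component volume
#' @param x a ComponentImages.
#' @param compartment `"gas"`, `"membrane"` or `"rbc"`.
#' @return complex 3D array.
#' @export
setGeneric("componentVolume", function(x, compartment) {
  standardGeneric("componentVolume")
})

#' @rdname componentVolume
#' @export
setMethod("componentVolume", "ComponentImages", function(x, compartment) {
  switch(match.arg(compartment, c("gas", "membrane", "rbc")),
    gas = x@gas, membrane = x@membrane, rbc = x@rbc
  )
})

#' Gas-exchange ratio map
#' @param x a RatioMaps object.
#' @param which `"rbc_m"`, `"rbc_gas"` or `"m_gas"`.
#' @return numeric 3D array (`NA` outside the mask).
#' @export
setGeneric("ratioMap", function(x, which) standardGeneric("ratioMap"))

#' @rdname ratioMap
#' @export
setMethod("ratioMap", "RatioMaps", function(x, which) {
  switch(match.arg(which, c("rbc_m", "rbc_gas", "m_gas")),
    rbc_m = x@rbcM, rbc_gas = x@rbcGas, m_gas = x@mGas
  )
})

#' Voxels dropped by the low-denominator guard
#' @param x a RatioMaps object.
#' @return named integer vector.
#' @export
setGeneric("exclusionCount", function(x) standardGeneric("exclusionCount"))

#' @rdname exclusionCount
#' @export
setMethod("exclusionCount", "RatioMaps", function(x) x@exclusionCount)

setMethod("show", "RadialTrajectory", function(object) {
  cat("RadialTrajectory:", nSpokes(object), "spokes x",
      object@samplesPerSpoke, "samples,", object@spokeStyle, "\n")
})

setMethod("show", "UndersamplingPlan", function(object) {
  cat(sprintf("UndersamplingPlan: AF %.3g, mode %s, %d/%d spokes retained\n",
              object@af, object@mode, length(object@retained),
              object@nSpokes))
})

setMethod("show", "KSpaceData", function(object) {
  d <- dim(object@data)
  cat(sprintf("KSpaceData: %d echoes x %d spokes x %d samples (TEs %s ms)\n",
              d[1], d[2], d[3], paste(object@teMs, collapse = "/")))
})

setMethod("show", "ResonanceModel", function(object) {
  cat("ResonanceModel:\n")
  for (cp in object@compartments) {
    cat(sprintf("  %-9s deltaF %8.1f Hz, T2* %5.2f ms\n", cp,
                object@deltaFHz[[cp]], object@t2starMs[[cp]]))
  }
})

setMethod("show", "PhaseMatrix", function(object) {
  cat(sprintf("PhaseMatrix: %d echoes x %d compartments, cond %.3g\n",
              nrow(object@entries), ncol(object@entries),
              object@conditionNumber))
})

setMethod("show", "DigitalLungPhantom", function(object) {
  cat(sprintf(
    "DigitalLungPhantom: %d^3 grid, lung fraction %.1f%%, RBC:M %.3g, M:Gas %.3g, %d defect(s)\n",
    object@matrixSize, 100 * mean(object@lungMask), object@rbcToM,
    object@mToGas, length(object@defects)
  ))
})

setMethod("show", "ComponentImages", function(object) {
  cat(sprintf("ComponentImages (%s): %s grid, voxel %s mm\n",
              object@reconLabel,
              paste(dim(object@gas), collapse = "x"),
              paste(signif(object@voxelMm, 3), collapse = "x")))
})

setMethod("show", "LungMask", function(object) {
  cat(sprintf("LungMask (%s): %d voxels (%.1f%%), threshold %.4g\n",
              object@source, sum(object@mask), 100 * mean(object@mask),
              object@thresholdValue))
})

setMethod("show", "RatioMaps", function(object) {
  mn <- function(a) mean(a[object@mask], na.rm = TRUE)
  cat(sprintf(
    "RatioMaps on %d voxels: RBC:M %.3g, RBC:Gas %.3g, M:Gas %.3g (excluded: %s)\n",
    sum(object@mask), mn(object@rbcM), mn(object@rbcGas), mn(object@mGas),
    paste(sprintf("%s=%d", names(object@exclusionCount),
                  object@exclusionCount), collapse = ", ")
  ))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: NMAE = %.4g * SNR^%.4g (rmse %.3g, n = %d, %s)\n",
              object@a, object@k, object@rmse, object@nPoints,
              object@method))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n  SNR:",
      paste(sprintf("%s=%.3g", names(object@snr), object@snr),
            collapse = ", "),
      "\n  NMAE (%):",
      paste(sprintf("%s=%.3g", names(object@nmaePct), object@nmaePct),
            collapse = ", "),
      "\n  voxels:", object@nVoxels, "\n")
})
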