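# Raw-data container: a self-describing directory bundle holding the
# multi-echo k-space, trajectory arrays, calibration FID and
# provenance. Layout (schema version 1):
#   meta.json            shapes, units, sequence metadata, provenance
#   kspace.bin           float64 little-endian, re/im interleaved,
#                        echo x spoke x sample (column-major)
#   directions.bin       float64 LE, nSpokes x 3 (column-major)
#   kcoords.bin          float64 LE, nSpokes x samples x 3
#   order.bin            int32 LE, temporal acquisition order
#   calibration_fid.bin  optional float64 LE re/im interleaved
# Field names follow ISMRMRD conventions where a counterpart exists
# (kspace data, trajectory, acquisition parameters).

.writeComplexBin <- function(x, path) {
  v <- as.vector(x)
  inter <- as.vector(rbind(Re(v), Im(v)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(inter, con, size = 8, endian = "little")
}

.readComplexBin <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = 2 * n, size = 8, endian = "little")
  complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
}

.writeDoubleBin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(as.numeric(x)), con, size = 8, endian = "little")
}

.readDoubleBin <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "double", n = n, size = 8, endian = "little")
}

#' Write a raw-data container
#'
#' Serializes a [KSpaceData-class] (plus optional calibration FID and
#' config) into a self-describing directory bundle; all array shapes
#' and units are recorded in `meta.json` together with a provenance
#' block (package version, seed, config hash).
#'
#' @param kdata a [KSpaceData-class].
#' @param dir output directory (created if needed).
#' @param config optional run-config list; stored alongside as
#'   `config.yaml` and hashed into the provenance block.
#' @param calibrationFid optional complex FID vector.
#' @param calibrationDwellS dwell time of the FID (s).
#' @param seed seed recorded in the provenance block.
#' @return `dir`, invisibly.
#' @export
writeRawData <- function(kdata, dir, config = NULL,
                         calibrationFid = NULL,
                         calibrationDwellS = NULL, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traj <- trajectory(kdata)
  d <- dim(kdata@data)
  meta <- list(
    schema = "xecs-rawdata-1",
    kspace = list(
      file = "kspace.bin", dtype = "complex128-interleaved-le",
      shape = d, dims = c("echo", "spoke", "sample"),
      order = "column-major", units = "arbitrary"
    ),
    trajectory = list(
      directions = list(file = "directions.bin", shape = c(d[2], 3L)),
      kcoords = list(
        file = "kcoords.bin", shape = c(d[2], d[3], 3L),
        units = "normalized (Nyquist 0.5)"
      ),
      order = list(file = "order.bin", dtype = "int32-le"),
      spoke_style = traj@spokeStyle
    ),
    acquisition = c(
      list(te_ms = kdata@teMs),
      kdata@meta[setdiff(names(kdata@meta), "flipWeights")]
    ),
    provenance = list(
      tool = "xecs", version = as.character(packageVersion("xecs")),
      seed = seed,
      config_hash = if (is.null(config)) NA_character_ else
        .configHash(config)
    )
  )
  if (!is.null(calibrationFid)) {
    meta$calibration <- list(
      file = "calibration_fid.bin", n = length(calibrationFid),
      dwell_s = calibrationDwellS
    )
    .writeComplexBin(calibrationFid, file.path(dir, "calibration_fid.bin"))
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(config)) {
    writeRunConfig(config, file.path(dir, "config.yaml"))
  }
  .writeComplexBin(kdata@data, file.path(dir, "kspace.bin"))
  .writeDoubleBin(spokeDirections(traj), file.path(dir, "directions.bin"))
  .writeDoubleBin(kCoords(traj), file.path(dir, "kcoords.bin"))
  con <- file(file.path(dir, "order.bin"), "wb")
  writeBin(spokeOrder(traj), con, size = 4, endian = "little")
  close(con)
  invisible(dir)
}

#' Read a raw-data container
#'
#' @param dir container directory written by [writeRawData()].
#' @return list with `kdata` ([KSpaceData-class]), `meta` (list),
#'   `calibrationFid` (complex or NULL), `config` (run-config or
#'   NULL).
#' @export
readRawData <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  .stopIf(!file.exists(metaPath), "not a raw-data container: %s", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  .stopIf(!identical(meta$schema, "xecs-rawdata-1"),
          "unsupported container schema: %s", meta$schema)
  d <- as.integer(meta$kspace$shape)
  data <- array(
    .readComplexBin(file.path(dir, meta$kspace$file), prod(d)), d
  )
  nS <- d[2]
  nM <- d[3]
  dirs <- matrix(
    .readDoubleBin(file.path(dir, "directions.bin"), nS * 3L), nS, 3L
  )
  k <- array(
    .readDoubleBin(file.path(dir, "kcoords.bin"), nS * nM * 3L),
    c(nS, nM, 3L)
  )
  con <- file(file.path(dir, "order.bin"), "rb")
  ord <- readBin(con, "integer", n = nS, size = 4, endian = "little")
  close(con)
  traj <- new("RadialTrajectory",
    directions = dirs, order = ord, samplesPerSpoke = nM,
    kCoords = k, spokeStyle = meta$trajectory$spoke_style
  )
  acq <- meta$acquisition
  kdata <- new("KSpaceData",
    data = data, teMs = as.numeric(acq$te_ms), trajectory = traj,
    meta = acq[setdiff(names(acq), "te_ms")]
  )
  fid <- NULL
  if (!is.null(meta$calibration)) {
    fid <- .readComplexBin(
      file.path(dir, meta$calibration$file), meta$calibration$n
    )
  }
  cfgPath <- file.path(dir, "config.yaml")
  config <- if (file.exists(cfgPath)) readRunConfig(cfgPath) else NULL
  list(kdata = kdata, meta = meta, calibrationFid = fid, config = config)
}

#' Write a volume as NIfTI
#'
#' Complex volumes are written as magnitude (with optional separate
#' real/imaginary files); the voxel size is derived from the field of
#' view.
#'
#' @param vol 3D array (complex or numeric).
#' @param path output path (`.nii` / `.nii.gz`).
#' @param fovCm field of view (cm).
#' @param writeComplex also write `_real`/`_imag` volumes for complex
#'   input.
#' @return the main path, invisibly.
#' @export
writeVolumeNifti <- function(vol, path, fovCm = 40,
                             writeComplex = FALSE) {
  vox <- 10 * fovCm / dim(vol)[1]
  wr <- function(arr, p) {
    img <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
    RNifti::pixdim(img) <- rep(vox, 3)
    RNifti::writeNifti(img, p)
  }
  if (is.complex(vol)) {
    wr(abs(vol), path)
    if (writeComplex) {
      stem <- sub("\\.nii(\\.gz)?$", "", path)
      ext <- sub(paste0("^", stem), "", path)
      wr(Re(vol), paste0(stem, "_real", ext))
      wr(Im(vol), paste0(stem, "_imag", ext))
    }
  } else {
    wr(vol, path)
  }
  invisible(path)
}

#' Write phantom compartments and mask as NIfTI
#'
#' @param phantom a [DigitalLungPhantom-class].
#' @param dir output directory.
#' @param fovCm field of view (cm).
#' @return `dir`, invisibly.
#' @export
writePhantomNifti <- function(phantom, dir, fovCm = 40) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolumeNifti(phantom@rhoGas, file.path(dir, "rho_gas.nii.gz"), fovCm)
  writeVolumeNifti(phantom@rhoM, file.path(dir, "rho_membrane.nii.gz"),
                   fovCm)
  writeVolumeNifti(phantom@rhoRbc, file.path(dir, "rho_rbc.nii.gz"), fovCm)
  writeVolumeNifti(phantom@lungMask + 0, file.path(dir, "lung_mask.nii.gz"),
                   fovCm)
  invisible(dir)
}
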