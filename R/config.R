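# Run configuration: a single YAML file holding every protocol and
# reconstruction parameter, serializable with an exact round trip.

#' Default run configuration
#'
#' Nested list of every pipeline parameter with the standard protocol
#' defaults: TR 15 ms, TEs 0.57/1.27/1.97/2.67 ms, flips 22/0.22 deg,
#' 31.25 kHz bandwidth, 934 spokes, 32^3 matrix, 40 cm FOV; gridding
#' (oversampling 1.2, kernel width 8); CS (lambda1 0.003, lambda2
#' 0.0003); healthy-lung phantom ratios RBC:M 0.41, M:Gas 0.0098.
#'
#' Resonance offsets may be given in Hz (`delta_f_hz`) or in ppm with
#' `reference_mhz` (`delta_ppm`); Hz is canonical internally.
#'
#' @param seed integer seed recorded in the config.
#' @return a named list (class `xecsRunConfig`).
#' @export
defaultRunConfig <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    output_dir = ".",
    fov_cm = 40,
    sequence = list(
      te_ms = c(0.57, 1.27, 1.97, 2.67), tr_ms = 15,
      flip_dissolved_deg = 22, flip_gas_deg = 0.22, n_dummy = 20L,
      bandwidth_hz = 31250
    ),
    resonances = list(
      compartments = c("gas", "membrane", "rbc"),
      delta_ppm = c(0, 197.7, 217.2),
      reference_mhz = 17.66,
      t2star_ms = c(20, 2, 2)
    ),
    trajectory = list(
      n_spokes = 934L, samples_per_spoke = 32L,
      spoke_style = "center_out", direction_method = "phyllotaxis"
    ),
    phantom = list(
      matrix = 32L, rbc_to_m = 0.41, m_to_gas = 0.0098,
      texture_amp = 0.08, defects = list()
    ),
    simulation = list(
      noise_sigma = "auto", target_rbc_snr = 9.2,
      depolarization = "off", depolarization_deg = 7.5,
      t1_decay_s = NA_real_
    ),
    gridding = list(
      oversampling = 1.2, kernel_width = 8L, matrix = 32L,
      dcf_mode = "analytic_r2"
    ),
    cs = list(
      lambda1 = 0.003, lambda2 = 0.0003, max_iter = 40L,
      admm_rho = 1, cg_iter = 8L, tol = 1e-4,
      normalize_data = TRUE, data_term = "squared",
      oversampling = 1.5, kernel_width = 5L
    ),
    undersampling = list(af = 2, mode = "first_n"),
    metrics = list(noise_slices = 3L, nmae_normalizer = "mean")
  )
  class(cfg) <- c("xecsRunConfig", "list")
  cfg
}

#' Write / read a run configuration (YAML)
#'
#' `readRunConfig(writeRunConfig(cfg, path))` reproduces `cfg`
#' exactly; unknown keys are rejected, and ppm resonance offsets are
#' preserved as given (conversion to Hz happens in
#' [configResonanceModel()]).
#'
#' @param config a run-config list.
#' @param path file path.
#' @return `writeRunConfig`: the path, invisibly; `readRunConfig`: the
#'   config list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  .stopIf(!file.exists(path), "config file not found: %s", path)
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop(sprintf("malformed config %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  ref <- defaultRunConfig()
  unknown <- setdiff(names(raw), names(ref))
  .stopIf(length(unknown) > 0, "unknown config keys: %s",
          paste(unknown, collapse = ", "))
  cfg <- modifyList(unclass(ref), raw)
  # unnamed list fields are replaced wholesale (modifyList merges by
  # name and would drop them)
  if (!is.null(raw$phantom$defects)) {
    cfg$phantom$defects <- lapply(raw$phantom$defects, function(d) {
      d$center <- as.numeric(unlist(d$center))
      d
    })
  }
  # integer-valued fields
  cfg$seed <- as.integer(cfg$seed)
  for (f in c("n_spokes", "samples_per_spoke")) {
    cfg$trajectory[[f]] <- as.integer(cfg$trajectory[[f]])
  }
  cfg$phantom$matrix <- as.integer(cfg$phantom$matrix)
  cfg$gridding$matrix <- as.integer(cfg$gridding$matrix)
  cfg$gridding$kernel_width <- as.integer(cfg$gridding$kernel_width)
  cfg$sequence$n_dummy <- as.integer(cfg$sequence$n_dummy)
  for (f in c("max_iter", "cg_iter", "kernel_width")) {
    cfg$cs[[f]] <- as.integer(cfg$cs[[f]])
  }
  cfg$metrics$noise_slices <- as.integer(cfg$metrics$noise_slices)
  class(cfg) <- c("xecsRunConfig", "list")
  cfg
}

#' Parameter objects from a run configuration
#'
#' Helpers turning config sections into the typed parameter objects
#' used by the pipeline.
#'
#' @param config a run-config list.
#' @return the corresponding parameter object.
#' @export
configSequenceParams <- function(config) {
  s <- config$sequence
  sequenceParams(
    teMs = s$te_ms, trMs = s$tr_ms,
    flipDissolvedDeg = s$flip_dissolved_deg,
    flipGasDeg = s$flip_gas_deg, nDummy = s$n_dummy,
    bandwidthHz = s$bandwidth_hz
  )
}

#' @rdname configSequenceParams
#' @export
configResonanceModel <- function(config) {
  r <- config$resonances
  cp <- r$compartments
  if (!is.null(r$delta_f_hz)) {
    resonanceModel(
      deltaFHz = setNames(r$delta_f_hz, cp),
      t2starMs = setNames(r$t2star_ms, cp)
    )
  } else {
    resonanceModel(
      deltaPpm = setNames(r$delta_ppm, cp),
      t2starMs = setNames(r$t2star_ms, cp),
      referenceMHz = r$reference_mhz
    )
  }
}

#' @rdname configSequenceParams
#' @export
configGriddingConfig <- function(config) {
  g <- config$gridding
  griddingConfig(
    oversampling = g$oversampling, kernelWidth = g$kernel_width,
    matrix = g$matrix, dcfMode = g$dcf_mode
  )
}

#' @rdname configSequenceParams
#' @export
configCSConfig <- function(config) {
  cc <- config$cs
  csConfig(
    lambda1 = cc$lambda1, lambda2 = cc$lambda2, maxIter = cc$max_iter,
    admmRho = cc$admm_rho, cgIter = cc$cg_iter, tol = cc$tol,
    normalizeData = cc$normalize_data, dataTerm = cc$data_term
  )
}

# Stable hash of a config (provenance): md5 of its canonical YAML.
.configHash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeRunConfig(config, tf)
  unname(tools::md5sum(tf))
}
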