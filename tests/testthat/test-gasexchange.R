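test_that("gas-signal correction applies the flip-angle ratio", {
  gas <- array(1 + 0i, c(2, 2, 2))
  out <- correctGasSignal(gas, sequenceParams(), resonanceModel(),
                          t2starCorrection = "none")
  expect_equal(abs(out[1]), 97.561, tolerance = 1e-4)
  eq <- sequenceParams(flipDissolvedDeg = 10, flipGasDeg = 10)
  expect_equal(correctGasSignal(gas, eq, resonanceModel(),
                                t2starCorrection = "none"),
               gas, tolerance = 1e-14)
  bad <- sequenceParams()
  bad@flipGasDeg <- 0
  expect_error(correctGasSignal(gas, bad, resonanceModel(),
                                t2starCorrection = "none"), "flip")
})

test_that("readout-decay correction matches numeric quadrature", {
  gas <- array(1 + 0i, c(2, 2, 2))
  seqp <- sequenceParams()
  flipFac <- sin(22 * pi / 180) / sin(0.22 * pi / 180)
  tau <- 1.024 # ms, 32 samples at 31.25 kHz
  model <- resonanceModel(deltaPpm = c(gas = 0, membrane = 197.7,
                                       rbc = 217.2),
                          t2starMs = c(gas = 1e9, membrane = 2, rbc = 2))
  out <- correctGasSignal(gas, seqp, model, "window", readoutMs = tau)
  # oracle: mean attenuation of exp(-t/T2) over [0, tau] by quadrature
  quad <- integrate(function(t) exp(-t / 2), 0, tau)$value / tau
  expect_equal(abs(out[1]) / flipFac, quad, tolerance = 1e-6)

  # window length derived from bandwidth and samples per spoke
  out2 <- correctGasSignal(gas, seqp, model, "window",
                           samplesPerSpoke = 32)
  expect_equal(out2, out, tolerance = 1e-12)

  # midpoint ("point") variant
  outP <- correctGasSignal(gas, seqp, model, "point", readoutMs = tau)
  expect_equal(abs(outP[1]) / flipFac, exp(-tau / 2 / 2),
               tolerance = 1e-9)
  # equal T2* in both phases: decay factor cancels exactly
  same <- resonanceModel(t2starMs = c(gas = 2, membrane = 2, rbc = 2))
  outS <- correctGasSignal(gas, seqp, same, "window", readoutMs = tau)
  expect_equal(abs(outS[1]), flipFac, tolerance = 1e-12)
})

test_that("noise thresholding keeps almost nothing on a pure-noise volume", {
  noise <- randomComplexArray(rep(32, 3), seed = 9)
  mask <- makeMask(noise, k = 3)
  expect_lt(mean(maskArray(mask)), 0.01)
  expect_error(makeMask(array(0i, rep(8, 3))), "zero")
})

test_that("the membrane-derived mask recovers the phantom lung", {
  grd <- smallGridding()
  study <- smallStudy()
  m <- maskArray(grd$mask)
  truth <- maskArray(study$phantom)
  dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gt(dice, 0.9)
  expect_equal(grd$mask@source, "membrane_gridding")
  expect_true(grd$mask@thresholdValue > 0)
})

test_that("ratio maps are exact for identical compartments and guarded denominators", {
  vol <- randomComplexArray(rep(8, 3), seed = 2) + 5
  ci <- componentImages(vol, vol, vol, "gridding")
  mask <- new("LungMask", mask = array(c(rep(FALSE, 256), rep(TRUE, 128),
                                         rep(FALSE, 128)), rep(8, 3)),
              thresholdValue = 0, source = "truth")
  seqEq <- sequenceParams(flipDissolvedDeg = 5, flipGasDeg = 5)
  maps <- computeRatioMaps(ci, mask, seqEq, resonanceModel())
  inMask <- maskArray(mask)
  expect_true(all(abs(ratioMap(maps, "rbc_m")[inMask] - 1) < 1e-12))
  expect_true(all(abs(ratioMap(maps, "m_gas")[inMask] - 1) < 1e-12))
  expect_identical(unname(exclusionCount(maps)), c(0L, 0L, 0L))

  # a near-zero membrane voxel is excluded and counted
  mem2 <- vol
  low <- which(inMask)[1]
  mem2[low] <- 1e-9
  maps2 <- computeRatioMaps(componentImages(vol, mem2, vol, "gridding"),
                            mask, seqEq, resonanceModel())
  expect_identical(exclusionCount(maps2)[["rbc_m"]], 1L)
  expect_true(is.na(ratioMap(maps2, "rbc_m")[low]))
})

test_that("ratio maps are invariant to global complex scaling of the data", {
  study <- smallStudy()
  cfg <- study$config
  kd <- study$kdata
  kd2 <- kd
  kd2@data <- kd@data * (0.3 - 1.7i)
  img1 <- reconstructStudy(kd, study$model, "gridding", config = cfg)
  img2 <- reconstructStudy(kd2, study$model, "gridding", config = cfg)
  mask <- truthMask(study$phantom)
  m1 <- computeRatioMaps(img1, mask, study$seq, study$model)
  m2 <- computeRatioMaps(img2, mask, study$seq, study$model)
  expect_equal(ratioMap(m1, "rbc_m"), ratioMap(m2, "rbc_m"),
               tolerance = 1e-10)
  expect_equal(ratioMap(m1, "m_gas"), ratioMap(m2, "m_gas"),
               tolerance = 1e-10)
})

test_that("a focal RBC defect appears at its programmed depth", {
  def <- list(list(center = c(20, 32, 32), radius = 9,
                   compartment = "rbc", attenuation = 0.2))
  ph <- makeLungPhantom(64, defects = def, seed = 1)
  traj <- radialTrajectory(2400, 64, seed = 1)
  kd <- simulateKSpace(ph, traj)
  comp <- separateComponents(kd,
    buildPhaseMatrix(resonanceModel(), echoTimes(kd)))
  imgs <- lapply(comp@channels, function(ch) {
    gridReconstruct(ch, traj, griddingConfig(matrix = 64L))
  })
  ci <- componentImages(imgs$gas, imgs$membrane, imgs$rbc, "gridding")
  maps <- computeRatioMaps(ci, truthMask(ph))
  rm_ <- ratioMap(maps, "rbc_m")
  m <- maskArray(ph)
  idx <- which(array(TRUE, rep(64, 3)), arr.ind = TRUE)
  dist <- array(sqrt(rowSums(sweep(idx, 2, c(20, 32, 32))^2)), rep(64, 3))
  inside <- mean(rm_[m & dist <= 5], na.rm = TRUE)
  outside <- mean(rm_[m & dist > 12], na.rm = TRUE)
  expect_equal(inside / outside, 0.2, tolerance = 0.1)
})
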