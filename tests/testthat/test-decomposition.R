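test_that("phase matrix entries follow the shift/decay formula", {
  model <- resonanceModel()
  te <- c(0.57, 1.27, 1.97, 2.67)
  phi <- buildPhaseMatrix(model, te)
  expect_equal(dim(phaseEntries(phi)), c(4L, 3L))
  # spot-check an entry against the scalar formula
  e23 <- exp(2i * pi * model@deltaFHz[["rbc"]] * te[2] / 1000) *
    exp(-te[2] / model@t2starMs[["rbc"]])
  expect_equal(unname(phaseEntries(phi)[2, "rbc"]), unname(e23),
               tolerance = 1e-14)
  expect_true(all(abs(phaseEntries(phi)) <= 1 + 1e-12))

  # condition number matches an independent SVD of the entry matrix
  sv <- svd(phaseEntries(phi))$d
  expect_equal(conditionNumber(phi), max(sv) / min(sv), tolerance = 1e-12)

  # degenerate limit: no shifts, no decay -> matrix of ones, rank 1
  flat <- resonanceModel(deltaPpm = c(gas = 0, membrane = 0, rbc = 0),
                         t2starMs = c(gas = 1e12, membrane = 1e12,
                                      rbc = 1e12))
  phiFlat <- buildPhaseMatrix(flat, te)
  expect_equal(unname(phaseEntries(phiFlat)),
               matrix(1 + 0i, 4, 3), tolerance = 1e-9)

  # one echo, one compartment, TE = 1 ms, T2* = 2 ms -> |entry| = e^-0.5
  one <- resonanceModel(deltaFHz = c(gas = 0), t2starMs = c(gas = 2))
  expect_equal(unname(abs(phaseEntries(buildPhaseMatrix(one, 1))[1, 1])),
               exp(-0.5), tolerance = 1e-14)

  expect_error(buildPhaseMatrix(model, c(0.57, 1.27)), "echoes")
  bad <- model
  bad@t2starMs[["rbc"]] <- -1
  expect_error(buildPhaseMatrix(bad, te), "t2star")
})

test_that("separation recovers noiseless component k-space exactly", {
  ph <- makeLungPhantom(8, seed = 2)
  traj <- radialTrajectory(20, 8, seed = 3)
  seqp <- sequenceParams()
  model <- resonanceModel()
  kd <- simulateKSpace(ph, traj, model, seqp, method = "direct")
  comp <- separateComponents(kd, buildPhaseMatrix(model, seqp@teMs))
  kmat <- matrix(kCoords(traj), ncol = 3)
  w <- c(gas = sin(seqp@flipGasDeg * pi / 180),
         membrane = sin(seqp@flipDissolvedDeg * pi / 180),
         rbc = sin(seqp@flipDissolvedDeg * pi / 180))
  for (cp in c("gas", "membrane", "rbc")) {
    ref <- directDftOracle(w[[cp]] * phantomDensity(ph, cp), kmat)
    got <- as.vector(kSpaceArray(comp, cp))
    expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-8)
  }
  expect_lt(max(comp@residual), 1e-10 * max(abs(kSpaceArray(kd))))
})

test_that("separation is column-selective", {
  # data synthesized from the gas column only -> dissolved channels ~ 0
  traj <- radialTrajectory(10, 4, seed = 1)
  model <- resonanceModel()
  te <- c(0.57, 1.27, 1.97, 2.67)
  phi <- buildPhaseMatrix(model, te)
  gasOnly <- randomComplexArray(c(10, 4), seed = 8)
  data <- array(0i, c(4, 10, 4))
  for (e in 1:4) data[e, , ] <- phaseEntries(phi)[e, "gas"] * gasOnly
  kd <- new("KSpaceData", data = data, teMs = te, trajectory = traj,
            meta = list())
  comp <- separateComponents(kd, phi)
  gmax <- max(abs(kSpaceArray(comp, "gas")))
  expect_lt(max(abs(kSpaceArray(comp, "membrane"))), 1e-10 * gmax)
  expect_lt(max(abs(kSpaceArray(comp, "rbc"))), 1e-10 * gmax)
  expect_equal(kSpaceArray(comp, "gas"), gasOnly, tolerance = 1e-10)
})

test_that("separation noise amplification matches pseudoinverse row norms", {
  traj <- radialTrajectory(125, 8, seed = 1) # 1000 k-samples
  model <- resonanceModel()
  te <- c(0.57, 1.27, 1.97, 2.67)
  phi <- buildPhaseMatrix(model, te)
  sigma <- 0.7
  set.seed(42)
  noise <- array(complex(real = rnorm(4 * 1000, 0, sigma),
                         imaginary = rnorm(4 * 1000, 0, sigma)),
                 c(4, 125, 8))
  kd <- new("KSpaceData", data = noise, teMs = te, trajectory = traj,
            meta = list())
  comp <- separateComponents(kd, phi)
  amp <- noiseAmplification(phi)
  for (cp in c("gas", "membrane", "rbc")) {
    sdGot <- sd(c(Re(kSpaceArray(comp, cp)), Im(kSpaceArray(comp, cp))))
    # relative MC error of an SD from 2000 values ~ 1/sqrt(2*2000)
    expect_equal(sdGot, sigma * amp[[cp]], tolerance = 5 / sqrt(4000))
  }
})

test_that("pseudoinverse solution minimizes the per-sample residual", {
  model <- resonanceModel()
  phi <- buildPhaseMatrix(model, c(0.57, 1.27, 1.97, 2.67))
  set.seed(3)
  s <- complex(real = rnorm(4), imaginary = rnorm(4))
  rho <- xecs:::.pinv(phaseEntries(phi)) %*% s
  base <- sum(abs(phaseEntries(phi) %*% rho - s)^2)
  for (i in 1:20) {
    pert <- rho + 0.01 * complex(real = rnorm(3), imaginary = rnorm(3))
    expect_gte(sum(abs(phaseEntries(phi) %*% pert - s)^2), base)
  }
})

test_that("ill-conditioned phase matrices are rejected with diagnostics", {
  flat <- resonanceModel(deltaPpm = c(gas = 0, membrane = 0, rbc = 0),
                         t2starMs = c(gas = 1e12, membrane = 1e12,
                                      rbc = 1e12))
  phi <- buildPhaseMatrix(flat, c(0.57, 1.27, 1.97, 2.67))
  traj <- radialTrajectory(5, 4, seed = 1)
  kd <- new("KSpaceData", data = array(1 + 0i, c(4, 5, 4)),
            teMs = c(0.57, 1.27, 1.97, 2.67), trajectory = traj,
            meta = list())
  expect_error(separateComponents(kd, phi), "condition number")
})

test_that("calibration fitting recovers resonance parameters", {
  model <- resonanceModel()
  amps <- c(gas = 1, membrane = 0.4, rbc = 0.25)
  fid <- simulateCalibrationFid(model, amps, dwellS = 5e-5, n = 256)
  init <- resonanceModel(deltaPpm = c(gas = 0, membrane = 195, rbc = 220),
                         t2starMs = c(gas = 15, membrane = 2.5, rbc = 1.6))
  fit <- fitCalibrationSpectra(fid, 5e-5, init)
  expect_true(all(abs(fit$model@deltaFHz - model@deltaFHz) < 1))
  expect_true(all(abs(fit$model@t2starMs / model@t2starMs - 1) < 0.02))
  expect_equal(unname(abs(fit$amplitudes)), unname(amps),
               tolerance = 1e-3)

  # deterministic: identical runs give identical results
  fit2 <- fitCalibrationSpectra(fid, 5e-5, init)
  expect_identical(fit$model@deltaFHz, fit2$model@deltaFHz)

  # single peak: one-parameter family recovered to high precision
  one <- resonanceModel(deltaFHz = c(gas = 0), t2starMs = c(gas = 20))
  fid1 <- simulateCalibrationFid(one, c(gas = 2), dwellS = 1e-4, n = 128)
  f1 <- fitCalibrationSpectra(fid1, 1e-4, one)
  expect_equal(abs(f1$amplitudes[["gas"]]), 2, tolerance = 1e-6)
  expect_equal(f1$model@t2starMs[["gas"]], 20, tolerance = 1e-4)

  expect_error(fitCalibrationSpectra(fid[1:32], 5e-5, init), "64")
})
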