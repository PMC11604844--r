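test_that("phantom densities honor the configured compartment ratios", {
  ph <- makeLungPhantom(32, rbcToM = 0.41, mToGas = 0.0098, seed = 3)
  m <- maskArray(ph)
  frac <- mean(m)
  expect_gt(frac, 0.10)
  expect_lt(frac, 0.40)
  r <- phantomDensity(ph, "rbc")[m] / phantomDensity(ph, "membrane")[m]
  expect_true(all(abs(r - 0.41) < 1e-9))
  rg <- phantomDensity(ph, "membrane")[m] / phantomDensity(ph, "gas")[m]
  expect_true(all(abs(rg - 0.0098) < 1e-9))
  # densities vanish outside the lung
  expect_true(all(phantomDensity(ph, "gas")[!m] == 0))
})

test_that("phantom defects attenuate only the named compartment", {
  def <- list(list(center = c(16, 16, 16), radius = 3,
                   compartment = "rbc", attenuation = 0))
  ph <- makeLungPhantom(32, defects = def, seed = 3)
  idx <- which(array(TRUE, rep(32, 3)), arr.ind = TRUE)
  inside <- array(sqrt(rowSums(sweep(idx, 2, c(16, 16, 16))^2)) <= 3,
                  rep(32, 3))
  expect_true(all(phantomDensity(ph, "rbc")[inside] == 0))
  ref <- makeLungPhantom(32, seed = 3)
  expect_equal(phantomDensity(ph, "membrane"),
               phantomDensity(ref, "membrane"))
  expect_error(
    makeLungPhantom(32, defects = list(list(center = c(40, 1, 1),
      radius = 2, compartment = "rbc", attenuation = 0))),
    "outside"
  )
})

test_that("simulated k-space matches the direct DFT oracle", {
  # single active compartment, zero shift, effectively infinite T2*:
  # every echo must equal the DFT of the flip-weighted density
  ph <- makeLungPhantom(8, seed = 2)
  ph@rhoM[] <- 0
  ph@rhoRbc[] <- 0
  traj <- radialTrajectory(20, 8, seed = 3)
  model <- resonanceModel(deltaPpm = c(gas = 0, membrane = 0, rbc = 0),
                          t2starMs = c(gas = 1e12, membrane = 1e12,
                                       rbc = 1e12))
  seqp <- sequenceParams()
  kd <- simulateKSpace(ph, traj, model, seqp, method = "direct")
  wGas <- sin(seqp@flipGasDeg * pi / 180)
  ref <- directDftOracle(wGas * phantomDensity(ph, "gas"),
                         matrix(kCoords(traj), ncol = 3))
  for (e in 1:4) {
    got <- as.vector(kSpaceArray(kd)[e, , ])
    expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-10)
  }
})

test_that("simulator is linear and exactly zero for an empty phantom", {
  traj <- radialTrajectory(15, 8, seed = 1)
  ph1 <- makeLungPhantom(8, seed = 1)
  ph2 <- makeLungPhantom(8, seed = 9, rbcToM = 0.2, mToGas = 0.02)
  phSum <- ph1
  phSum@rhoGas <- ph1@rhoGas + ph2@rhoGas
  phSum@rhoM <- ph1@rhoM + ph2@rhoM
  phSum@rhoRbc <- ph1@rhoRbc + ph2@rhoRbc
  phSum@lungMask <- array(ph1@lungMask | ph2@lungMask, dim(ph1@lungMask))
  k1 <- simulateKSpace(ph1, traj, method = "direct")
  k2 <- simulateKSpace(ph2, traj, method = "direct")
  kSum <- simulateKSpace(phSum, traj, method = "direct")
  expect_equal(kSpaceArray(kSum), kSpaceArray(k1) + kSpaceArray(k2),
               tolerance = 1e-12)

  zero <- ph1
  zero@rhoGas[] <- 0
  zero@rhoM[] <- 0
  zero@rhoRbc[] <- 0
  kz <- simulateKSpace(zero, traj, method = "direct")
  expect_true(all(kSpaceArray(kz) == 0))
})

test_that("real densities give conjugate-symmetric spectra on full-diameter spokes", {
  ph <- makeLungPhantom(8, seed = 4)
  traj <- radialTrajectory(12, 9, spokeStyle = "full_diameter", seed = 2)
  model <- resonanceModel(deltaPpm = c(gas = 0, membrane = 0, rbc = 0),
                          t2starMs = c(gas = 20, membrane = 2, rbc = 2))
  kd <- simulateKSpace(ph, traj, model, method = "direct")
  s <- kSpaceArray(kd)[1, , ]
  mirrored <- s[, 9:1] # sample j <-> -k of sample 10-j
  expect_lt(max(abs(s - Conj(mirrored))), 1e-10 * max(abs(s)))
})

test_that("noise realization is seed-reproducible", {
  ph <- makeLungPhantom(8, seed = 1)
  traj <- radialTrajectory(10, 8, seed = 1)
  simA <- simulationParams(noiseSigma = 0.5, seed = 11L)
  k1 <- simulateKSpace(ph, traj, sim = simA, method = "direct")
  k2 <- simulateKSpace(ph, traj, sim = simA, method = "direct")
  expect_identical(kSpaceArray(k1), kSpaceArray(k2))
  k3 <- simulateKSpace(ph, traj,
                       sim = simulationParams(noiseSigma = 0.5, seed = 12L),
                       method = "direct")
  expect_false(identical(kSpaceArray(k1), kSpaceArray(k3)))
})

test_that("per-spoke depolarization attenuates later spokes", {
  ph <- makeLungPhantom(8, seed = 1)
  traj <- radialTrajectory(50, 8, seed = 7)
  kd <- simulateKSpace(ph, traj,
                       sim = simulationParams(depolarization = "per_spoke"),
                       method = "direct")
  ord <- spokeOrder(traj)
  first <- which(ord == 1)
  last <- which(ord == 50)
  # compare center-of-k-space magnitudes of the temporally first and
  # last spokes
  expect_gt(abs(kSpaceArray(kd)[1, first, 1]),
            abs(kSpaceArray(kd)[1, last, 1]))
  # off: no temporal dependence
  kd0 <- simulateKSpace(ph, traj, method = "direct")
  expect_equal(abs(kSpaceArray(kd0)[1, first, 1]),
               abs(kSpaceArray(kd0)[1, last, 1]), tolerance = 1e-12)
})
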