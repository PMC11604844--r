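test_that("Kaiser-Bessel window matches the Bessel-series oracle", {
  beta <- kbBeta(8, 1.2)
  expect_equal(beta, pi * sqrt((8 / 1.2)^2 * 0.7^2 - 0.8),
               tolerance = 1e-14)
  w <- kaiserBessel(c(0, 1, 2), 8, beta)
  i0 <- besselI0Series(beta)
  for (i in 1:3) {
    u <- c(0, 1, 2)[i]
    ref <- besselI0Series(beta * sqrt(1 - (2 * u / 8)^2)) / i0
    expect_equal(w[i], ref, tolerance = 1e-10)
  }
  # peak at zero, even, compactly supported
  expect_equal(which.max(kaiserBessel(seq(-4, 4, 0.5), 8, beta)), 9L)
  for (u in c(0.5, 1, 3)) {
    expect_identical(kaiserBessel(u, 8, beta), kaiserBessel(-u, 8, beta))
  }
  expect_identical(kaiserBessel(4.01, 8, beta), 0)
  expect_error(kaiserBessel(1, 8, -1), "beta")
})

test_that("density compensation grows as r^2 with a finite center weight", {
  t2 <- samplePositions(matrix(c(0, 0, 1), 1), 2)
  w <- densityCompensation(t2)
  expect_gt(w[1, 2], w[1, 1])
  expect_gt(w[1, 1], 0)
  traj <- radialTrajectory(30, 8, seed = 1)
  w8 <- densityCompensation(traj)
  expect_equal(sum(w8), 1, tolerance = 1e-12)
  r <- sqrt(rowSums(matrix(kCoords(traj)[1, , ], 8, 3)^2))
  expect_equal(w8[1, 3:8] / w8[1, 2], (r[3:8] / r[2])^2,
               tolerance = 1e-12)
})

test_that("discrete Voronoi weights are equal for uniform Cartesian points", {
  g <- 6
  ax <- ((1:g) - 0.5) / g - 0.5
  pts <- as.matrix(expand.grid(ax, ax, ax))
  n <- nrow(pts) / g
  k <- array(0, c(n, g, 3))
  for (i in 1:3) k[, , i] <- matrix(pts[, i], n, g)
  traj <- new("RadialTrajectory",
    directions = matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE),
    order = seq_len(n), samplesPerSpoke = as.integer(g),
    kCoords = k, spokeStyle = "full_diameter"
  )
  w <- densityCompensation(traj, "voronoi", voronoiGrid = 12L)
  expect_equal(range(w * length(w)), c(1, 1), tolerance = 1e-12)

  # duplicated k-points are merged with shared weight: acquiring every
  # point twice halves each weight instead of double-counting cells
  kDup <- array(0, c(2 * n, g, 3))
  kDup[1:n, , ] <- k
  kDup[n + (1:n), , ] <- k
  trajDup <- new("RadialTrajectory",
    directions = rbind(traj@directions, traj@directions),
    order = seq_len(2 * n), samplesPerSpoke = as.integer(g),
    kCoords = kDup, spokeStyle = "full_diameter"
  )
  wd <- densityCompensation(trajDup, "voronoi", voronoiGrid = 12L)
  expect_equal(sum(wd), 1, tolerance = 1e-12)
  expect_equal(wd[1, ], wd[n + 1, ], tolerance = 1e-12)
  expect_equal(range(wd * length(wd)), c(1, 1), tolerance = 1e-12)
})

test_that("density compensation lowers PSF sidelobe energy", {
  traj <- radialTrajectory(200, 8, seed = 1)
  gcfg <- griddingConfig(matrix = 8L, oversampling = 2, kernelWidth = 6L)
  imp <- array(0i, rep(8, 3))
  imp[5, 5, 5] <- 1
  y <- matrix(nufftForward(imp, encodingModel(traj, matrix = 8L)), 200, 8)
  side <- function(p) {
    p <- abs(p) / max(abs(p))
    idx <- which(array(TRUE, rep(8, 3)), arr.ind = TRUE)
    r <- sqrt(rowSums(sweep(idx, 2, c(5, 5, 5))^2))
    sum(p[r > 2])
  }
  withDcf <- gridReconstruct(y, traj, gcfg)
  uniform <- gridReconstruct(y, traj, gcfg,
                             dcf = matrix(1 / length(y), 200, 8))
  expect_lt(side(withDcf), side(uniform))
})

test_that("gridding matches the adjoint-DFT oracle with the same DCF", {
  ph <- makeLungPhantom(8, seed = 2)
  traj <- radialTrajectory(200, 8, seed = 5)
  kd <- simulateKSpace(ph, traj, method = "direct")
  comp <- separateComponents(kd,
    buildPhaseMatrix(resonanceModel(), echoTimes(kd)))
  gcfg <- griddingConfig(matrix = 8L, oversampling = 2, kernelWidth = 6L)
  dcf <- densityCompensation(traj)
  img <- gridReconstruct(kSpaceArray(comp, "rbc"), traj, gcfg, dcf = dcf)
  ref <- adjointDftOracle(
    as.vector(kSpaceArray(comp, "rbc")) * as.vector(dcf),
    matrix(kCoords(traj), ncol = 3), 8
  )
  nrms <- sqrt(mean(abs(img - ref)^2)) / sqrt(mean(abs(ref)^2))
  expect_lt(nrms, 0.02)
})

test_that("gridding is linear and a DC impulse gives a flat image", {
  traj <- radialTrajectory(200, 8, seed = 1)
  gcfg <- griddingConfig(matrix = 8L, oversampling = 2, kernelWidth = 6L)
  expect_true(all(gridReconstruct(matrix(0i, 200, 8), traj, gcfg) == 0))

  s <- matrix(0i, 200, 8)
  s[, 1] <- 1 # center-out spokes share the k-space origin at sample 1
  img <- gridReconstruct(s, traj, gcfg)
  ctr <- abs(img[3:6, 3:6, 3:6])
  expect_lt(sd(ctr) / mean(ctr), 0.01)

  # exact homogeneity: image energy scales with the data
  y <- randomComplexArray(c(200, 8), seed = 3)
  i1 <- gridReconstruct(y, traj, gcfg)
  i2 <- gridReconstruct((2 + 1i) * y, traj, gcfg)
  expect_equal(i2, (2 + 1i) * i1, tolerance = 1e-12)

  expect_error(gridReconstruct(y, traj, gcfg, dcf = matrix(0, 200, 8)),
               "all zero")
})

test_that("a voxel-shifted phantom reconstructs as the shifted image", {
  ph <- makeLungPhantom(16, seed = 6)
  shift <- 2L
  phS <- ph
  # circular shift of all densities along the first axis
  perm <- c((16 - shift + 1):16, 1:(16 - shift))
  phS@rhoGas <- ph@rhoGas[perm, , ]
  phS@rhoM <- ph@rhoM[perm, , ]
  phS@rhoRbc <- ph@rhoRbc[perm, , ]
  phS@lungMask <- array(ph@lungMask[perm, , ], rep(16, 3))
  traj <- radialTrajectory(500, 16, seed = 2)
  gcfg <- griddingConfig(matrix = 16L)
  phi <- buildPhaseMatrix(resonanceModel(), c(0.57, 1.27, 1.97, 2.67))
  img <- gridReconstruct(kSpaceArray(
    separateComponents(simulateKSpace(ph, traj, method = "direct"), phi),
    "gas"), traj, gcfg)
  imgS <- gridReconstruct(kSpaceArray(
    separateComponents(simulateKSpace(phS, traj, method = "direct"), phi),
    "gas"), traj, gcfg)
  # the non-Cartesian transform is not periodic at off-grid k, so the
  # wrapped band is excluded: rows shifted out of range are dropped
  a <- imgS[(1 + shift):16, , ]
  b <- img[1:(16 - shift), , ]
  nrms <- sqrt(mean(abs(a - b)^2)) / sqrt(mean(abs(img)^2))
  expect_lt(nrms, 0.02)
})

test_that("the protocol-default gridding runs a full study in seconds", {
  traj <- radialTrajectory(934, 32, seed = 1)
  y <- randomComplexArray(c(934, 32), seed = 1)
  t0 <- proc.time()[3]
  img <- gridReconstruct(y, traj, griddingConfig())
  elapsed <- proc.time()[3] - t0
  expect_equal(dim(img), rep(32L, 3))
  expect_lt(elapsed, 10)
})
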