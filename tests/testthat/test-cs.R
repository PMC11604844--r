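test_that("complex soft thresholding shrinks magnitude and keeps phase", {
  expect_identical(softThreshold(3 + 4i, 5), 0 + 0i)
  expect_identical(softThreshold(3 + 4i, 0), 3 + 4i)
  expect_equal(softThreshold(6 + 8i, 5), 3 + 4i, tolerance = 1e-14)
  z <- complex(real = rnorm(50), imaginary = rnorm(50))
  out <- softThreshold(z, 0.3)
  nz <- abs(z) > 0.3
  expect_equal(Arg(out[nz]), Arg(z[nz]), tolerance = 1e-12)
  expect_true(all(out[!nz] == 0))
  expect_error(softThreshold(1 + 1i, -1), "tau")
})

test_that("TV transform differentiates with replicate-edge boundary", {
  expect_true(all(tvForward(array(7 + 2i, c(4, 4, 4))) == 0))
  ramp <- array(0i, c(4, 4, 4))
  for (i in 1:4) ramp[i, , ] <- i - 1
  d <- tvForward(ramp)
  expect_true(all(d[1:3, , , 1] == 1)) # interior differences
  expect_true(all(d[4, , , 1] == 0)) # replicate edge
  expect_true(all(d[, , , 2:3] == 0))
})

test_that("TV forward/adjoint pass the dot-product test", {
  x <- randomComplexArray(rep(16, 3), seed = 1)
  d <- array(complex(real = rnorm(16^3 * 3), imaginary = rnorm(16^3 * 3)),
             c(16, 16, 16, 3))
  lhs <- sum(Conj(tvForward(x)) * d)
  rhs <- sum(Conj(x) * tvAdjoint(d))
  expect_lt(abs(lhs - rhs) / sqrt(abs(lhs) * abs(rhs)), 1e-10)
})

test_that("objective value equals an independent three-term sum", {
  traj <- radialTrajectory(30, 8, seed = 2)
  enc <- encodingModel(traj, matrix = 8L)
  y <- complex(real = rnorm(240), imaginary = rnorm(240))
  expect_identical(objectiveValue(array(0i, rep(8, 3)),
                                  rep(0i, 240), enc, 0.1, 0.1), 0)
  expect_equal(objectiveValue(array(0i, rep(8, 3)), y, enc, 0.1, 0.1),
               sqrt(sum(abs(y)^2)), tolerance = 1e-12)

  x <- randomComplexArray(rep(8, 3), seed = 3)
  # independent recomputation: oracle DFT + explicit difference sums
  Ax <- directDftOracle(x, xecs:::.flatKCoords(traj))
  tvSum <- 0
  for (ax in 1:3) {
    dd <- apply(x, setdiff(1:3, ax), diff)
    tvSum <- tvSum + sum(abs(dd))
  }
  ref <- sqrt(sum(abs(Ax - y)^2)) + 0.01 * sum(abs(x)) + 0.002 * tvSum
  expect_equal(objectiveValue(x, y, enc, 0.01, 0.002), ref,
               tolerance = 1e-4)
  refSq <- sum(abs(Ax - y)^2) + 0.01 * sum(abs(x)) + 0.002 * tvSum
  expect_equal(objectiveValue(x, y, enc, 0.01, 0.002, squaredData = TRUE),
               refSq, tolerance = 1e-4)
})

test_that("unregularized ADMM on a covering trajectory matches least squares", {
  traj <- cubeCoveringTrajectory(400, 8)
  ph <- makeLungPhantom(8, seed = 2)
  kd <- simulateKSpace(ph, traj, method = "direct")
  comp <- separateComponents(kd,
    buildPhaseMatrix(resonanceModel(), echoTimes(kd)))
  y <- as.vector(kSpaceArray(comp, "gas"))
  # explicit-matrix least-squares oracle
  kmat <- xecs:::.flatKCoords(traj)
  idx <- which(array(TRUE, rep(8, 3)), arr.ind = TRUE)
  A <- exp(-2i * pi * (kmat %*% t(sweep(idx - 1, 2, 4))))
  xls <- qr.solve(A, y)
  enc <- encodingModel(traj, matrix = 8L)
  res <- admmSolve(y, enc, csConfig(lambda1 = 0, lambda2 = 0,
    maxIter = 50L, cgIter = 20L, admmRho = 1e-3, tol = 0))
  rel <- sqrt(sum(abs(as.vector(res$image) - xls)^2) / sum(abs(xls)^2))
  expect_lt(rel, 1e-3)

  # and the least-squares image agrees with gridding over the lung
  grd <- gridReconstruct(kSpaceArray(comp, "gas"), traj,
    griddingConfig(matrix = 8L, oversampling = 2, kernelWidth = 6L))
  m <- maskArray(ph)
  a <- abs(grd)[m] / sqrt(mean(abs(grd)[m]^2))
  b <- abs(array(xls, rep(8, 3)))[m]
  b <- b / sqrt(mean(b^2))
  expect_lt(sqrt(mean((a - b)^2)), 0.05)
})

test_that("zero data with positive regularization gives the zero image", {
  traj <- radialTrajectory(30, 8, seed = 1)
  enc <- encodingModel(traj, matrix = 8L)
  res <- admmSolve(rep(0i, 240), enc,
                   csConfig(lambda1 = 0.01, lambda2 = 0.001,
                            maxIter = 5L))
  expect_true(all(res$image == 0))
})

test_that("stronger L1 weights never increase the solution's L1 norm", {
  ph <- makeLungPhantom(8, seed = 2)
  traj <- radialTrajectory(100, 8, seed = 3)
  kd <- simulateKSpace(ph, traj,
                       sim = simulationParams(noiseSigma = 0.002,
                                              seed = 2L),
                       method = "direct")
  comp <- separateComponents(kd,
    buildPhaseMatrix(resonanceModel(), echoTimes(kd)))
  y <- as.vector(kSpaceArray(comp, "rbc"))
  enc <- encodingModel(traj, matrix = 8L)
  l1s <- vapply(c(0, 0.003, 0.03, 0.3), function(lam) {
    res <- admmSolve(y, enc, csConfig(lambda1 = lam, lambda2 = 0,
                                      maxIter = 30L, tol = 0))
    sum(abs(res$image))
  }, numeric(1))
  expect_true(all(diff(l1s) <= 1e-6 * l1s[1]))
})

test_that("the ADMM objective trace settles monotonically", {
  ph <- makeLungPhantom(8, seed = 2)
  traj <- radialTrajectory(150, 8, seed = 4)
  kd <- simulateKSpace(ph, traj,
                       sim = simulationParams(noiseSigma = 0.001,
                                              seed = 3L),
                       method = "direct")
  comp <- separateComponents(kd,
    buildPhaseMatrix(resonanceModel(), echoTimes(kd)))
  plan <- selectSpokes(traj, af = 2)
  enc <- encodingModel(traj, plan, matrix = 8L)
  y <- kSpaceArray(comp, "rbc")[retainedSpokes(plan), ]
  for (dt in c("squared", "unsquared")) {
    res <- admmSolve(y, enc, csConfig(maxIter = 30L, tol = 0,
                                      dataTerm = dt))
    obj <- res$trace$objective
    tail80 <- obj[ceiling(0.2 * length(obj)):length(obj)]
    expect_true(all(diff(tail80) <= 1e-8 * obj[1]))
  }
})
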