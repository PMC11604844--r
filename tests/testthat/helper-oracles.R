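# Independent oracles and shared fixtures. Oracles are deliberately
# naive (direct sums, series expansions) and independent of the
# package's FFT/gridding code paths.

# Brute-force DFT of a (possibly complex) volume at arbitrary k-points,
# phase-referenced to the center voxel N/2 (0-based).
directDftOracle <- function(vol, kmat) {
  N <- dim(vol)[1]
  idx <- which(array(TRUE, dim(vol)), arr.ind = TRUE)
  pos <- sweep(idx - 1L, 2L, N / 2)
  vals <- as.vector(vol)
  vapply(seq_len(nrow(kmat)), function(j) {
    sum(vals * exp(-2i * pi * as.vector(pos %*% kmat[j, ])))
  }, complex(1))
}

# Conjugate-transpose (adjoint) DFT of weighted samples.
adjointDftOracle <- function(y, kmat, N) {
  idx <- which(array(TRUE, rep(N, 3L)), arr.ind = TRUE)
  pos <- sweep(idx - 1L, 2L, N / 2)
  out <- vapply(seq_len(nrow(idx)), function(p) {
    sum(y * exp(2i * pi * as.vector(kmat %*% pos[p, ])))
  }, complex(1))
  array(out, rep(N, 3L))
}

# Modified Bessel I0 by its power series (oracle for the KB window).
besselI0Series <- function(x, terms = 60L) {
  k <- 0:(terms - 1L)
  sum((x / 2)^(2 * k) / factorial(k)^2)
}

# A trajectory whose per-spoke radius extends to the k-space cube face
# (direction-dependent max radius): every Cartesian frequency region
# is covered, so the plain least-squares problem is well conditioned
# ("fully sampled" in the cube sense). Still satisfies |k|_inf <= 0.5.
cubeCoveringTrajectory <- function(nSpokes, samplesPerSpoke) {
  d <- generateSpokeDirections(nSpokes)
  rmax <- 0.5 / apply(abs(d), 1L, max)
  m <- samplesPerSpoke
  k <- array(0, c(nSpokes, m, 3L))
  for (a in 1:3) {
    k[, , a] <- outer(d[, a] * rmax, (0:(m - 1)) / (m - 1))
  }
  methods::new("RadialTrajectory",
    directions = d, order = seq_len(nSpokes),
    samplesPerSpoke = as.integer(m), kCoords = k,
    spokeStyle = "center_out"
  )
}

# A trajectory wrapper around arbitrary k-points (n x 3), used to probe
# the NUFFT at scattered locations.
scatterTrajectory <- function(pts) {
  n <- nrow(pts)
  k <- array(0, c(n, 2L, 3L))
  for (a in 1:3) k[, 2L, a] <- pts[, a]
  methods::new("RadialTrajectory",
    directions = matrix(rep(c(0, 0, 1), n), n, 3L, byrow = TRUE),
    order = seq_len(n), samplesPerSpoke = 2L,
    kCoords = k, spokeStyle = "center_out"
  )
}

randomComplexArray <- function(dims, seed = 1L) {
  set.seed(seed)
  array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))),
        dims)
}

# Run configuration for a small (16^3) phantom study used across the
# unit tests; built once per test session.
smallStudyConfig <- function(seed = 5L) {
  cfg <- defaultRunConfig(seed = seed)
  cfg$phantom$matrix <- 16L
  cfg$gridding$matrix <- 16L
  cfg$trajectory$n_spokes <- 250L
  cfg$trajectory$samples_per_spoke <- 16L
  cfg$cs$max_iter <- 25L
  cfg$metrics$noise_slices <- 2L
  cfg
}

.fixtureEnv <- new.env(parent = emptyenv())

smallStudy <- function() {
  if (is.null(.fixtureEnv$study)) {
    .fixtureEnv$study <- simulateStudy(smallStudyConfig())
  }
  .fixtureEnv$study
}

smallGridding <- function() {
  if (is.null(.fixtureEnv$grid)) {
    study <- smallStudy()
    cfg <- study$config
    img <- reconstructStudy(study$kdata, study$model, "gridding",
                            af = 1, config = cfg)
    gx <- gasExchangeMaps(img, seq = study$seq, model = study$model,
                          config = cfg)
    .fixtureEnv$grid <- list(images = img, maps = gx$maps, mask = gx$mask)
  }
  .fixtureEnv$grid
}
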