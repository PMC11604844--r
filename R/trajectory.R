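# 3D radial trajectory generation, acquisition ordering and
# retrospective undersampling.

#' Generate near-equidistant spoke directions on the sphere
#'
#' Default scheme is the deterministic spiral-phyllotaxis
#' (generalized-Fibonacci) lattice, which distributes `n` points
#' near-uniformly over the unit sphere. A single spoke is placed at the
#' +z pole by convention.
#'
#' @param n number of spokes (>= 1).
#' @param method direction scheme; currently `"phyllotaxis"`.
#' @return numeric matrix (n x 3) of unit vectors.
#' @examples
#' d <- generateSpokeDirections(934)
#' range(sqrt(rowSums(d^2)))
#' @export
generateSpokeDirections <- function(n, method = c("phyllotaxis")) {
  method <- match.arg(method)
  .stopIf(length(n) != 1L || !is.finite(n) || n < 1,
          "n must be a positive count")
  n <- as.integer(n)
  if (n == 1L) {
    return(matrix(c(0, 0, 1), 1L, 3L))
  }
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  golden <- pi * (3 - sqrt(5))
  phi <- (i - 1) * golden
  r <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(r * cos(phi), r * sin(phi), z)
  # renormalize to machine precision
  d / sqrt(rowSums(d^2))
}

#' Random temporal acquisition order
#'
#' @param nSpokes number of spokes.
#' @param seed integer seed; the permutation is reproducible for a
#'   fixed seed.
#' @return integer permutation of `1:nSpokes`.
#' @export
randomizeOrder <- function(nSpokes, seed = 1L) {
  .stopIf(nSpokes < 1, "nSpokes must be >= 1")
  nSpokes <- as.integer(nSpokes)
  .withSeed(as.integer(seed), sample.int(nSpokes))
}

#' Lay out k-space sample positions along spokes
#'
#' Samples are uniformly spaced along each direction: radius 0 to 0.5
#' for `center_out` spokes, -0.5 to 0.5 for `full_diameter` (normalized
#' units, Nyquist at 0.5).
#'
#' @param directions unit direction matrix (n x 3), e.g. from
#'   [generateSpokeDirections()].
#' @param samplesPerSpoke readout samples per spoke (>= 2).
#' @param spokeStyle `"center_out"` (default) or `"full_diameter"`.
#' @param order temporal acquisition order (permutation); defaults to
#'   acquisition in index order.
#' @return a [RadialTrajectory-class].
#' @export
samplePositions <- function(directions, samplesPerSpoke = 32L,
                            spokeStyle = c("center_out", "full_diameter"),
                            order = NULL) {
  spokeStyle <- match.arg(spokeStyle)
  .stopIf(samplesPerSpoke < 2, "samplesPerSpoke must be >= 2")
  if (is.vector(directions)) directions <- matrix(directions, 1L)
  n <- nrow(directions)
  m <- as.integer(samplesPerSpoke)
  if (is.null(order)) order <- seq_len(n)
  radii <- if (spokeStyle == "center_out") {
    0.5 * (0:(m - 1)) / (m - 1)
  } else {
    -0.5 + (0:(m - 1)) / (m - 1)
  }
  k <- array(0, c(n, m, 3L))
  for (a in 1:3) k[, , a] <- outer(directions[, a], radii)
  new("RadialTrajectory",
    directions = directions, order = as.integer(order),
    samplesPerSpoke = m, kCoords = k, spokeStyle = spokeStyle
  )
}

#' Build a complete radial trajectory
#'
#' Convenience wrapper: phyllotaxis directions, randomized acquisition
#' order, uniform sample positions.
#'
#' @param nSpokes number of spokes.
#' @param samplesPerSpoke readout samples per spoke.
#' @param spokeStyle `"center_out"` or `"full_diameter"`.
#' @param seed seed for the random acquisition order.
#' @inheritParams generateSpokeDirections
#' @return a [RadialTrajectory-class].
#' @examples
#' traj <- radialTrajectory(934, 32, seed = 7)
#' traj
#' @export
radialTrajectory <- function(nSpokes, samplesPerSpoke = 32L,
                             spokeStyle = c("center_out", "full_diameter"),
                             seed = 1L, method = "phyllotaxis") {
  d <- generateSpokeDirections(nSpokes, method)
  samplePositions(d, samplesPerSpoke, match.arg(spokeStyle),
                  order = randomizeOrder(nrow(d), seed))
}

#' Select spokes for retrospective undersampling
#'
#' Retains `round-half-up(S / af)` spokes. `first_n` keeps the
#' temporally first spokes of the acquisition (consecutive ordering);
#' `random` samples uniformly without replacement.
#'
#' @param traj a [RadialTrajectory-class].
#' @param af acceleration factor (>= 1).
#' @param mode `"first_n"` or `"random"`.
#' @param seed seed for random selection.
#' @return an [UndersamplingPlan-class].
#' @examples
#' traj <- radialTrajectory(934, 8)
#' length(retainedSpokes(selectSpokes(traj, af = 2)))  # 467
#' @export
selectSpokes <- function(traj, af = 1, mode = c("first_n", "random"),
                         seed = 1L) {
  mode <- match.arg(mode)
  .stopIf(af < 1, "acceleration factor must be >= 1")
  S <- nSpokes(traj)
  nKeep <- .roundHalfUp(S / af)
  retained <- if (mode == "first_n") {
    which(spokeOrder(traj) <= nKeep)
  } else {
    sort(.withSeed(as.integer(seed), sample.int(S, nKeep)))
  }
  new("UndersamplingPlan",
    af = af, mode = mode, seed = as.integer(seed),
    retained = as.integer(sort(retained)), nSpokes = S
  )
}

#' Retained spoke count for a given acceleration factor
#'
#' Round-half-up of `nSpokes / af`: a 934-spoke acquisition keeps
#' 467, 311 and 234 spokes at AF 2, 3 and 4.
#'
#' @param nSpokes total spokes.
#' @param af acceleration factor(s), vectorized.
#' @return integer vector of retained counts.
#' @export
retainedSpokeCount <- function(nSpokes, af) {
  .stopIf(any(af < 1), "acceleration factor must be >= 1")
  as.integer(.roundHalfUp(nSpokes / af))
}

#' Export a trajectory as a flat CSV table
#'
#' Columns: spoke, sample, kx, ky, kz (debugging aid).
#'
#' @param traj a [RadialTrajectory-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportTrajectoryCSV <- function(traj, path) {
  k <- kCoords(traj)
  n <- nSpokes(traj)
  m <- samplesPerSpoke(traj)
  df <- data.frame(
    spoke = rep(seq_len(n), m),
    sample = rep(seq_len(m), each = n),
    kx = as.vector(k[, , 1]),
    ky = as.vector(k[, , 2]),
    kz = as.vector(k[, , 3])
  )
  df <- df[order(df$spoke, df$sample), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Flatten the k coordinates of (optionally a subset of) spokes into an
# (nSamples x 3) matrix, spoke-major.
.flatKCoords <- function(traj, spokes = NULL) {
  k <- kCoords(traj)
  if (!is.null(spokes)) k <- k[spokes, , , drop = FALSE]
  matrix(k, ncol = 3L)
}
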