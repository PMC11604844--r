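# Conventional non-Cartesian reconstruction: density compensation,
# Kaiser-Bessel convolution gridding onto an oversampled Cartesian
# grid, inverse FFT, deapodization and central crop.

#' Kaiser-Bessel window
#'
#' `w(u) = I0(beta * sqrt(1 - (2u/width)^2)) / I0(beta)` for
#' `|u| <= width/2`, zero outside.
#'
#' @param u offset in grid cells (vectorized).
#' @param width kernel width in grid cells.
#' @param beta shape parameter (> 0).
#' @return numeric weights.
#' @examples
#' kaiserBessel(c(-1, 0, 1), 8, kbBeta(8, 1.2))
#' @export
kaiserBessel <- function(u, width, beta) {
  .stopIf(beta <= 0, "beta must be > 0")
  cpp_kb_window(as.numeric(u), width, beta)
}

#' Density compensation weights for a radial trajectory
#'
#' `analytic_r2`: weights proportional to `|k|^2` along each spoke with
#' a finite center weight (the average of `r^2` over the first radial
#' cell). `voronoi`: a discrete Voronoi estimate - each sample is
#' weighted by the k-space volume of the fine-grid cells nearest to it
#' (duplicate k-points are merged and share the merged weight).
#' Weights are normalized to sum to 1 over the returned samples.
#'
#' @param traj a [RadialTrajectory-class].
#' @param mode `"analytic_r2"` or `"voronoi"`.
#' @param spokes optional integer subset of spokes (e.g.
#'   `retainedSpokes(plan)`).
#' @param voronoiGrid fine-grid resolution per axis for the discrete
#'   Voronoi estimate.
#' @return numeric matrix (nSpokes x samplesPerSpoke) of weights for
#'   the selected spokes.
#' @export
densityCompensation <- function(traj, mode = c("analytic_r2", "voronoi"),
                                spokes = NULL, voronoiGrid = 32L) {
  mode <- match.arg(mode)
  if (is.null(spokes)) spokes <- seq_len(nSpokes(traj))
  k <- kCoords(traj)[spokes, , , drop = FALSE]
  nS <- length(spokes)
  nM <- samplesPerSpoke(traj)
  r <- sqrt(k[, , 1]^2 + k[, , 2]^2 + k[, , 3]^2)
  dim(r) <- c(nS, nM)
  if (mode == "analytic_r2") {
    w <- r^2
    # finite center weight: mean of r^2 over the first radial cell
    dr <- abs(r[, 2] - r[, 1])
    zero <- w == 0
    if (any(zero)) {
      w[zero] <- rep((dr^2) / 12, nM)[zero]
    }
  } else {
    pts <- matrix(k, ncol = 3L)
    key <- apply(round(pts, 12), 1L, paste, collapse = ",")
    grp <- match(key, unique(key))
    sites <- pts[!duplicated(key), , drop = FALSE]
    g <- as.integer(voronoiGrid)
    ax <- (((1:g) - 0.5) / g - 0.5) # cell centers in [-0.5, 0.5]
    queries <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
    nearest <- cpp_nearest_site(sites, queries)
    cellVol <- (1 / g)^3
    siteW <- tabulate(nearest, nbins = nrow(sites)) * cellVol
    dup <- tabulate(grp, nbins = nrow(sites))
    w <- matrix(siteW[grp] / dup[grp], nS, nM)
  }
  w / sum(w)
}

#' Gridding reconstruction of one spectral channel
#'
#' Density-compensated Kaiser-Bessel convolution onto an
#' `(oversampling * matrix)^3` grid, inverse FFT, deapodization by the
#' kernel transform, and central crop. Linear in the input data; the
#' complex image is returned (magnitude is taken only at the mapping
#' stage).
#'
#' @param samples complex matrix (nSpokes x samplesPerSpoke) of one
#'   component's k-space, or the matching subset when `plan` is given.
#' @param traj a [RadialTrajectory-class].
#' @param config a [GriddingConfig-class].
#' @param plan optional [UndersamplingPlan-class]; `samples` may be
#'   either the full spoke set (subset internally) or already
#'   restricted to the retained spokes.
#' @param dcf optional precomputed density-compensation weights for the
#'   retained spokes (must not be all zero).
#' @return complex 3D array (`matrix^3`).
#' @export
gridReconstruct <- function(samples, traj, config = griddingConfig(),
                            plan = NULL, dcf = NULL) {
  spokes <- if (is.null(plan)) seq_len(nSpokes(traj)) else
    retainedSpokes(plan)
  if (nrow(samples) == nSpokes(traj) &&
      length(spokes) != nSpokes(traj)) {
    samples <- samples[spokes, , drop = FALSE]
  }
  .stopIf(nrow(samples) != length(spokes) ||
            ncol(samples) != samplesPerSpoke(traj),
          "sample matrix shape does not match trajectory/plan")
  if (is.null(dcf)) {
    dcf <- densityCompensation(traj, config@dcfMode, spokes = spokes)
  }
  .stopIf(all(dcf == 0), "density compensation weights are all zero")
  kmat <- .flatKCoords(traj, spokes)
  plan3 <- .nufftPlan(config@matrix, config@oversampling,
                      config@kernelWidth, config@kbBeta)
  # scale convention: exact conjugate-transpose (adjoint) DFT of the
  # density-compensated data
  .nufftAdjointRaw(as.vector(samples) * as.vector(dcf), kmat, plan3)
}
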