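# Non-uniform Fourier encoding: Kaiser-Bessel interpolated evaluation
# of the DFT at arbitrary k-space locations, and its exact conjugate
# transpose. The forward model is
#   s_j = sum_p x(p) exp(-2i*pi*k_j . (p - c)),  c = N/2 (center voxel),
# evaluated by deapodization -> centered zero-padding -> FFT ->
# Kaiser-Bessel interpolation with periodic wrap; because voxel
# positions are integers the true DFT is periodic in k with period 1,
# so the wrap is exact and only the interpolation contributes error.

.nufftPlan <- function(N, oversampling = 2, kernelWidth = 6L,
                       beta = NULL) {
  N <- as.integer(N)
  G <- .gridSize(N, oversampling)
  if (is.null(beta)) beta <- kbBeta(kernelWidth, G / N)
  list(
    N = N, G = G, width = as.numeric(kernelWidth), beta = beta,
    apod = .kbApod3(N, G, kernelWidth, beta)
  )
}

# kmat: (n x 3) normalized k coordinates in [-0.5, 0.5].
.nufftForwardRaw <- function(image, kmat, plan) {
  stopifnot(dim(image)[1] == plan$N)
  x <- image / plan$apod
  xp <- .padCenter(x, plan$G)
  X <- .fftshift3(fft(.fftshift3(xp)))
  coords <- kmat * plan$G + plan$G / 2
  cpp_kb_interp(coords, as.vector(X), dim(X), plan$width, plan$beta)
}

.nufftAdjointRaw <- function(samples, kmat, plan) {
  coords <- kmat * plan$G + plan$G / 2
  g <- cpp_kb_spread(coords, as.complex(samples),
                     c(plan$G, plan$G, plan$G), plan$width, plan$beta)
  dim(g) <- c(plan$G, plan$G, plan$G)
  xi <- .fftshift3(fft(.fftshift3(g), inverse = TRUE))
  .cropCenter(xi, plan$N) / plan$apod
}

#' Build an encoding model A = PF
#'
#' Bundles a trajectory, an undersampling plan (the sampling operator
#' P) and Kaiser-Bessel interpolation settings defining the non-uniform
#' Fourier operator F. Forward and adjoint are exact transposes of each
#' other (dot-product test holds to rounding error).
#'
#' @param traj a [RadialTrajectory-class].
#' @param plan an [UndersamplingPlan-class]; default retains all
#'   spokes.
#' @param matrix image matrix size per axis.
#' @param oversampling,kernelWidth interpolation accuracy settings
#'   (defaults 2 and 6 give relative interpolation error well below
#'   1e-3).
#' @param kbBetaValue kernel shape; default Beatty formula.
#' @return an [EncodingModel-class].
#' @export
encodingModel <- function(traj, plan = NULL, matrix = 32L,
                          oversampling = 2, kernelWidth = 6L,
                          kbBetaValue = NULL) {
  if (is.null(plan)) plan <- selectSpokes(traj, af = 1)
  if (is.null(kbBetaValue)) {
    G <- .gridSize(as.integer(matrix), oversampling)
    kbBetaValue <- kbBeta(kernelWidth, G / as.integer(matrix))
  }
  new("EncodingModel",
    trajectory = traj, plan = plan, matrix = as.integer(matrix),
    oversampling = oversampling, kernelWidth = as.integer(kernelWidth),
    kbBeta = kbBetaValue
  )
}

.encPlan <- function(enc) {
  .nufftPlan(enc@matrix, enc@oversampling, enc@kernelWidth, enc@kbBeta)
}

.encKmat <- function(enc) {
  .flatKCoords(enc@trajectory, retainedSpokes(enc@plan))
}

#' Non-uniform Fourier forward and adjoint operators
#'
#' `nufftForward` evaluates the DFT of a complex image at the retained
#' k-space locations of the encoding model; `nufftAdjoint` applies the
#' exact conjugate transpose.
#'
#' @param image complex 3D array (`matrix^3`).
#' @param samples complex vector of non-Cartesian samples
#'   (spoke-major flattening of the retained spokes).
#' @param enc an [EncodingModel-class].
#' @return `nufftForward`: complex sample vector; `nufftAdjoint`:
#'   complex 3D array.
#' @examples
#' traj <- radialTrajectory(50, 8)
#' enc <- encodingModel(traj, matrix = 8L)
#' x <- array(complex(real = rnorm(512), imaginary = rnorm(512)),
#'            c(8, 8, 8))
#' s <- nufftForward(x, enc)
#' xb <- nufftAdjoint(s, enc)
#' @export
nufftForward <- function(image, enc) {
  .stopIf(!identical(dim(image), rep(enc@matrix, 3L)),
          "image dimensions do not match the encoding model")
  .nufftForwardRaw(image, .encKmat(enc), .encPlan(enc))
}

#' @rdname nufftForward
#' @export
nufftAdjoint <- function(samples, enc) {
  kmat <- .encKmat(enc)
  .stopIf(length(samples) != nrow(kmat),
          "sample count does not match the encoding model (%d vs %d)",
          length(samples), nrow(kmat))
  .nufftAdjointRaw(samples, kmat, .encPlan(enc))
}
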