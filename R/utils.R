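# Internal numeric helpers shared by the gridding and CS modules.

# fftshift for a 3D array with even dimensions (self-inverse).
.fftshift3 <- function(x) {
  d <- dim(x)
  stopifnot(all(d %% 2L == 0L))
  ix <- c((d[1] / 2 + 1):d[1], 1:(d[1] / 2))
  iy <- c((d[2] / 2 + 1):d[2], 1:(d[2] / 2))
  iz <- c((d[3] / 2 + 1):d[3], 1:(d[3] / 2))
  x[ix, iy, iz, drop = FALSE]
}

# Zero-pad a cubic array to size G, keeping the center voxel N/2
# (0-based) at G/2. Adjoint of .cropCenter.
.padCenter <- function(x, G) {
  N <- dim(x)[1]
  if (N == G) return(x)
  out <- array(0 + 0i, c(G, G, G))
  off <- (G - N) / 2
  out[off + (1:N), off + (1:N), off + (1:N)] <- x
  out
}

.cropCenter <- function(x, N) {
  G <- dim(x)[1]
  if (N == G) return(x)
  off <- (G - N) / 2
  x[off + (1:N), off + (1:N), off + (1:N), drop = FALSE]
}

# Fourier transform of the (I0(beta)-normalized) Kaiser-Bessel window
# evaluated at image positions x in grid cells from the image center:
#   c(x) = W * sinh(sqrt(beta^2 - (pi W x / G)^2)) /
#          (sqrt(...) * I0(beta)).
# Dividing the image by c undoes both the kernel's smoothing and its
# DC gain, so the interpolated samples approximate the DFT with unit
# overall scale.
.kbApodAxis <- function(N, G, width, beta) {
  x <- (0:(N - 1)) - N / 2
  arg <- beta^2 - (pi * width * x / G)^2
  v <- numeric(N)
  pos <- arg > 0
  v[pos] <- sinh(sqrt(arg[pos])) / sqrt(arg[pos])
  neg <- arg < 0
  v[neg] <- sin(sqrt(-arg[neg])) / sqrt(-arg[neg])
  v[arg == 0] <- 1
  v * width / besselI(beta, 0)
}

.kbApod3 <- function(N, G, width, beta, floorFrac = 1e-6) {
  ax <- .kbApodAxis(N, G, width, beta)
  a <- outer(outer(ax, ax), ax)
  dim(a) <- c(N, N, N)
  # floor to avoid edge blow-up when dividing
  lim <- floorFrac * max(abs(a))
  a[abs(a) < lim] <- lim
  a
}

# Beatty minimal-aliasing Kaiser-Bessel shape parameter.
#' Kaiser-Bessel shape parameter (Beatty formula)
#'
#' `beta = pi * sqrt((W/alpha)^2 * (alpha - 0.5)^2 - 0.8)` for kernel
#' width `W` (grid cells) and grid oversampling ratio `alpha`.
#'
#' @param width kernel width in grid cells.
#' @param oversampling grid oversampling ratio (>= 1).
#' @return numeric shape parameter.
#' @export
kbBeta <- function(width, oversampling) {
  stopifnot(width > 0, oversampling >= 1)
  pi * sqrt((width / oversampling)^2 * (oversampling - 0.5)^2 - 0.8)
}

# Oversampled grid size: even and >= ceil(os * N).
.gridSize <- function(N, oversampling) {
  G <- ceiling(N * oversampling)
  G + (G %% 2L)
}

.complexInner <- function(a, b) sum(Conj(a) * b)

.l2norm <- function(x) sqrt(sum(abs(x)^2))

# round-half-up (base round() is round-half-even)
.roundHalfUp <- function(x) floor(x + 0.5)

.stopIf <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}

# Evaluate an expression with a temporary RNG seed, restoring the
# caller's RNG state afterwards (keeps simulations reproducible without
# clobbering the session RNG).
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
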