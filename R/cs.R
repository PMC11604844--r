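# Compressed-sensing reconstruction: ADMM on
#   argmin_x ||Ax - y||_2^2 + lambda1 ||x||_1 + lambda2 ||Tx||_1
# with A = PF the non-uniform encoding, identity sparsity transform,
# and T the stacked finite-difference (total variation) transform.
# A config switch selects the unsquared L2 data term instead.

#' Complex soft thresholding
#'
#' `z * max(1 - tau/|z|, 0)`: shrinks the magnitude by `tau`,
#' preserving phase; exactly zero when `|z| <= tau`.
#'
#' @param z complex (vector/array).
#' @param tau threshold (>= 0).
#' @return shrunk values, same shape as `z`.
#' @examples
#' softThreshold(6 + 8i, 5) # 3+4i
#' @export
softThreshold <- function(z, tau) {
  .stopIf(tau < 0, "tau must be >= 0")
  m <- abs(z)
  scale <- ifelse(m > tau, 1 - tau / m, 0)
  z * scale
}

#' Total-variation transform and its adjoint
#'
#' `tvForward` stacks per-axis forward differences
#' `d_a(i) = x(i+1) - x(i)` with replicate-edge boundary (the last
#' difference along each axis is zero); `tvAdjoint` is the exact
#' adjoint (negative divergence). The pair passes the dot-product test
#' to rounding error.
#'
#' @param x complex (or numeric) 3D array.
#' @param d 4D array (dim(x) x 3) of stacked differences.
#' @return `tvForward`: a 4D array (dim(x) x 3); `tvAdjoint`: a 3D
#'   array.
#' @export
tvForward <- function(x) {
  d <- dim(x)
  out <- array(0i, c(d, 3L))
  out[-d[1], , , 1] <- x[-1, , ] - x[-d[1], , ]
  out[, -d[2], , 2] <- x[, -1, ] - x[, -d[2], ]
  out[, , -d[3], 3] <- x[, , -1] - x[, , -d[3]]
  out
}

#' @rdname tvForward
#' @export
tvAdjoint <- function(d) {
  dd <- dim(d)[1:3]
  out <- array(0i, dd)
  d1 <- d[, , , 1]
  out[1, , ] <- out[1, , ] - d1[1, , ]
  if (dd[1] > 2) {
    out[2:(dd[1] - 1), , ] <- out[2:(dd[1] - 1), , ] +
      d1[1:(dd[1] - 2), , ] - d1[2:(dd[1] - 1), , ]
  }
  out[dd[1], , ] <- out[dd[1], , ] + d1[dd[1] - 1, , ]
  d2 <- d[, , , 2]
  out[, 1, ] <- out[, 1, ] - d2[, 1, ]
  if (dd[2] > 2) {
    out[, 2:(dd[2] - 1), ] <- out[, 2:(dd[2] - 1), ] +
      d2[, 1:(dd[2] - 2), ] - d2[, 2:(dd[2] - 1), ]
  }
  out[, dd[2], ] <- out[, dd[2], ] + d2[, dd[2] - 1, ]
  d3 <- d[, , , 3]
  out[, , 1] <- out[, , 1] - d3[, , 1]
  if (dd[3] > 2) {
    out[, , 2:(dd[3] - 1)] <- out[, , 2:(dd[3] - 1)] +
      d3[, , 1:(dd[3] - 2)] - d3[, , 2:(dd[3] - 1)]
  }
  out[, , dd[3]] <- out[, , dd[3]] + d3[, , dd[3] - 1]
  out
}

#' Regularized objective value
#'
#' `||Ax - y||_2 + lambda1 ||x||_1 + lambda2 ||Tx||_1` (the L2 data
#' term as printed; set `squaredData = TRUE` for the squared form the
#' solver minimizes by default).
#'
#' @param x complex 3D image.
#' @param y complex data samples.
#' @param enc an [EncodingModel-class].
#' @param lambda1,lambda2 regularization weights.
#' @param squaredData square the data term.
#' @return numeric scalar.
#' @export
objectiveValue <- function(x, y, enc, lambda1, lambda2,
                           squaredData = FALSE) {
  r <- .l2norm(nufftForward(x, enc) - y)
  if (squaredData) r <- r^2
  r + lambda1 * sum(abs(x)) + lambda2 * sum(abs(tvForward(x)))
}

# Conjugate gradient for a Hermitian positive-definite operator.
.cgSolve <- function(applyOp, b, x0, maxIter, tol = 0) {
  x <- x0
  b2 <- Re(.complexInner(b, b))
  if (b2 == 0) return(x * 0)
  r <- b - applyOp(x)
  p <- r
  rs <- Re(.complexInner(r, r))
  if (rs == 0) return(x)
  for (i in seq_len(maxIter)) {
    Ap <- applyOp(p)
    pAp <- Re(.complexInner(p, Ap))
    if (!is.finite(pAp) || pAp <= 0) {
      stop(sprintf(
        "CG breakdown at inner iteration %d (curvature %.3g)", i, pAp
      ), call. = FALSE)
    }
    alpha <- rs / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rsNew <- Re(.complexInner(r, r))
    if (tol > 0 && rsNew <= tol^2 * b2) {
      rs <- rsNew
      break
    }
    p <- r + (rsNew / rs) * p
    rs <- rsNew
  }
  x
}

#' ADMM solver for the regularized reconstruction
#'
#' Operator splitting with `z1 = x` (image-domain L1) and `z2 = Tx`
#' (total variation): the x-update solves
#' `(A*A + rho I + rho T*T) x = A*y + rho(z1 - u1) + rho T*(z2 - u2)`
#' by warm-started conjugate gradient, the z-updates are complex
#' soft-thresholding with `tau = lambda/rho`, and dual updates are
#' standard. With the unsquared data term an additional split
#' `z0 = Ax - y` with an L2-norm proximal step is used. Stops at
#' `maxIter` or when the relative x-change drops below `tol`.
#'
#' When `normalizeData` is set, `y` is scaled so the adjoint image
#' `A*y` has unit maximum magnitude before the lambdas are applied
#' (making the weights transferable across noise levels), and the
#' solution is scaled back.
#'
#' @param y complex sample vector on the retained spokes of `enc`
#'   (spoke-major), or a matrix (nRetained x samplesPerSpoke).
#' @param enc an [EncodingModel-class].
#' @param cfg a [CSConfig-class].
#' @return list with `image` (complex 3D array), `trace` (data.frame:
#'   iteration, objective, relChange), `iterations`, `converged`,
#'   `scale`.
#' @export
admmSolve <- function(y, enc, cfg = csConfig()) {
  y <- as.vector(y)
  .stopIf(length(y) == 0, "empty data")
  kmat <- .encKmat(enc)
  .stopIf(length(y) != nrow(kmat),
          "data length does not match the encoding model")
  plan <- .encPlan(enc)
  fwd0 <- function(x) .nufftForwardRaw(x, kmat, plan)
  adj0 <- function(s) .nufftAdjointRaw(s, kmat, plan)

  # Normalization: rescale the operator to unit spectral norm (power
  # iteration) and the data so a density-compensated adjoint (gridding
  # scale) image has unit maximum magnitude. In these units the
  # solution is O(1) and the lambdas act at a scale that transfers
  # across noise levels and sampling densities.
  sNorm <- 1
  scale <- 1
  if (cfg@normalizeData) {
    v <- adj0(y)
    vn <- .l2norm(v)
    if (vn == 0) v[1] <- 1 + 0i else v <- v / vn
    lam <- 1
    for (i in 1:8) {
      w <- adj0(fwd0(v))
      lam <- .l2norm(w)
      v <- w / lam
    }
    sNorm <- sqrt(lam)
    dcf <- densityCompensation(enc@trajectory, spokes =
                                 retainedSpokes(enc@plan))
    scale <- max(abs(adj0(as.vector(dcf) * y)))
    if (scale == 0) scale <- 1
  }
  fwd <- function(x) fwd0(x) / sNorm
  adj <- function(s) adj0(s) / sNorm
  y <- y / (sNorm * scale)
  Aty <- adj(y)

  rho <- cfg@admmRho
  squared <- cfg@dataTerm == "squared"
  x <- Aty / max(1, max(abs(Aty))) * 0 # start from zero
  z1 <- x
  u1 <- x
  Tx <- tvForward(x)
  z2 <- Tx
  u2 <- Tx
  if (!squared) {
    z0 <- complex(length.out = length(y))
    u0 <- complex(length.out = length(y))
  }

  applyOp <- if (squared) {
    function(v) adj(fwd(v)) + rho * v + rho * tvAdjoint(tvForward(v))
  } else {
    function(v) rho * (adj(fwd(v)) + v + tvAdjoint(tvForward(v)))
  }

  trace <- data.frame(
    iteration = integer(), objective = numeric(), relChange = numeric()
  )
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(cfg@maxIter)) {
    iter <- it
    xPrev <- x
    rhs <- if (squared) {
      2 * Aty + rho * (z1 - u1) + rho * tvAdjoint(z2 - u2)
    } else {
      rho * (adj(y + z0 - u0) + (z1 - u1) + tvAdjoint(z2 - u2))
    }
    opScaled <- if (squared) {
      function(v) 2 * adj(fwd(v)) + rho * v + rho * tvAdjoint(tvForward(v))
    } else {
      applyOp
    }
    x <- .cgSolve(opScaled, rhs, x, cfg@cgIter)
    Ax <- fwd(x)
    Tx <- tvForward(x)
    if (!squared) {
      w <- Ax - y + u0
      wn <- .l2norm(w)
      z0 <- if (wn > 1 / rho) (1 - 1 / (rho * wn)) * w else w * 0
      u0 <- u0 + Ax - y - z0
    }
    z1 <- softThreshold(x + u1, cfg@lambda1 / rho)
    u1 <- u1 + x - z1
    z2 <- softThreshold(Tx + u2, cfg@lambda2 / rho)
    u2 <- u2 + Tx - z2
    obj <- {
      r <- .l2norm(Ax - y)
      (if (squared) r^2 else r) + cfg@lambda1 * sum(abs(x)) +
        cfg@lambda2 * sum(abs(Tx))
    }
    relChange <- .l2norm(x - xPrev) / max(.l2norm(xPrev), 1e-300)
    trace <- rbind(trace, data.frame(
      iteration = it, objective = obj, relChange = relChange
    ))
    if (it > 1L && relChange < cfg@tol) {
      converged <- TRUE
      break
    }
  }
  list(
    image = x * scale, trace = trace, iterations = iter,
    converged = converged, scale = scale
  )
}
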