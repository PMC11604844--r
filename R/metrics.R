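# Quantitative comparison machinery: SNR, NMAE, CV, pixelwise
# regression, Bland-Altman agreement and the NMAE ~ SNR power law.

.noiseSliceIndex <- function(dim3, nSlices = 3L) {
  c(seq_len(nSlices), (dim3 - nSlices + 1):dim3)
}

#' Image SNR: in-mask mean magnitude over background real-part SD
#'
#' SNR is the ratio of the mean absolute signal within the lung mask
#' to the SD of the real part of the signal over six slices outside
#' the lung (three from each end of the slice axis by default).
#'
#' @param image complex 3D volume.
#' @param mask a [LungMask-class] or logical array.
#' @param noiseSlices slices taken from each end of the third axis, or
#'   an explicit integer vector of slice indices via `sliceIndex`.
#' @param sliceIndex optional explicit noise slice indices.
#' @return numeric SNR.
#' @export
imageSNR <- function(image, mask, noiseSlices = 3L, sliceIndex = NULL) {
  m <- if (is(mask, "LungMask")) maskArray(mask) else mask
  d <- dim(image)
  if (is.null(sliceIndex)) {
    sliceIndex <- .noiseSliceIndex(d[3], noiseSlices)
  }
  inNoise <- array(FALSE, d)
  inNoise[, , sliceIndex] <- TRUE
  .stopIf(any(m & inNoise), "noise slices overlap the lung mask")
  noiseSD <- sd(Re(image[inNoise]))
  .stopIf(noiseSD == 0, "noise SD is zero in the designated slices")
  mean(abs(image[m])) / noiseSD
}

#' Normalized mean absolute error (percent)
#'
#' `100 * mean(|test - ref|) / mean(|ref|)` over the mask (the
#' `"range"` normalizer divides by the in-mask range of the reference
#' instead). Voxels where either map is `NA` (excluded by the
#' denominator guard) are dropped.
#'
#' @param test,ref numeric maps on one grid.
#' @param mask a [LungMask-class] or logical array.
#' @param normalizer `"mean"` (default) or `"range"`.
#' @return NMAE in percent.
#' @export
nmae <- function(test, ref, mask, normalizer = c("mean", "range")) {
  normalizer <- match.arg(normalizer)
  m <- if (is(mask, "LungMask")) maskArray(mask) else mask
  .stopIf(!identical(dim(test), dim(ref)), "maps must share one grid")
  ok <- m & !is.na(test) & !is.na(ref)
  tv <- test[ok]
  rv <- ref[ok]
  norm <- if (normalizer == "mean") mean(abs(rv)) else diff(range(rv))
  .stopIf(norm == 0, "reference normalizer is zero over the mask")
  100 * mean(abs(tv - rv)) / norm
}

#' Coefficient of variation of a map
#'
#' SD over mean within the mask (`NA` voxels dropped).
#'
#' @param map numeric 3D map.
#' @param mask a [LungMask-class] or logical array.
#' @return numeric CV.
#' @export
cvMap <- function(map, mask) {
  m <- if (is(mask, "LungMask")) maskArray(mask) else mask
  v <- map[m]
  v <- v[!is.na(v)]
  sd(v) / mean(v)
}

#' Pixelwise linear regression with adjusted R-squared
#'
#' Ordinary least squares `y ~ x` over the masked voxels;
#' `adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - 2)` (single predictor).
#'
#' @param x,y numeric maps on one grid.
#' @param mask a [LungMask-class] or logical array.
#' @return list: slope, intercept, r2, adjustedR2, n.
#' @export
pixelwiseRegression <- function(x, y, mask) {
  m <- if (is(mask, "LungMask")) maskArray(mask) else mask
  ok <- m & !is.na(x) & !is.na(y)
  xv <- x[ok]
  yv <- y[ok]
  .stopIf(length(xv) < 3, "need at least 3 voxels for regression")
  .stopIf(sd(xv) == 0, "degenerate (constant) predictor")
  fit <- lm(yv ~ xv)
  rss <- sum(resid(fit)^2)
  tss <- sum((yv - mean(yv))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  n <- length(xv)
  list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r2 = r2, adjustedR2 = 1 - (1 - r2) * (n - 1) / (n - 2), n = n
  )
}

#' Bland-Altman agreement
#'
#' Bias is the mean difference `a - b`; limits of agreement are
#' `bias +/- 1.96 SD(diff)`.
#'
#' @param a,b paired measurements (e.g. per-subject mean ratios).
#' @return list: bias, loa (length 2), sdDiff, n.
#' @export
blandAltman <- function(a, b) {
  .stopIf(length(a) != length(b), "inputs must be paired")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s),
       sdDiff = s, n = length(d))
}

#' Fit the NMAE ~ a * SNR^k power law
#'
#' Default is ordinary least squares on the log-log line
#' `log(NMAE) = log(a) + k log(SNR)`; `method = "nls"` refines with a
#' direct nonlinear fit started from the log-log estimate.
#'
#' @param snrValues,nmaeValues positive paired values (>= 3 pairs).
#' @param method `"loglog"` or `"nls"`.
#' @return a [PowerLawFit-class].
#' @examples
#' fitPowerLaw(c(2, 5, 10, 20), 50 / c(2, 5, 10, 20))
#' @export
fitPowerLaw <- function(snrValues, nmaeValues,
                        method = c("loglog", "nls")) {
  method <- match.arg(method)
  .stopIf(length(snrValues) != length(nmaeValues),
          "inputs must be paired")
  .stopIf(length(snrValues) < 3, "need at least 3 points")
  .stopIf(any(snrValues <= 0) || any(nmaeValues <= 0),
          "power-law fit requires positive values")
  lx <- log(snrValues)
  ly <- log(nmaeValues)
  fit <- lm(ly ~ lx)
  a <- exp(unname(coef(fit)[1]))
  k <- unname(coef(fit)[2])
  rmse <- sqrt(mean(resid(fit)^2))
  if (method == "nls") {
    nfit <- minpack.lm::nlsLM(
      nmaeValues ~ a * snrValues^k, start = list(a = a, k = k)
    )
    a <- unname(coef(nfit)["a"])
    k <- unname(coef(nfit)["k"])
    rmse <- sqrt(mean(resid(nfit)^2))
  }
  new("PowerLawFit",
    a = a, k = k, rmse = rmse, nPoints = length(snrValues),
    method = method
  )
}

#' Compare two reconstructions of one study
#'
#' Computes the standard fidelity metrics between a test and a
#' reference reconstruction over a common mask: per-map NMAE and CV,
#' pixelwise regression of each ratio map, per-component SNR, and
#' Bland-Altman of the map means.
#'
#' @param testMaps,refMaps [RatioMaps-class] objects on one grid.
#' @param testImages,refImages optional [ComponentImages-class] for
#'   SNR reporting.
#' @param mask a [LungMask-class] or logical array (conventionally the
#'   reference/gridding mask).
#' @param noiseSlices noise slices from each end of the slice axis.
#' @return a [MetricsReport-class].
#' @export
evaluateRecon <- function(testMaps, refMaps, testImages = NULL,
                          refImages = NULL, mask = NULL,
                          noiseSlices = 3L) {
  m <- if (is.null(mask)) refMaps@mask else
    if (is(mask, "LungMask")) maskArray(mask) else mask
  pairs <- list(
    rbc_m = list(t = testMaps@rbcM, r = refMaps@rbcM),
    rbc_gas = list(t = testMaps@rbcGas, r = refMaps@rbcGas),
    m_gas = list(t = testMaps@mGas, r = refMaps@mGas)
  )
  nmaeV <- vapply(pairs, function(p) nmae(p$t, p$r, m), numeric(1))
  reg <- lapply(pairs, function(p) pixelwiseRegression(p$r, p$t, m))
  ba <- lapply(pairs, function(p) {
    blandAltman(mean(p$t[m], na.rm = TRUE), mean(p$r[m], na.rm = TRUE))
  })
  cvs <- list(
    test = vapply(pairs, function(p) cvMap(p$t, m), numeric(1)),
    ref = vapply(pairs, function(p) cvMap(p$r, m), numeric(1))
  )
  snrV <- numeric(0)
  for (nm in c("test", "ref")) {
    img <- if (nm == "test") testImages else refImages
    if (is.null(img)) next
    for (cp in c("gas", "membrane", "rbc")) {
      snrV[paste(nm, cp, sep = "_")] <-
        imageSNR(componentVolume(img, cp), m, noiseSlices)
    }
  }
  new("MetricsReport",
    snr = snrV, nmaePct = nmaeV, cv = cvs, regression = reg,
    blandAltman = ba, nVoxels = as.integer(sum(m))
  )
}
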