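# Protocol arithmetic: breath-hold durations, isotopic enrichment and
# dose-equivalent volumes for enriched vs natural-abundance xenon.

#' Breath-hold duration of a radial acquisition
#'
#' `nSpokes * TR` (seconds); one spoke (all echoes, flyback readout)
#' is acquired per repetition. Set `includeDummy = TRUE` to add the
#' initial dummy pulses. A fully sampled 934-spoke acquisition at
#' TR = 15 ms takes ~14 s; the first 467 spokes (acceleration factor
#' 2) take ~7 s.
#'
#' @param nSpokes spokes acquired.
#' @param trMs repetition time (ms).
#' @param nDummy dummy pulses at the start of the sequence.
#' @param includeDummy include the dummy pulses in the duration.
#' @return duration in seconds.
#' @export
breathHoldDuration <- function(nSpokes, trMs = 15, nDummy = 20L,
                               includeDummy = FALSE) {
  (nSpokes + if (includeDummy) nDummy else 0L) * trMs / 1000
}

#' Isotopic concentration ratio of enriched to natural-abundance xenon
#'
#' Enriched xenon is ~86% 129Xe; natural abundance is ~26%, giving a
#' concentration ratio of ~3.3.
#'
#' @param enrichedFraction 129Xe isotopic fraction of enriched gas.
#' @param naturalFraction 129Xe isotopic fraction of natural-abundance
#'   gas.
#' @return numeric ratio.
#' @export
isotopicConcentrationRatio <- function(enrichedFraction = 0.86,
                                       naturalFraction = 0.26) {
  .stopIf(naturalFraction <= 0, "naturalFraction must be > 0")
  enrichedFraction / naturalFraction
}

#' Dose-equivalent volume of an inhaled xenon dose
#'
#' Inhaled volume scaled by the 129Xe isotopic fraction and the
#' polarization: a cross-dose comparator of signal content. A 1 L
#' natural-abundance dose at 30% polarization is ~80 mL; the same
#' enriched dose is ~260 mL.
#'
#' @param doseMl inhaled volume (mL).
#' @param isotopicFraction 129Xe fraction of the gas.
#' @param polarization polarization fraction.
#' @return dose-equivalent volume (mL).
#' @export
doseEquivalentVolume <- function(doseMl, isotopicFraction,
                                 polarization) {
  .stopIf(any(c(doseMl, isotopicFraction, polarization) < 0),
          "all inputs must be non-negative")
  doseMl * isotopicFraction * polarization
}
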