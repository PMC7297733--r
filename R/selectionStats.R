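#' @include AllClasses.R
NULL

#' Empirical enrichment test for donor-haplotype over-representation
#'
#' Tests whether a haplotype donates horizontal transfers more often than
#' expected under equal per-haplotype transfer opportunity relative to
#' its population frequency. Each replicate draws \code{nEvents} donor
#' haplotypes i.i.d. from \code{haplotypeFreqs}; the empirical p value is
#' the proportion of replicates in which the target haplotype count
#' equals or exceeds \code{observedCount}. The raw proportion (which can
#' be 0) is reported alongside the (k+1)/(n+1) estimator and the exact
#' binomial upper-tail probability of the target's marginal.
#'
#' @param haplotypeFreqs named numeric frequencies summing to 1.
#' @param nEvents number of observed horizontal-transfer events.
#' @param observedCount observed target-haplotype event count.
#' @param target target haplotype name.
#' @param replicates Monte-Carlo replicates (default 10000).
#' @param seed randomisation seed (default 76).
#' @param restrictedToPairs set when \code{nEvents}/\code{observedCount}
#'   were restricted to events with a sampled matched host; recorded in
#'   the result, the computation is identical.
#' @return an \linkS4class{EnrichmentResult}.
#' @export
enrichmentTest <- function(haplotypeFreqs, nEvents, observedCount, target,
                           replicates = 10000L, seed = 76L,
                           restrictedToPairs = FALSE) {
  if (abs(sum(haplotypeFreqs) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1")
  if (!target %in% names(haplotypeFreqs))
    stop("target haplotype absent from frequencies: ", target)
  if (observedCount < 0L || observedCount > nEvents)
    stop("observedCount must lie in [0, nEvents]")
  set.seed(seed)
  draws <- matrix(sample(names(haplotypeFreqs), nEvents * replicates,
                         replace = TRUE, prob = haplotypeFreqs),
                  nrow = nEvents)
  k <- colSums(draws == target)
  hits <- sum(k >= observedCount)
  new("EnrichmentResult", target = target, nEvents = as.integer(nEvents),
      observedCount = as.integer(observedCount),
      replicates = as.integer(replicates), seed = as.integer(seed),
      empiricalP = hits / replicates,
      empiricalPSmoothed = (hits + 1) / (replicates + 1),
      exactP = exactTailProbability(haplotypeFreqs[[target]], nEvents,
                                    observedCount),
      restrictedToPairs = isTRUE(restrictedToPairs))
}

#' Exact binomial upper tail
#'
#' P(X >= k) for X ~ Binomial(n, freq), computed by direct summation of
#' the probability mass terms. Serves as the closed-form oracle for the
#' empirical enrichment test (per-event categorical draws and a single
#' multinomial draw have the same target marginal).
#'
#' @param freq success probability in [0, 1].
#' @param n number of trials.
#' @param k threshold count.
#' @return probability.
#' @export
exactTailProbability <- function(freq, n, k) {
  stopifnot(freq >= 0, freq <= 1, k >= 0, k <= n)
  if (k == 0L) return(1)
  i <- seq.int(k, n)
  sum(choose(n, i) * freq^i * (1 - freq)^(n - i))
}

#' Calibrate the somatic mtDNA mutation rate
#'
#' Anchors the molecular clock on a dated lineage divergence: the rate is
#' the mean somatic mutation count divided by the divergence time, with
#' the interval obtained by dividing by the divergence-time interval
#' bounds (older divergence bound gives the lower rate bound).
#'
#' @param meanMutations mean somatic mtDNA mutation count since the
#'   divergence (e.g. 9.437 for the second tumour lineage).
#' @param divergenceYears divergence-time point estimate in years.
#' @param divergenceInterval length-2 numeric, divergence-time interval
#'   in years (e.g. a 95\% highest-posterior-density interval).
#' @return a \linkS4class{RateEstimate} in mutations per year.
#' @export
calibrateRate <- function(meanMutations, divergenceYears,
                          divergenceInterval) {
  if (meanMutations <= 0) stop("meanMutations must be > 0")
  if (divergenceYears <= 0 || any(divergenceInterval <= 0))
    stop("divergence times must be > 0")
  lo <- min(divergenceInterval)
  hi <- max(divergenceInterval)
  new("RateEstimate", point = meanMutations / divergenceYears,
      low = meanMutations / hi, high = meanMutations / lo,
      meanMutations = meanMutations, divergenceYears = divergenceYears,
      divergenceInterval = c(lo, hi))
}

#' Date a horizontal-transfer event from its somatic burden
#'
#' Years since transfer = somatic mutation count / mutation rate, with
#' the interval from the rate interval. The count should include only
#' confident polymorphic somatic variants, excluding variants whose
#' germline or somatic status is unknown (see
#' \code{\link{classifyGroupVariants}}).
#'
#' @param somaticCount mean (or single) somatic mutation count, >= 0.
#' @param rateEstimate a \linkS4class{RateEstimate}.
#' @return list with \code{years} and \code{interval} (low, high).
#' @export
dateHtEvent <- function(somaticCount, rateEstimate) {
  stopifnot(is(rateEstimate, "RateEstimate"), somaticCount >= 0)
  list(years = somaticCount / rateEstimate@point,
       interval = c(low = somaticCount / rateEstimate@high,
                    high = somaticCount / rateEstimate@low))
}
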