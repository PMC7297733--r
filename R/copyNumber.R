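#' @include AllClasses.R
NULL

#' Nuclear tumour fraction from the somatic VAF mode
#'
#' Tumour purity under diploidy is twice the modal somatic variant allele
#' fraction, capped at 1. The mode is estimated by a fixed-bin histogram
#' over (0.05, 0.95] with bin width 0.02 (mode = midpoint of the maximal
#' bin; ties resolve to the lower bin), a reproducible stand-in for the
#' unstated mode procedure.
#'
#' @param somaticVafs numeric VAFs of somatic nuclear variants; at least
#'   20 observations in (0, 1) are required.
#' @param binWidth histogram bin width.
#' @return tumour fraction in (0, 1].
#' @export
estimateNuclearTumourFraction <- function(somaticVafs, binWidth = 0.02) {
  v <- somaticVafs[!is.na(somaticVafs)]
  if (sum(v > 0 & v < 1) < 20L)
    stop("need >= 20 somatic VAF observations in (0, 1)")
  breaks <- seq(0.05, 0.95, by = binWidth)
  v <- v[v > breaks[1L] & v <= breaks[length(breaks)]]
  bin <- findInterval(v, breaks, left.open = TRUE, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  modeBin <- which.max(counts)                 # ties -> lower bin
  mode <- breaks[modeBin] + binWidth / 2
  min(1, 2 * mode)
}

#' Mitochondrial tumour fraction from homoplasmic variant VAFs
#'
#' The fraction of a tumour's mtDNA molecules that are tumour-derived,
#' estimated as the median VAF of tumour-specific homoplasmic mtDNA
#' variants (host-derived molecules dilute every such variant equally).
#'
#' @param mtSomaticVafs numeric VAFs of tumour-specific homoplasmic mtDNA
#'   variants (>= 1 required).
#' @return fraction in (0, 1].
#' @export
estimateMtTumourFraction <- function(mtSomaticVafs) {
  v <- mtSomaticVafs[!is.na(mtSomaticVafs)]
  if (!length(v)) stop("need >= 1 tumour-specific mtDNA variant VAF")
  median(v)
}

#' mtDNA copy number per cell
#'
#' Copies per cell = (mtCOV-T / nuclCOV-T) x P, where mtCOV-T is the mean
#' mitochondrial coverage times the mtDNA tumour fraction, nuclCOV-T the
#' mean nuclear coverage times the nuclear tumour fraction, and P the
#' ploidy (2 for these tumours and dogs). Invariant under uniform scaling
#' of both coverages.
#'
#' @param mtCoverage mean coverage across the mitochondrial genome.
#' @param nuclearCoverage mean coverage across the nuclear genome.
#' @param mtFraction mitochondrial tumour fraction in (0, 1].
#' @param nuclearFraction nuclear tumour fraction in (0, 1].
#' @param ploidy ploidy P (default 2).
#' @return mtDNA copies per cell.
#' @export
mtdnaCopyNumber <- function(mtCoverage, nuclearCoverage, mtFraction,
                            nuclearFraction, ploidy = 2) {
  stopifnot(mtCoverage > 0, nuclearCoverage > 0, ploidy >= 1)
  if (any(c(mtFraction, nuclearFraction) <= 0) ||
      any(c(mtFraction, nuclearFraction) > 1))
    stop("tumour fractions must lie in (0, 1]")
  denom <- nuclearCoverage * nuclearFraction
  if (denom == 0) stop("zero denominator")
  (mtCoverage * mtFraction) / denom * ploidy
}

#' Pooled-variance two-sample t test
#'
#' Classical unpaired two-tailed Student's t test (equal-variance pooled
#' form) for comparing copy number between haplotype groups.
#'
#' @param valuesA,valuesB numeric vectors, each with >= 2 values.
#' @return list with \code{t} and \code{p}.
#' @export
compareGroupsTtest <- function(valuesA, valuesB) {
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    stop("each group needs >= 2 values")
  if (var(c(valuesA, valuesB)) == 0)
    stop("degenerate variance: all values identical")
  fit <- t.test(valuesA, valuesB, var.equal = TRUE,
                alternative = "two.sided")
  list(t = unname(fit$statistic), p = fit$p.value)
}
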