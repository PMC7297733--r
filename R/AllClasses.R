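#' @import methods
#' @importFrom stats median rbinom rmultinom rnbinom rnorm rpois runif
#'   setNames quantile model.matrix p.adjust qpois t.test wilcox.test
#'   var lm.fit as.dist C contr.sum
#' @importFrom utils head read.table write.table packageVersion
NULL

## Column layout shared by every variant-call table in the package.
.CALL_COLUMNS <- c("sample", "pos", "ref", "alt",
                   "supporting_reads", "total_reads", "vaf")

## Canine mtDNA length (CanFam3.1 convention); coordinates are 1-based,
## inclusive and circular.
.MT_GENOME_LENGTH <- 16727L

#' VariantTable: per-sample mtDNA variant calls
#'
#' Holds validated variant calls with read support and variant allele
#' fractions (VAF) on a circular mitochondrial genome. Positions are
#' 1-based; insertions are anchored at the base preceding the inserted
#' sequence (so the published control-region insertion of two cytosines is
#' stored as POS 16660, REF = anchor base, ALT = anchor + "CC").
#'
#' @slot calls data.frame with columns sample, pos, ref, alt,
#'   supporting_reads, total_reads, vaf.
#' @slot genomeLength single integer, circular genome length in bp.
#' @export
setClass("VariantTable",
         representation(calls = "data.frame", genomeLength = "integer"),
         prototype(calls = data.frame(sample = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      supporting_reads = integer(),
                                      total_reads = integer(),
                                      vaf = numeric()),
                   genomeLength = .MT_GENOME_LENGTH))

setValidity("VariantTable", function(object) {
  calls <- object@calls
  msg <- character()
  if (!all(.CALL_COLUMNS %in% names(calls)))
    return(paste("calls must have columns:",
                 paste(.CALL_COLUMNS, collapse = ", ")))
  if (length(object@genomeLength) != 1L || object@genomeLength <= 0L)
    msg <- c(msg, "genomeLength must be a single positive integer")
  if (nrow(calls)) {
    if (any(calls$pos < 1L | calls$pos > object@genomeLength))
      msg <- c(msg, "positions must lie in [1, genomeLength]")
    if (any(!nzchar(calls$ref)) || any(!nzchar(calls$alt)))
      msg <- c(msg, "ref and alt alleles must be non-empty")
    if (any(calls$supporting_reads > calls$total_reads, na.rm = TRUE))
      msg <- c(msg, "supporting_reads must not exceed total_reads")
    ok <- !is.na(calls$total_reads) & calls$total_reads > 0 &
      !is.na(calls$supporting_reads)
    if (any(ok) && any(abs(calls$vaf[ok] -
            calls$supporting_reads[ok] / calls$total_reads[ok]) > 1e-6))
      msg <- c(msg, "vaf must equal supporting_reads/total_reads")
    if (any(calls$vaf < 0 | calls$vaf > 1))
      msg <- c(msg, "vaf must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' HaplotypeProfileSet: named haplogroup variant profiles
#'
#' Each haplogroup (e.g. A1d1a, A1e, B1) is defined by its set of variants
#' relative to a shared reference sequence.
#'
#' @slot profiles named list; each element a data.frame with pos, ref, alt.
#' @slot reference single character string, the reference sequence
#'   (circular; may be empty when only variant-set arithmetic is needed).
#' @slot genomeLength single integer.
#' @export
setClass("HaplotypeProfileSet",
         representation(profiles = "list", reference = "character",
                        genomeLength = "integer"),
         prototype(profiles = list(), reference = "",
                   genomeLength = .MT_GENOME_LENGTH))

setValidity("HaplotypeProfileSet", function(object) {
  msg <- character()
  nm <- names(object@profiles)
  if (length(object@profiles) && (is.null(nm) || anyDuplicated(nm)))
    msg <- c(msg, "profile names must be present and unique")
  for (p in object@profiles) {
    if (!all(c("pos", "ref", "alt") %in% names(p))) {
      msg <- c(msg, "each profile needs pos, ref, alt columns")
      break
    }
    if (nrow(p) && any(p$pos < 1L | p$pos > object@genomeLength)) {
      msg <- c(msg, "profile positions out of range")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: study conditions for synthetic cohorts
#'
#' Defaults reproduce the structure of the published 539-tumour cohort:
#' 19 horizontal-transfer events with the Table-1 donor haplotypes (11 of
#' them A1d1a), member counts summing to 539, heteroplasmic fractions 0.55
#' and 0.15 for the two heteroplasmic events, one recombinant event, a
#' somatic mutation clock of 0.0201 mutations/year and a host population of
#' 495 dogs drawn from 18 haplotype frequencies.
#'
#' @slot nDogs host-dog population size.
#' @slot haplotypeFreqs named numeric, haplotype frequencies summing to 1.
#' @slot nTumours number of tumours.
#' @slot nHtEvents number of horizontal-transfer events.
#' @slot htDonorHaplotypes donor haplotype per event (length nHtEvents), or
#'   character(0) to sample donors from haplotypeFreqs names.
#' @slot memberCounts tumours per event (length nHtEvents, sums to
#'   nTumours), or integer(0) for a random partition.
#' @slot mutationRate somatic mtDNA mutations per year.
#' @slot eventAges age in years of each event.
#' @slot heteroplasmyFractions per-event introduced-haplotype fraction in
#'   (0,1); NA means homoplasmic.
#' @slot incumbentHaplotypes per-event incumbent haplotype carried at
#'   1 - fraction in heteroplasmic/recombinant tumours; NA where unused.
#' @slot recombinantEventIndex index of the recombinant event, 0 for none.
#' @slot recombinantBreakpoints two circular breakpoint positions.
#' @slot genomeLength circular genome length (bp).
#' @slot seed integer seed for the single pseudo-random stream of the run.
#' @export
setClass("SimulationConfig",
         representation(nDogs = "integer", haplotypeFreqs = "numeric",
                        nTumours = "integer", nHtEvents = "integer",
                        htDonorHaplotypes = "character",
                        memberCounts = "integer",
                        mutationRate = "numeric", eventAges = "numeric",
                        heteroplasmyFractions = "numeric",
                        incumbentHaplotypes = "character",
                        recombinantEventIndex = "integer",
                        recombinantBreakpoints = "numeric",
                        genomeLength = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  f <- object@haplotypeFreqs
  if (is.null(names(f)) || !length(f))
    msg <- c(msg, "haplotypeFreqs must be a named numeric vector")
  else if (abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, sprintf("haplotypeFreqs must sum to 1 (got %.12f)", sum(f)))
  if (any(f < 0)) msg <- c(msg, "haplotypeFreqs must be non-negative")
  if (object@genomeLength <= 0L) msg <- c(msg, "genomeLength must be > 0")
  if (any(object@eventAges < 0)) msg <- c(msg, "eventAges must be >= 0")
  if (object@mutationRate < 0) msg <- c(msg, "mutationRate must be >= 0")
  if (object@nHtEvents > object@nTumours)
    msg <- c(msg, "n_ht_events exceeds n_tumours")
  if (length(object@htDonorHaplotypes) &&
      length(object@htDonorHaplotypes) != object@nHtEvents)
    msg <- c(msg, "htDonorHaplotypes must have length nHtEvents (or 0)")
  if (length(object@memberCounts)) {
    if (length(object@memberCounts) != object@nHtEvents)
      msg <- c(msg, "memberCounts must have length nHtEvents (or 0)")
    else if (sum(object@memberCounts) != object@nTumours)
      msg <- c(msg, "memberCounts must sum to nTumours")
    if (any(object@memberCounts < 1L))
      msg <- c(msg, "memberCounts must all be >= 1")
  }
  if (length(object@eventAges) != object@nHtEvents)
    msg <- c(msg, "eventAges must have length nHtEvents")
  hf <- object@heteroplasmyFractions
  if (length(hf) != object@nHtEvents)
    msg <- c(msg, "heteroplasmyFractions must have length nHtEvents")
  else if (any(!is.na(hf) & (hf <= 0 | hf >= 1)))
    msg <- c(msg, "heteroplasmy fractions must lie in (0, 1)")
  if (object@recombinantEventIndex > object@nHtEvents)
    msg <- c(msg, "recombinantEventIndex out of range")
  if (length(msg)) msg else TRUE
})

#' CtvtCohort: a simulated clonal-tumour cohort with ground truth
#'
#' @slot tree nuclear clonal phylogeny (ape phylo) with tumour tip labels.
#' @slot variants VariantTable of per-tumour mtDNA calls.
#' @slot profiles HaplotypeProfileSet used to build germline haplotypes.
#' @slot truth list with elements \code{tumours} and \code{events}
#'   (data.frames of per-tumour and per-event ground truth).
#' @slot config the SimulationConfig that generated the cohort.
#' @export
setClass("CtvtCohort",
         representation(tree = "ANY", variants = "VariantTable",
                        profiles = "HaplotypeProfileSet", truth = "list",
                        config = "SimulationConfig"))

setValidity("CtvtCohort", function(object) {
  msg <- character()
  if (!inherits(object@tree, "phylo"))
    msg <- c(msg, "tree must be an ape phylo object")
  else if (anyDuplicated(object@tree$tip.label))
    msg <- c(msg, "tree tip labels must be unique")
  if (!all(c("tumours", "events") %in% names(object@truth)))
    msg <- c(msg, "truth must contain 'tumours' and 'events'")
  if (length(msg)) msg else TRUE
})

#' HTEvent: one mtDNA horizontal-transfer event
#'
#' @slot id event identifier (e.g. "HT1").
#' @slot donor donor haplotype name.
#' @slot replaced replaced (incumbent) haplotype name or "Unknown".
#' @slot members tumour ids belonging to the event.
#' @slot heteroplasmyFractions introduced-haplotype fraction per member
#'   (1.0 when homoplasmic).
#' @slot location inferred sampling location or "ambiguous".
#' @slot somaticCounts per-member count of polymorphic somatic variants.
#' @slot fixedUnknown variant keys fixed in all members, somatic/germline
#'   status undetermined.
#' @export
setClass("HTEvent",
         representation(id = "character", donor = "character",
                        replaced = "character", members = "character",
                        heteroplasmyFractions = "numeric",
                        location = "character", somaticCounts = "numeric",
                        fixedUnknown = "character"),
         prototype(replaced = "Unknown", location = "ambiguous",
                   heteroplasmyFractions = numeric(),
                   somaticCounts = numeric(), fixedUnknown = character()))

setValidity("HTEvent", function(object) {
  msg <- character()
  if (!length(object@members)) msg <- c(msg, "members must be non-empty")
  hf <- object@heteroplasmyFractions
  if (length(hf) && any(hf <= 0 | hf > 1))
    msg <- c(msg, "heteroplasmy fractions must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' HeteroplasmyCall: haplotype composition of one tumour
#'
#' @slot tumour tumour id.
#' @slot fractions named numeric haplotype fractions (sum to 1 +- 0.02).
#' @slot hostHaplotype matched host germline haplotype (or NA).
#' @slot heteroplasmic logical flag.
#' @export
setClass("HeteroplasmyCall",
         representation(tumour = "character", fractions = "numeric",
                        hostHaplotype = "character",
                        heteroplasmic = "logical"))

setValidity("HeteroplasmyCall", function(object) {
  if (!length(object@fractions)) return("fractions must be non-empty")
  if (abs(sum(object@fractions) - 1) > 0.02)
    return("fractions must sum to 1 (tolerance 0.02)")
  TRUE
})

#' RateEstimate: somatic mtDNA mutation rate with uncertainty
#'
#' @slot point point rate, mutations per year.
#' @slot low,high interval bounds (mutations per year).
#' @slot meanMutations mean somatic mutation count used as anchor.
#' @slot divergenceYears divergence-time anchor in years.
#' @slot divergenceInterval anchor uncertainty interval in years.
#' @export
setClass("RateEstimate",
         representation(point = "numeric", low = "numeric", high = "numeric",
                        meanMutations = "numeric",
                        divergenceYears = "numeric",
                        divergenceInterval = "numeric"))

setValidity("RateEstimate", function(object) {
  if (object@low > object@point || object@point > object@high)
    return("rate interval must satisfy low <= point <= high")
  if (any(c(object@point, object@low, object@high) <= 0))
    return("rates must be positive")
  TRUE
})

#' EnrichmentResult: donor-haplotype enrichment test outcome
#'
#' @slot target target haplotype name.
#' @slot nEvents number of observed horizontal-transfer events.
#' @slot observedCount observed number of target-haplotype events.
#' @slot replicates Monte-Carlo replicates.
#' @slot seed randomisation seed.
#' @slot empiricalP raw empirical upper-tail p (can be 0).
#' @slot empiricalPSmoothed (k+1)/(n+1) estimator, never 0.
#' @slot exactP exact binomial upper-tail probability (oracle).
#' @slot restrictedToPairs whether only matched tumour-host pairs entered.
#' @export
setClass("EnrichmentResult",
         representation(target = "character", nEvents = "integer",
                        observedCount = "integer", replicates = "integer",
                        seed = "integer", empiricalP = "numeric",
                        empiricalPSmoothed = "numeric", exactP = "numeric",
                        restrictedToPairs = "logical"))

setValidity("EnrichmentResult", function(object) {
  if (object@replicates <= 0L) return("replicates must be > 0")
  if (object@empiricalP < 0 || object@empiricalP > 1)
    return("empirical p must lie in [0, 1]")
  TRUE
})

#' PhasedHaplotypes: recombinant haplotypes phased from long reads
#'
#' @slot sites informative site positions (circular coordinates).
#' @slot patterns matrix of consensus alleles ("A"/"B"/NA), one row per
#'   haplotype, columns = sites.
#' @slot frequencies haplotype frequencies (sum + unassigned = 1).
#' @slot lowLevel logical, frequency below the reporting threshold.
#' @slot nReads supporting reads per haplotype.
#' @slot unassignedFraction fraction of reads not assignable to a single
#'   haplotype.
#' @export
setClass("PhasedHaplotypes",
         representation(sites = "numeric", patterns = "matrix",
                        frequencies = "numeric", lowLevel = "logical",
                        nReads = "integer", unassignedFraction = "numeric"))

setValidity("PhasedHaplotypes", function(object) {
  if (sum(object@frequencies) > 1 + 1e-9)
    return("haplotype frequencies must sum to <= 1")
  if (abs(sum(object@frequencies) + object@unassignedFraction - 1) > 1e-6)
    return("frequencies plus unassigned fraction must sum to 1")
  TRUE
})
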