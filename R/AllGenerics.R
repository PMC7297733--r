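#' @include AllClasses.R
NULL

#' Accessors
#'
#' Slot access for the package's S4 containers.
#' @param object an mtHijack S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantCalls", function(object) standardGeneric("variantCalls"))
#' @rdname accessors
#' @export
setMethod("variantCalls", "VariantTable", function(object) object@calls)

#' @rdname accessors
#' @export
setGeneric("genomeLength", function(object) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setMethod("genomeLength", "VariantTable", function(object) object@genomeLength)
#' @rdname accessors
#' @export
setMethod("genomeLength", "HaplotypeProfileSet",
          function(object) object@genomeLength)
#' @rdname accessors
#' @export
setMethod("genomeLength", "SimulationConfig",
          function(object) object@genomeLength)

#' @rdname accessors
#' @export
setGeneric("sampleNames", function(object) standardGeneric("sampleNames"))
#' @rdname accessors
#' @export
setMethod("sampleNames", "VariantTable",
          function(object) unique(object@calls$sample))

#' @rdname accessors
#' @export
setGeneric("profileNames", function(object) standardGeneric("profileNames"))
#' @rdname accessors
#' @export
setMethod("profileNames", "HaplotypeProfileSet",
          function(object) names(object@profiles))

#' @rdname accessors
#' @export
setGeneric("profileVariants",
           function(object, name) standardGeneric("profileVariants"))
#' @rdname accessors
#' @param name haplotype profile name.
#' @export
setMethod("profileVariants", "HaplotypeProfileSet", function(object, name) {
  if (!name %in% names(object@profiles))
    stop("unknown haplotype: ", name)
  object@profiles[[name]]
})

#' @rdname accessors
#' @export
setGeneric("referenceSequence",
           function(object) standardGeneric("referenceSequence"))
#' @rdname accessors
#' @export
setMethod("referenceSequence", "HaplotypeProfileSet",
          function(object) object@reference)

#' @rdname accessors
#' @export
setGeneric("cohortTree", function(object) standardGeneric("cohortTree"))
#' @rdname accessors
#' @export
setMethod("cohortTree", "CtvtCohort", function(object) object@tree)

#' @rdname accessors
#' @export
setGeneric("cohortVariants", function(object) standardGeneric("cohortVariants"))
#' @rdname accessors
#' @export
setMethod("cohortVariants", "CtvtCohort", function(object) object@variants)

#' @rdname accessors
#' @export
setGeneric("cohortProfiles", function(object) standardGeneric("cohortProfiles"))
#' @rdname accessors
#' @export
setMethod("cohortProfiles", "CtvtCohort", function(object) object@profiles)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "CtvtCohort", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("cohortConfig", function(object) standardGeneric("cohortConfig"))
#' @rdname accessors
#' @export
setMethod("cohortConfig", "CtvtCohort", function(object) object@config)

#' @rdname accessors
#' @export
setGeneric("eventId", function(object) standardGeneric("eventId"))
#' @rdname accessors
#' @export
setMethod("eventId", "HTEvent", function(object) object@id)

#' @rdname accessors
#' @export
setGeneric("eventDonor", function(object) standardGeneric("eventDonor"))
#' @rdname accessors
#' @export
setMethod("eventDonor", "HTEvent", function(object) object@donor)

#' @rdname accessors
#' @export
setGeneric("eventReplaced", function(object) standardGeneric("eventReplaced"))
#' @rdname accessors
#' @export
setMethod("eventReplaced", "HTEvent", function(object) object@replaced)

#' @rdname accessors
#' @export
setGeneric("eventMembers", function(object) standardGeneric("eventMembers"))
#' @rdname accessors
#' @export
setMethod("eventMembers", "HTEvent", function(object) object@members)

#' @rdname accessors
#' @export
setGeneric("isHeteroplasmic", function(object) standardGeneric("isHeteroplasmic"))
#' @rdname accessors
#' @export
setMethod("isHeteroplasmic", "HTEvent", function(object) {
  length(object@heteroplasmyFractions) > 0 &&
    any(object@heteroplasmyFractions < 1)
})
#' @rdname accessors
#' @export
setMethod("isHeteroplasmic", "HeteroplasmyCall",
          function(object) object@heteroplasmic)

#' @rdname accessors
#' @export
setGeneric("haplotypeFractionsOf",
           function(object) standardGeneric("haplotypeFractionsOf"))
#' @rdname accessors
#' @export
setMethod("haplotypeFractionsOf", "HeteroplasmyCall",
          function(object) object@fractions)

#' @rdname accessors
#' @export
setGeneric("ratePoint", function(object) standardGeneric("ratePoint"))
#' @rdname accessors
#' @export
setMethod("ratePoint", "RateEstimate", function(object) object@point)

#' @rdname accessors
#' @export
setGeneric("rateInterval", function(object) standardGeneric("rateInterval"))
#' @rdname accessors
#' @export
setMethod("rateInterval", "RateEstimate",
          function(object) c(low = object@low, high = object@high))

#' @rdname accessors
#' @export
setGeneric("empiricalP", function(object) standardGeneric("empiricalP"))
#' @rdname accessors
#' @export
setMethod("empiricalP", "EnrichmentResult", function(object) object@empiricalP)

#' @rdname accessors
#' @export
setGeneric("exactP", function(object) standardGeneric("exactP"))
#' @rdname accessors
#' @export
setMethod("exactP", "EnrichmentResult", function(object) object@exactP)

#' @rdname accessors
#' @export
setGeneric("haplotypeFrequencies",
           function(object) standardGeneric("haplotypeFrequencies"))
#' @rdname accessors
#' @export
setMethod("haplotypeFrequencies", "PhasedHaplotypes",
          function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("haplotypeFrequencies", "SimulationConfig",
          function(object) object@haplotypeFreqs)

#' @rdname accessors
#' @export
setGeneric("haplotypePatterns",
           function(object) standardGeneric("haplotypePatterns"))
#' @rdname accessors
#' @export
setMethod("haplotypePatterns", "PhasedHaplotypes",
          function(object) object@patterns)

## ---- show methods -------------------------------------------------------

setMethod("show", "VariantTable", function(object) {
  cat("VariantTable:", nrow(object@calls), "calls,",
      length(unique(object@calls$sample)), "samples, genome",
      object@genomeLength, "bp (circular)\n")
  if (nrow(object@calls)) print(head(object@calls, 4L))
})

setMethod("show", "HaplotypeProfileSet", function(object) {
  cat("HaplotypeProfileSet:", length(object@profiles), "haplotypes;",
      "genome", object@genomeLength, "bp\n")
  if (length(object@profiles))
    cat("  ", paste(names(object@profiles), collapse = " "), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nDogs, "dogs,", object@nTumours,
      "tumours,", object@nHtEvents, "HT events, rate",
      object@mutationRate, "/yr, seed", object@seed, "\n")
})

setMethod("show", "CtvtCohort", function(object) {
  cat("CtvtCohort:", length(object@tree$tip.label), "tumours,",
      nrow(object@truth$events), "HT events,",
      nrow(object@variants@calls), "variant calls\n")
})

setMethod("show", "HTEvent", function(object) {
  cat(sprintf("HTEvent %s: donor %s, replaced %s, %d tumour(s), %s\n",
              object@id, object@donor, object@replaced,
              length(object@members),
              if (isHeteroplasmic(object))
                sprintf("heteroplasmic (%.0f%%)",
                        100 * mean(object@heteroplasmyFractions))
              else "homoplasmic"))
})

setMethod("show", "HeteroplasmyCall", function(object) {
  cat(sprintf("HeteroplasmyCall %s [%s]: %s\n", object@tumour,
              if (object@heteroplasmic) "heteroplasmic" else "homoplasmic",
              paste(sprintf("%s=%.2f", names(object@fractions),
                            object@fractions), collapse = ", ")))
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate: %.4f mutations/yr (%.4f-%.4f)\n",
              object@point, object@low, object@high))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult: %d/%d events for %s; empirical p = %.4g (exact %.4g)\n",
    object@observedCount, object@nEvents, object@target,
    object@empiricalP, object@exactP))
})

setMethod("show", "PhasedHaplotypes", function(object) {
  cat("PhasedHaplotypes:", nrow(object@patterns), "haplotypes over",
      length(object@sites), "informative sites; frequencies",
      paste(sprintf("%.2f", object@frequencies), collapse = "/"),
      sprintf("(unassigned %.2f)\n", object@unassignedFraction))
})
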