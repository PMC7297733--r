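#' @include AllClasses.R utils.R phyloCore.R
NULL

## Tip index sets of every node (tips = trivial clades), by ape node id.
.cladeTips <- function(tree) {
  nTip <- length(tree$tip.label)
  nAll <- nTip + tree$Nnode
  childrenOf <- split(tree$edge[, 2L], tree$edge[, 1L])
  tipsOf <- vector("list", nAll)
  for (i in seq_len(nTip)) tipsOf[[i]] <- i
  rec <- function(v) {
    kids <- childrenOf[[as.character(v)]]
    for (k in kids) if (k > nTip) rec(k)
    tipsOf[[v]] <<- sort(unlist(tipsOf[kids]))
  }
  rec(nTip + 1L)
  tipsOf
}

#' Detect mtDNA horizontal-transfer events
#'
#' Formalises "clustered together on both trees": tumours sharing a donor
#' haplotype are partitioned into maximal subsets that are the complete
#' tip set of a nuclear-tree clade containing only members of that subset
#' (mtDNA-side clustering is implied by the shared haplotype label). Each
#' subset is one horizontal-transfer event. Events whose members are
#' paraphyletic on the nuclear tree are split by this rule, never merged.
#'
#' @param tree rooted nuclear phylo tree whose tips are tumours.
#' @param tumourHaplotypes named character vector, tumour -> introduced
#'   mtDNA haplotype (see \code{\link{tumourHaplotypes}}).
#' @param heteroplasmyFractions optional named numeric, tumour ->
#'   introduced-haplotype fraction (defaults to 1, homoplasmic).
#' @return list of \linkS4class{HTEvent}, ordered by decreasing size then
#'   donor name, with ids "HT1", "HT2", ...
#' @export
detectHtEvents <- function(tree, tumourHaplotypes,
                           heteroplasmyFractions = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing <- setdiff(names(tumourHaplotypes), tips)
  if (length(missing))
    stop("tumour absent from tree: ", paste(missing, collapse = ", "))
  if (!all(tips %in% names(tumourHaplotypes)))
    stop("every tumour tip needs a haplotype label")
  nTip <- length(tips)
  lab <- tumourHaplotypes[tips]

  ## pure state per node: haplotype if all descendant tips agree, else NA
  childrenOf <- split(tree$edge[, 2L], tree$edge[, 1L])
  nAll <- nTip + tree$Nnode
  pure <- rep(NA_character_, nAll)
  pure[seq_len(nTip)] <- lab
  rec <- function(v) {
    kids <- childrenOf[[as.character(v)]]
    for (k in kids) if (k > nTip) rec(k)
    st <- unique(pure[kids])
    if (length(st) == 1L && !is.na(st)) pure[v] <<- st
  }
  root <- nTip + 1L
  rec(root)

  parentOf <- integer(nAll)
  parentOf[tree$edge[, 2L]] <- tree$edge[, 1L]
  isMaximal <- !is.na(pure) &
    (seq_len(nAll) == root | is.na(pure[pmax(parentOf, 1L)]))
  isMaximal[root] <- !is.na(pure[root])
  nodes <- which(isMaximal)

  tipsOf <- .cladeTips(tree)
  members <- lapply(nodes, function(v) tips[tipsOf[[v]]])
  donors <- pure[nodes]
  ord <- order(-lengths(members), donors,
               vapply(members, `[[`, "", 1L))
  events <- vector("list", length(nodes))
  for (i in seq_along(ord)) {
    m <- members[[ord[i]]]
    hf <- if (is.null(heteroplasmyFractions)) rep(1, length(m))
          else ifelse(is.na(heteroplasmyFractions[m]), 1,
                      heteroplasmyFractions[m])
    events[[i]] <- new("HTEvent", id = paste0("HT", i),
                       donor = donors[ord[i]], members = m,
                       heteroplasmyFractions = setNames(hf, m))
  }
  events
}

#' Infer the haplotype an event replaced
#'
#' The replaced (incumbent) haplotype is read off the nuclear tree as the
#' final Fitch most-parsimonious-reconstruction state at the parent of
#' the event's clade; a non-singleton state set, or an event clade at the
#' root, yields "Unknown".
#'
#' @param event an \linkS4class{HTEvent}.
#' @param tree rooted nuclear phylo tree.
#' @param tumourHaplotypes named character vector, tumour -> haplotype.
#' @param fit optional precomputed \code{\link{fitchParsimony}} result
#'   for \code{tree}/\code{tumourHaplotypes} (saves recomputation when
#'   interrogating many events of one cohort).
#' @return haplotype name or "Unknown".
#' @export
inferReplacedHaplotype <- function(event, tree, tumourHaplotypes,
                                   fit = NULL) {
  stopifnot(is(event, "HTEvent"), inherits(tree, "phylo"))
  m <- event@members
  nTip <- length(tree$tip.label)
  node <- if (length(m) == 1L) match(m, tree$tip.label)
          else ape::getMRCA(tree, m)
  if (is.na(node) || node == nTip + 1L) return("Unknown")
  parentOf <- integer(nTip + tree$Nnode)
  parentOf[tree$edge[, 2L]] <- tree$edge[, 1L]
  if (is.null(fit)) fit <- fitchParsimony(tree, tumourHaplotypes)
  st <- fit$final[[parentOf[node]]]
  if (length(st) == 1L) st else "Unknown"
}

#' Estimate per-haplotype fractions within one tumour
#'
#' Each haplotype's fraction is the median VAF of its private marker
#' variants (variants belonging to exactly one profile) observed in the
#' sample; haplotypes with no observed marker get 0 and fractions are
#' renormalised to sum to 1.
#'
#' @param object a \linkS4class{VariantTable}.
#' @param sample sample id.
#' @param profiles a \linkS4class{HaplotypeProfileSet}.
#' @return named numeric vector of fractions summing to 1 (possibly
#'   length 0 when no marker variant is observed).
#' @export
haplotypeFractions <- function(object, sample, profiles) {
  stopifnot(is(object, "VariantTable"), is(profiles, "HaplotypeProfileSet"))
  calls <- sampleCalls(object, sample)
  keys <- variantKeysOf(calls)
  allKeys <- lapply(profiles@profiles, variantKeysOf)
  tabulated <- table(unlist(allKeys))
  privateOf <- lapply(allKeys, function(k) k[tabulated[k] == 1L])
  ## median over ALL of the haplotype's markers, absent markers counting
  ## as 0: a stray somatic hit on one marker cannot fake a haplotype
  fr <- vapply(privateOf, function(mk) {
    if (!length(mk)) return(0)
    v <- calls$vaf[match(mk, keys)]
    v[is.na(v)] <- 0
    median(v)
  }, numeric(1L))
  fr <- fr[fr > 0]
  if (!length(fr)) return(fr)
  fr / sum(fr)
}

#' Call heteroplasmy in one tumour
#'
#' A tumour is heteroplasmic when two or more distinct mtDNA haplotypes
#' are each present above the frequency threshold (strictly more than
#' 10\% by default) after removing any haplotype explained by the matched
#' host dog's germline haplotype. Host removal precedes the threshold
#' test.
#'
#' @param fractions named numeric haplotype fractions (sum to 1, within
#'   0.02).
#' @param hostHaplotype matched host germline haplotype, or NA when no
#'   host was sampled.
#' @param threshold frequency threshold (strict inequality).
#' @param tumour tumour id recorded in the call.
#' @return a \linkS4class{HeteroplasmyCall}.
#' @export
callHeteroplasmy <- function(fractions, hostHaplotype = NA_character_,
                             threshold = 0.10, tumour = "tumour") {
  if (!length(fractions)) stop("fractions must be non-empty")
  informative <- fractions[is.na(hostHaplotype) |
                             names(fractions) != hostHaplotype]
  het <- sum(informative > threshold) >= 2L
  new("HeteroplasmyCall", tumour = tumour, fractions = fractions,
      hostHaplotype = as.character(hostHaplotype), heteroplasmic = het)
}

#' Classify an event's non-donor variants
#'
#' Variants absent from the donor profile but present in all members of
#' the event are fixed within the group and of undetermined
#' somatic/germline status ("fixed-unknown"); variants present in a
#' strict subset of members are confident polymorphic somatic mutations.
#' For a singleton event every private variant is fixed-unknown.
#'
#' @param event an \linkS4class{HTEvent}.
#' @param object a \linkS4class{VariantTable} covering all members.
#' @param donorProfile data.frame (pos, ref, alt) of the donor haplotype.
#' @return list with \code{somaticByMember} (named list of variant keys),
#'   \code{somaticCounts} (named integer per member), and
#'   \code{fixedUnknown} (variant keys).
#' @export
classifyGroupVariants <- function(event, object, donorProfile) {
  stopifnot(is(event, "HTEvent"), is(object, "VariantTable"))
  m <- event@members
  have <- m %in% object@calls$sample
  if (!all(have))
    stop("event members missing from variant table: ",
         paste(m[!have], collapse = ", "))
  donorKeys <- variantKeysOf(donorProfile)
  keysBy <- lapply(m, function(s) {
    calls <- sampleCalls(object, s)
    setdiff(variantKeysOf(calls[calls$vaf > 0, , drop = FALSE]), donorKeys)
  })
  names(keysBy) <- m
  carriers <- table(unlist(keysBy))
  fixed <- names(carriers)[carriers == length(m)]
  somaticByMember <- lapply(keysBy, function(k) setdiff(k, fixed))
  counts <- lengths(somaticByMember)
  list(somaticByMember = somaticByMember,
       somaticCounts = setNames(as.integer(counts), m),
       fixedUnknown = sort(fixed))
}

#' Infer the geographic origin of an event
#'
#' Unanimous member locations give the location directly; otherwise the
#' Fitch most-parsimonious-reconstruction state of the event's clade on
#' the nuclear tree is used if it is a singleton, else "ambiguous".
#'
#' @param event an \linkS4class{HTEvent}.
#' @param sampleLocations named character vector, tumour -> location.
#' @param tree optional rooted nuclear phylo tree (needed only for the
#'   parsimony fallback; it requires locations for all tips).
#' @return location string or "ambiguous".
#' @export
inferEventLocation <- function(event, sampleLocations, tree = NULL) {
  stopifnot(is(event, "HTEvent"))
  m <- event@members
  loc <- sampleLocations[m]
  if (any(is.na(loc)))
    stop("missing location for: ", paste(m[is.na(loc)], collapse = ", "))
  u <- unique(loc)
  if (length(u) == 1L) return(unname(u))
  if (is.null(tree)) return("ambiguous")
  node <- ape::getMRCA(tree, m)
  fit <- fitchParsimony(tree, sampleLocations)
  st <- fit$final[[node]]
  if (length(st) == 1L) st else "ambiguous"
}

#' Variants specific to one haplogroup
#'
#' Variants present in the target haplotype's profile and absent from all
#' other profiles, except those listed in \code{allowSharedWith} (e.g.
#' the closely related parent haplotype).
#'
#' @param target target haplotype name.
#' @param profiles a \linkS4class{HaplotypeProfileSet}.
#' @param allowSharedWith haplotype names allowed to share the variants.
#' @return character vector of variant keys.
#' @export
discoverHaplotypeSpecificVariants <- function(target, profiles,
                                              allowSharedWith = character()) {
  stopifnot(is(profiles, "HaplotypeProfileSet"))
  if (!target %in% names(profiles@profiles))
    stop("unknown haplotype: ", target)
  targetKeys <- variantKeysOf(profiles@profiles[[target]])
  others <- setdiff(names(profiles@profiles), c(target, allowSharedWith))
  otherKeys <- unique(unlist(lapply(profiles@profiles[others],
                                    variantKeysOf)))
  sort(setdiff(targetKeys, otherKeys))
}

#' Count independent somatic occurrences of a variant
#'
#' Counts tumours carrying the variant whose assigned haplotype is not in
#' \code{excludeHaplotypes} (to exclude germline carriers of the variant),
#' collapsing carriers that belong to the same horizontal-transfer event
#' to a single occurrence.
#'
#' @param variant variant key or list/row with pos, ref, alt.
#' @param object a \linkS4class{VariantTable}.
#' @param tumourHaplotypes named character vector, tumour -> haplotype.
#' @param excludeHaplotypes haplotypes whose carriers are not counted.
#' @param events optional list of \linkS4class{HTEvent} used to collapse
#'   same-event carriers.
#' @return integer count of independent somatic occurrences.
#' @export
countSomaticRecurrence <- function(variant, object, tumourHaplotypes,
                                   excludeHaplotypes = character(),
                                   events = NULL) {
  stopifnot(is(object, "VariantTable"))
  key <- if (is.character(variant) && length(variant) == 1L) variant
         else variantKey(variant$pos, variant$ref, variant$alt)
  calls <- object@calls
  carriers <- unique(calls$sample[variantKeysOf(calls) == key &
                                    calls$vaf > 0])
  carriers <- carriers[!(tumourHaplotypes[carriers] %in% excludeHaplotypes)]
  if (!length(carriers)) return(0L)
  if (is.null(events)) return(length(carriers))
  eventOf <- character()
  for (e in events) eventOf[e@members] <- e@id
  grp <- eventOf[carriers]
  grp[is.na(grp)] <- paste0(".solo", seq_len(sum(is.na(grp))))
  length(unique(grp))
}

#' Tabulate detected events
#'
#' One row per event mirroring the published summary-table layout: id,
#' donor haplotype, replaced haplotype, number of tumours, percentage
#' heteroplasmy and location.
#'
#' @param events list of \linkS4class{HTEvent}.
#' @return data.frame.
#' @export
htEventTable <- function(events) {
  do.call(rbind, lapply(events, function(e) {
    data.frame(event = e@id, donor = e@donor, replaced = e@replaced,
               n_tumours = length(e@members),
               percent_heteroplasmy =
                 round(100 * mean(e@heteroplasmyFractions), 1L),
               location = e@location, stringsAsFactors = FALSE)
  }))
}
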