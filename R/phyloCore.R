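#' @include AllClasses.R utils.R
NULL

#' Proportion of differing sites (p-distance)
#'
#' For two equal-length sequences, the fraction of mismatching positions;
#' for two variant sets (character vectors of variant keys), the size of
#' their symmetric difference divided by \code{nSites}.
#'
#' @param a,b sequences (single strings) or variant-key vectors.
#' @param nSites number of compared sites; defaults to the sequence
#'   length in sequence mode and is required in variant-set mode.
#' @return numeric fraction in [0, 1].
#' @export
pDistance <- function(a, b, nSites = NULL) {
  seqMode <- is.character(a) && length(a) == 1L && is.character(b) &&
    length(b) == 1L && nchar(a) > 1L && nchar(a) == nchar(b)
  if (seqMode) {
    if (is.null(nSites)) nSites <- nchar(a)
    if (nSites <= 0) stop("nSites must be > 0")
    sa <- strsplit(a, "")[[1L]]
    sb <- strsplit(b, "")[[1L]]
    return(sum(sa != sb) / nSites)
  }
  if (is.null(nSites) || nSites <= 0) stop("nSites must be > 0")
  length(union(setdiff(a, b), setdiff(b, a))) / nSites
}

#' Neighbour-joining tree
#'
#' Builds an unrooted NJ tree from a symmetric distance matrix (standard
#' Saitou-Nei algorithm via \pkg{ape}). Output is deterministic for a
#' given taxon order; Q-criterion ties are resolved by the first pair in
#' input order.
#'
#' @param d distance matrix (matrix or dist) over >= 3 taxa.
#' @return an \pkg{ape} phylo tree.
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbour joining needs at least 3 taxa")
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  ape::nj(as.dist(d))
}

#' Newick tree I/O
#'
#' Thin validated wrappers over \pkg{ape}'s newick parser/writer.
#' Round-trips preserve topology, tip labels and branch lengths.
#'
#' @param path file path.
#' @return \code{readNewickTree}: a phylo tree.
#' @export
readNewickTree <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stop("cannot parse newick file: ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in ", path)
  tree
}

#' @rdname readNewickTree
#' @param tree a phylo tree.
#' @export
writeNewickTree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Assign a sample to its nearest haplogroup profile
#'
#' Returns the profile minimising the symmetric-difference distance
#' between the sample's variant set and the profile's variant set. Ties
#' at the minimum resolve to the lexicographically smallest name and set
#' the ambiguity flag. An automatable equivalent of tree-topology
#' haplogroup assignment when profiles are distinct.
#'
#' @param sampleVariants character vector of variant keys (see
#'   \code{\link{variantKey}}) or data.frame with pos/ref/alt.
#' @param profiles a \linkS4class{HaplotypeProfileSet}.
#' @return list with \code{haplotype}, \code{distance}, \code{ambiguous}.
#' @export
assignHaplotype <- function(sampleVariants, profiles) {
  stopifnot(is(profiles, "HaplotypeProfileSet"))
  if (!length(profiles@profiles)) stop("profiles must be non-empty")
  if (is.data.frame(sampleVariants))
    sampleVariants <- variantKeysOf(sampleVariants)
  d <- vapply(profiles@profiles, function(p) {
    k <- variantKeysOf(p)
    length(setdiff(sampleVariants, k)) + length(setdiff(k, sampleVariants))
  }, numeric(1L))
  d <- d[order(names(d))]            # lexicographic tie-break
  best <- which(d == min(d))
  list(haplotype = names(d)[best[1L]], distance = unname(min(d)),
       ambiguous = length(best) >= 2L)
}

#' Haplotype labels for every sample of a variant table
#'
#' Assigns each sample's dominant variant set (calls with VAF above
#' \code{vafThreshold}) to its nearest profile.
#'
#' @param object a \linkS4class{VariantTable}.
#' @param profiles a \linkS4class{HaplotypeProfileSet}.
#' @param vafThreshold minimum VAF for a call to enter the dominant set.
#' @return named character vector, sample -> haplotype.
#' @export
tumourHaplotypes <- function(object, profiles, vafThreshold = 0.5) {
  stopifnot(is(object, "VariantTable"))
  calls <- object@calls[object@calls$vaf > vafThreshold, , drop = FALSE]
  keysBySample <- split(variantKeysOf(calls), calls$sample)
  vapply(keysBySample, function(k)
    assignHaplotype(k, profiles)$haplotype, "")
}

#' Fitch parsimony with full MPR state sets
#'
#' Two-pass Fitch over an arbitrary discrete character: the bottom-up
#' pass uses Hartigan's counting rule (exact on multifurcations) to get
#' the minimum change count and preliminary state sets; the top-down pass
#' applies the standard refinement rules to obtain the final
#' most-parsimonious-reconstruction state set of every internal node.
#'
#' @param tree rooted phylo tree.
#' @param tipLabels named character vector, tip label -> state.
#' @return list with \code{changes} (parsimony minimum), \code{prelim}
#'   and \code{final} (lists of state sets indexed by ape node number)
#'   and \code{rootStates}.
#' @export
fitchParsimony <- function(tree, tipLabels) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(tips %in% names(tipLabels)) || any(is.na(tipLabels[tips])))
    stop("every tip must have a state label")
  nTip <- length(tips)
  nAll <- nTip + tree$Nnode
  childrenOf <- split(tree$edge[, 2L], tree$edge[, 1L])
  prelim <- vector("list", nAll)
  final <- vector("list", nAll)
  for (i in seq_len(nTip)) prelim[[i]] <- unname(tipLabels[tips[i]])
  changes <- 0L

  down <- function(v) {            # bottom-up: Hartigan counting rule
    kids <- childrenOf[[as.character(v)]]
    for (k in kids) if (k > nTip) down(k)
    counts <- table(unlist(lapply(kids, function(k) prelim[[k]])))
    kmax <- max(counts)
    prelim[[v]] <<- sort(names(counts)[counts == kmax])
    changes <<- changes + length(kids) - kmax
  }
  up <- function(v) {              # top-down MPR refinement
    kids <- childrenOf[[as.character(v)]]
    for (k in kids) {
      if (k <= nTip) next
      fu <- final[[v]]
      pv <- prelim[[k]]
      gkids <- childrenOf[[as.character(k)]]
      childUnion <- sort(unique(unlist(prelim[gkids])))
      final[[k]] <<- if (all(fu %in% pv)) fu
      else if (!length(Reduce(intersect, prelim[gkids])))
        sort(union(pv, fu))                       # node formed by union
      else sort(union(pv, intersect(fu, childUnion)))
      up(k)
    }
  }

  root <- nTip + 1L
  down(root)
  final[[root]] <- prelim[[root]]
  for (i in seq_len(nTip)) final[[i]] <- prelim[[i]]
  up(root)
  list(changes = changes, prelim = prelim, final = final,
       rootStates = final[[root]])
}
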