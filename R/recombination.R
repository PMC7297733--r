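#' @include AllClasses.R utils.R
NULL

#' Read long-read allele patterns
#'
#' Long-format TSV (read_id, pos, allele) of parental allele calls at
#' informative sites, converted to a reads x sites matrix with entries
#' "A" (first parent), "B" (second parent) or NA (site not called on the
#' read).
#'
#' @param path TSV path.
#' @return character matrix, rows = reads, columns = site positions.
#' @export
readAllelePatterns <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("read_id", "pos", "allele")
  if (!all(need %in% names(tab)))
    stop("allele-pattern TSV needs columns: ", paste(need, collapse = ", "))
  sites <- sort(unique(tab$pos))
  reads <- unique(tab$read_id)
  m <- matrix(NA_character_, length(reads), length(sites),
              dimnames = list(reads, sites))
  m[cbind(match(tab$read_id, reads), match(tab$pos, sites))] <- tab$allele
  m
}

#' Phase recombinant haplotypes from long-read allele patterns
#'
#' Reads are clustered by exact allele-pattern agreement over the
#' informative sites, with missing calls acting as wildcards: complete
#' reads seed the clusters (largest first); a read with missing sites
#' joins the largest compatible cluster, ties leave it in the unassigned
#' pool, and incompatible partial patterns form their own clusters.
#' Haplotypes below \code{minReportFraction} are flagged low-level but
#' never dropped. Consensus alleles are per-site majorities over cluster
#' members.
#'
#' @param reads character matrix from \code{\link{readAllelePatterns}}
#'   (entries "A"/"B"/NA), columns named by site position.
#' @param minReportFraction reporting threshold for the low-level flag.
#' @return a \linkS4class{PhasedHaplotypes}, haplotypes ordered by
#'   decreasing frequency.
#' @export
phaseLongReads <- function(reads, minReportFraction = 0.05) {
  stopifnot(is.matrix(reads))
  if (ncol(reads) < 2L)
    stop("no shared informative sites: need >= 2")
  if (nrow(reads) < 10L)
    stop("need >= 10 reads spanning the informative sites")
  nSites <- ncol(reads)
  complete <- !apply(is.na(reads), 1L, any)

  patStr <- apply(reads, 1L, function(r)
    paste(ifelse(is.na(r), "?", r), collapse = ""))
  seedTab <- sort(table(patStr[complete]), decreasing = TRUE)
  seedTab <- seedTab[order(-seedTab, names(seedTab))]   # tie: lexicographic
  clusterPat <- strsplit(names(seedTab), "")
  members <- lapply(names(seedTab), function(p)
    rownames(reads)[complete & patStr == p])
  sizes <- as.integer(seedTab)
  unassigned <- character()

  compatible <- function(r, p) {
    obs <- !is.na(r)
    all(r[obs] == p[obs] | p[obs] == "?")
  }
  for (id in rownames(reads)[!complete]) {
    r <- reads[id, ]
    hit <- which(vapply(clusterPat, compatible, TRUE, r = r))
    if (length(hit) == 0L) {
      ## new partial-pattern cluster (merge identical partial patterns)
      pat <- ifelse(is.na(r), "?", r)
      same <- which(vapply(clusterPat, function(p)
        identical(p, unname(pat)), TRUE))
      if (length(same)) {
        members[[same]] <- c(members[[same]], id)
        sizes[same] <- sizes[same] + 1L
      } else {
        clusterPat <- c(clusterPat, list(unname(pat)))
        members <- c(members, list(id))
        sizes <- c(sizes, 1L)
      }
    } else {
      best <- hit[sizes[hit] == max(sizes[hit])]
      if (length(best) > 1L) unassigned <- c(unassigned, id)
      else {
        members[[best]] <- c(members[[best]], id)
        sizes[best] <- sizes[best] + 1L
      }
    }
  }

  keep <- sizes > 0L
  members <- members[keep]
  sizes <- sizes[keep]
  consensus <- t(vapply(members, function(ids) {
    apply(reads[ids, , drop = FALSE], 2L, function(col) {
      col <- col[!is.na(col)]
      if (!length(col)) return(NA_character_)
      tab <- sort(table(col), decreasing = TRUE)
      if (length(tab) > 1L && tab[1L] == tab[2L]) NA_character_
      else names(tab)[1L]
    })
  }, character(nSites)))
  colnames(consensus) <- colnames(reads)

  ord <- order(-sizes)
  freqs <- sizes[ord] / nrow(reads)
  new("PhasedHaplotypes",
      sites = as.numeric(colnames(reads)),
      patterns = consensus[ord, , drop = FALSE],
      frequencies = unname(freqs),
      lowLevel = unname(freqs < minReportFraction),
      nReads = as.integer(sizes[ord]),
      unassignedFraction = length(unassigned) / nrow(reads))
}

#' Parental ancestry segments of a recombinant haplotype
#'
#' Minimal-breakpoint assignment of contiguous circular segments to the
#' two parents: each run of same-parent informative sites is one segment,
#' and breakpoints are placed midway between adjacent discordant sites
#' (walking forward around the circle, wrapping through the origin). On a
#' circular genome the breakpoint count is always even.
#'
#' @param pattern named character vector, site position -> "A" or "B"
#'   (one row of \code{haplotypePatterns}); every site must be diagnostic
#'   between the parents.
#' @param genomeLength circular genome length in bp.
#' @return list with \code{segments} (data.frame start, end, parent),
#'   \code{breakpoints} (positions) and \code{nBreakpoints}.
#' @export
segmentAncestry <- function(pattern, genomeLength = 16727L) {
  if (any(is.na(pattern)) || !all(pattern %in% c("A", "B")))
    stop("site not diagnostic between parents")
  pos <- as.numeric(names(pattern))
  ord <- order(pos)
  pos <- pos[ord]
  al <- pattern[ord]
  n <- length(pos)
  if (length(unique(al)) == 1L)
    return(list(segments = data.frame(start = 1, end = genomeLength,
                                      parent = al[[1L]]),
                breakpoints = numeric(), nBreakpoints = 0L))
  nxt <- c(seq_len(n)[-1L], 1L)
  disc <- which(al != al[nxt])
  bps <- vapply(disc, function(i)
    circMidpoint(pos[i], pos[nxt[i]], genomeLength), numeric(1L))
  ## walk segments breakpoint -> next breakpoint; parent = allele of the
  ## first informative site inside the segment
  ordBp <- order(bps)
  bps <- bps[ordBp]
  segStart <- bps
  segEnd <- c(bps[-1L], bps[1L])
  parent <- vapply(seq_along(bps), function(k) {
    s <- segStart[k]
    inside <- if (k < length(bps)) pos > s & pos <= segEnd[k]
              else pos > s | pos <= segEnd[k]
    al[inside][1L]
  }, "")
  list(segments = data.frame(start = circIndex(floor(segStart) + 1L,
                                               genomeLength),
                             end = floor(segEnd), parent = parent),
       breakpoints = bps, nBreakpoints = length(bps))
}

#' Variants fixed across all phased haplotypes
#'
#' Intersection of the donor-specific variant set with the variants
#' carried by every reported haplotype, including low-level ones.
#'
#' @param haplotypes list of character variant-key sets (one per
#'   haplotype), e.g. from \code{\link{carriedVariants}}.
#' @param donorSpecificVariants character vector of donor-specific
#'   variant keys.
#' @return character vector of variant keys.
#' @export
fixedVariants <- function(haplotypes, donorSpecificVariants) {
  if (!length(haplotypes)) stop("need >= 1 haplotype")
  sort(intersect(Reduce(intersect, haplotypes), donorSpecificVariants))
}

#' Donor variants carried by each phased haplotype
#'
#' Maps consensus allele patterns to variant keys: a haplotype carries
#' the donor variant at a site when its consensus allele there is "A"
#' (the donor-parent allele).
#'
#' @param phased a \linkS4class{PhasedHaplotypes}.
#' @param siteVariantKeys named character vector, site position ->
#'   donor variant key.
#' @return list of character variant-key sets, one per haplotype.
#' @export
carriedVariants <- function(phased, siteVariantKeys) {
  stopifnot(is(phased, "PhasedHaplotypes"))
  keys <- siteVariantKeys[as.character(phased@sites)]
  apply(phased@patterns, 1L, function(p)
    unname(keys[!is.na(p) & p == "A"]), simplify = FALSE)
}

#' Simulate a heteroplasmic recombinant mtDNA mixture
#'
#' Emulates a tumour in which a donor haplotype has recombined with the
#' incumbent mtDNA: several recombinant haplotypes segregate at given
#' frequencies, every haplotype carries the donor allele at one
#' universal site (the control-region insertion analogue), and ancestry
#' switches along the circular genome.
#'
#' @param frequencies haplotype frequencies (sum to 1); default three
#'   majors and two low-level haplotypes.
#' @param nSites number of informative sites.
#' @param universalSite index of the site fixed for the donor allele.
#' @param switchProb per-interval probability of switching parent.
#' @param genomeLength circular genome length.
#' @param seed integer seed.
#' @return list with \code{sites}, \code{patterns} (haplotype x site),
#'   \code{frequencies}, \code{universalSite} (position).
#' @export
simulateRecombinantMixture <- function(frequencies = c(0.42, 0.30, 0.20,
                                                       0.05, 0.03),
                                       nSites = 12L, universalSite = NULL,
                                       switchProb = 0.25,
                                       genomeLength = 16727L, seed = 1L) {
  stopifnot(abs(sum(frequencies) - 1) < 1e-9, nSites >= 3L)
  set.seed(seed)
  sites <- sort(c(16660, round(seq(400, genomeLength - 800,
                                   length.out = nSites - 1L))))
  if (is.null(universalSite)) universalSite <- which(sites == 16660)
  k <- length(frequencies)
  repeat {
    patterns <- t(vapply(seq_len(k), function(i) {
      al <- character(nSites)
      al[1L] <- sample(c("A", "B"), 1L)
      for (j in 2L:nSites)
        al[j] <- if (runif(1) < switchProb)
          setdiff(c("A", "B"), al[j - 1L]) else al[j - 1L]
      al[universalSite] <- "A"
      al
    }, character(nSites)))
    if (!anyDuplicated(apply(patterns, 1L, paste, collapse = ""))) break
  }
  colnames(patterns) <- sites
  rownames(patterns) <- paste0("H", seq_len(k))
  list(sites = sites, patterns = patterns, frequencies = frequencies,
       universalSite = sites[universalSite])
}

#' Simulate long reads from a recombinant mixture
#'
#' Draws each read's haplotype from the mixture frequencies and copies
#' its allele pattern; sequencing noise is modelled as per-site allele
#' dropout (missing calls), which the wildcard-matching phaser absorbs.
#'
#' @param mixture output of \code{\link{simulateRecombinantMixture}}.
#' @param nReads number of long reads.
#' @param dropout per-site missing-call probability.
#' @param seed integer seed.
#' @return character matrix of read allele patterns.
#' @export
simulateRecombinantReads <- function(mixture, nReads = 150L,
                                     dropout = 0.02, seed = 1L) {
  set.seed(seed)
  idx <- sample(nrow(mixture$patterns), nReads, replace = TRUE,
                prob = mixture$frequencies)
  reads <- mixture$patterns[idx, , drop = FALSE]
  rownames(reads) <- sprintf("read%04d", seq_len(nReads))
  drop <- matrix(runif(length(reads)) < dropout, nrow(reads))
  reads[drop] <- NA_character_
  reads
}
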