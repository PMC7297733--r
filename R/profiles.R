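#' @include AllClasses.R utils.R
NULL

## Deterministic builders for the synthetic reference genome, the 18-name
## haplogroup profile panel and the host-population haplotype frequencies.
## These are stand-ins: the published profile definitions and population
## frequencies live in restricted supplementary material, so the package
## ships synthetic equivalents with the same structure (names, nesting,
## marquee variants) and accepts user-supplied real tables everywhere.

## Internal constant seed: the reference and profiles are fixtures, not
## draws, so they are identical in every session.
.REFERENCE_SEED <- 1203L

#' Synthetic circular mtDNA reference sequence
#'
#' A deterministic random sequence standing in for the canine
#' mitochondrial reference (same length, 16727 bp). It is constant across
#' calls and does not consume the caller's random stream.
#'
#' @param genomeLength genome length in bp.
#' @return single character string of A/C/G/T.
#' @export
syntheticReference <- function(genomeLength = 16727L) {
  withLocalSeed(.REFERENCE_SEED, {
    paste(sample(c("A", "C", "G", "T"), genomeLength, replace = TRUE),
          collapse = "")
  })
}

## Transition partner of each base (used for synthetic substitution alts).
.transition <- c(A = "G", G = "A", C = "T", T = "C")

#' Synthetic haplogroup profile panel
#'
#' Builds variant-set profiles for the 18 canine mtDNA haplogroup names
#' used in transmissible-cancer host populations (A1, A1a1, A1b, A1c,
#' A1d1, A1d1a, A1d2, A1e, A1f, A1h, A2, A4, A5, A6, B1, B2, C1, C2),
#' nested cladistically: clade-shared variant blocks (A, A1, A1d, A1d1
#' branch, B, C) plus private variants per haplotype. The A1d1a profile
#' carries exactly eight private substitutions (among them the
#' non-synonymous 7593T>C analogue) and one private control-region
#' insertion of two cytosines at 16660 (16660insCC); 16672C>T sits on the
#' A1d1 branch and is therefore shared between A1d1 and A1d1a.
#'
#' @param nExtra number of additional unrelated synthetic haplogroups
#'   ("X1", "X2", ...) appended for stress tests needing more than 18
#'   distinct donors; each gets 20 private variants.
#' @param nPrivate private variants per standard haplotype (A1d1a is fixed
#'   at 9 to mirror the published count).
#' @param genomeLength genome length in bp.
#' @return a \linkS4class{HaplotypeProfileSet}.
#' @export
syntheticProfiles <- function(nExtra = 0L, nPrivate = 15L,
                              genomeLength = 16727L) {
  ref <- syntheticReference(genomeLength)
  baseAt <- function(p) substr(ref, p, p)
  special <- c(16660L, 16672L, 7593L)

  ## deterministic pool of well-spaced positions, skipping marquee sites
  pool <- seq(101L, genomeLength - 200L, by = 7L)
  pool <- setdiff(pool, special)
  cursor <- 0L
  takePos <- function(n) {
    idx <- cursor + seq_len(n)
    cursor <<- cursor + n
    pool[idx]
  }
  snpBlock <- function(n, extraPos = integer()) {
    p <- sort(c(takePos(n - length(extraPos)), extraPos))
    data.frame(pos = p, ref = vapply(p, baseAt, ""),
               alt = unname(.transition[vapply(p, baseAt, "")]),
               stringsAsFactors = FALSE)
  }

  bA    <- snpBlock(6L)                      # all A haplotypes
  bA1   <- snpBlock(6L)                      # the A1 subclade
  bA1d  <- snpBlock(5L)                      # A1d1, A1d1a, A1d2
  bA1d1 <- snpBlock(5L, extraPos = 16672L)   # A1d1 branch: A1d1 + A1d1a
  bB    <- snpBlock(12L)                     # B1, B2
  bC    <- snpBlock(12L)                     # C1, C2

  a1d1aPrivate <- rbind(
    snpBlock(8L, extraPos = 7593L),          # eight private SNPs
    data.frame(pos = 16660L, ref = baseAt(16660L),
               alt = paste0(baseAt(16660L), "CC"),   # 16660insCC analogue
               stringsAsFactors = FALSE))

  names18 <- c("A1", "A1a1", "A1b", "A1c", "A1d1", "A1d1a", "A1d2", "A1e",
               "A1f", "A1h", "A2", "A4", "A5", "A6", "B1", "B2", "C1", "C2")
  shared <- list(
    A1    = rbind(bA, bA1),       A1a1 = rbind(bA, bA1),
    A1b   = rbind(bA, bA1),       A1c  = rbind(bA, bA1),
    A1d1  = rbind(bA, bA1, bA1d, bA1d1),
    A1d1a = rbind(bA, bA1, bA1d, bA1d1),
    A1d2  = rbind(bA, bA1, bA1d), A1e  = rbind(bA, bA1),
    A1f   = rbind(bA, bA1),       A1h  = rbind(bA, bA1),
    A2 = bA, A4 = bA, A5 = bA, A6 = bA,
    B1 = bB, B2 = bB, C1 = bC, C2 = bC)

  profiles <- lapply(names18, function(nm) {
    priv <- if (nm == "A1d1a") a1d1aPrivate else snpBlock(nPrivate)
    out <- rbind(shared[[nm]], priv)
    out[order(out$pos), , drop = FALSE]
  })
  names(profiles) <- names18

  if (nExtra > 0L) {
    for (i in seq_len(nExtra)) {
      profiles[[paste0("X", i)]] <- snpBlock(20L)
    }
  }
  new("HaplotypeProfileSet", profiles = profiles, reference = ref,
      genomeLength = as.integer(genomeLength))
}

#' Synthetic host-dog haplotype frequencies
#'
#' A synthetic stand-in for the 18-haplotype frequency table of a global
#' transmissible-cancer host-dog population (n = 495). Counts are fixed
#' integers summing to 495, with A1d1a the most frequent haplotype at
#' 99/495 = 0.20. Shipped as
#' \code{inst/extdata/synthetic_host_haplotype_frequencies.tsv}; real
#' frequency tables can be supplied in the same two-column format.
#'
#' @param asCounts return integer counts rather than frequencies.
#' @return named numeric vector over the 18 haplotypes (sums to 1), or
#'   integer counts when \code{asCounts = TRUE}.
#' @export
syntheticHostFrequencies <- function(asCounts = FALSE) {
  counts <- c(A1d1a = 99L, A1a1 = 70L, A1e = 55L, B1 = 40L, A1b = 35L,
              A2 = 30L, A1 = 28L, A1d1 = 20L, A1c = 18L, A1f = 15L,
              A4 = 14L, A1d2 = 12L, A5 = 12L, B2 = 12L, A1h = 10L,
              A6 = 10L, C1 = 8L, C2 = 7L)
  if (asCounts) counts else counts / sum(counts)
}

#' Read / write haplotype frequency tables
#'
#' Two-column TSV (haplotype, count or frequency); counts are normalised
#' to frequencies on read.
#'
#' @param path file path.
#' @return named numeric frequencies summing to 1.
#' @export
readHaplotypeFrequencies <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("frequency table needs two columns")
  x <- tab[[2L]]
  names(x) <- tab[[1L]]
  x / sum(x)
}

#' Read haplogroup profiles from TSV
#'
#' Long-format TSV with columns haplotype, pos, ref, alt.
#'
#' @param path file path.
#' @param reference optional reference sequence string.
#' @param genomeLength genome length in bp.
#' @return a \linkS4class{HaplotypeProfileSet}.
#' @export
readHaplotypeProfiles <- function(path, reference = "",
                                  genomeLength = 16727L) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("haplotype", "pos", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop("profile TSV needs columns: ", paste(need, collapse = ", "))
  profiles <- lapply(split(tab, tab$haplotype), function(d) {
    d <- d[order(d$pos), c("pos", "ref", "alt")]
    rownames(d) <- NULL
    d
  })
  new("HaplotypeProfileSet", profiles = profiles, reference = reference,
      genomeLength = as.integer(genomeLength))
}

#' @rdname readHaplotypeProfiles
#' @param object a HaplotypeProfileSet.
#' @export
writeHaplotypeProfiles <- function(object, path) {
  stopifnot(is(object, "HaplotypeProfileSet"))
  rows <- do.call(rbind, lapply(names(object@profiles), function(nm) {
    cbind(haplotype = nm, object@profiles[[nm]])
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
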