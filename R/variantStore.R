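#' @include AllClasses.R utils.R
NULL

#' Read a variant table from VCF or TSV
#'
#' TSV columns: sample, chrom, pos, ref, alt, supporting_reads,
#' total_reads. VCF is the v4.2 single-sample dialect written by
#' \code{\link{writeVariantTable}} (contig "MT", AD/DP carrying
#' supporting/total reads); parsing is done with \pkg{vcfR}.
#'
#' @param path input file.
#' @param format "tsv" or "vcf".
#' @param genomeLength circular genome length used for validation.
#' @return a \linkS4class{VariantTable}.
#' @export
readVariantTable <- function(path, format = c("tsv", "vcf"),
                             genomeLength = 16727L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  calls <- if (format == "tsv") .readCallsTsv(path) else .readCallsVcf(path)
  makeVariantTable(calls, genomeLength)
}

.readCallsTsv <- function(path) {
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               colClasses = c(sample = "character", chrom = "character",
                              ref = "character", alt = "character")),
    error = function(e) stop("malformed TSV ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  need <- c("sample", "pos", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop("variant TSV needs columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(tab$pos) | !nzchar(tab$ref) | !nzchar(tab$alt))
  if (length(bad))
    stop("malformed row at line ", bad[1L] + 1L, " of ", path)
  tab
}

.readCallsVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)    # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  sampleId <- colnames(v@gt)[-1L]
  if (length(sampleId) != 1L)
    stop("expected a single-sample VCF, found ", length(sampleId))
  if (!nrow(fix))
    return(data.frame(sample = character(), pos = integer(),
                      ref = character(), alt = character(),
                      supporting_reads = integer(),
                      total_reads = integer()))
  dp <- suppressWarnings(
    as.integer(vcfR::extract.gt(v, element = "DP")[, 1L]))
  ad <- vcfR::extract.gt(v, element = "AD")[, 1L]
  supp <- suppressWarnings(
    as.integer(vapply(strsplit(ad, ","), function(x)
      if (length(x) >= 2L) x[2L] else NA_character_, "")))
  data.frame(sample = sampleId, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT, supporting_reads = supp, total_reads = dp,
             stringsAsFactors = FALSE)
}

#' Write a variant table to VCF or TSV
#'
#' The inverse of \code{\link{readVariantTable}}:
#' \code{readVariantTable(writeVariantTable(x))} reproduces \code{x}.
#' VCF output is v4.2, single sample, contig "MT", genotype fields
#' GT:AD:DP with AD = (reference reads, supporting reads).
#'
#' @param object a \linkS4class{VariantTable}.
#' @param path output file.
#' @param format "tsv" or "vcf" (VCF requires a single-sample table).
#' @return \code{path}, invisibly.
#' @export
writeVariantTable <- function(object, path, format = c("tsv", "vcf")) {
  stopifnot(is(object, "VariantTable"))
  format <- match.arg(format)
  calls <- object@calls
  if (format == "tsv") {
    out <- data.frame(sample = calls$sample,
                      chrom = rep("MT", nrow(calls)), pos = calls$pos,
                      ref = calls$ref, alt = calls$alt,
                      supporting_reads = calls$supporting_reads,
                      total_reads = calls$total_reads)
    ok <- tryCatch({
      write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("cannot write to ", path)
    return(invisible(path))
  }
  smp <- unique(calls$sample)
  if (length(smp) > 1L)
    stop("VCF output requires a single-sample table; found ",
         length(smp), " samples")
  if (!length(smp)) smp <- "SAMPLE"
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=MT,length=%d>", object@genomeLength),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
                  "\"Reads supporting each allele\">"),
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", smp), collapse = "\t"))
  body <- character()
  if (nrow(calls)) {
    calls <- calls[order(calls$pos, calls$ref, calls$alt), , drop = FALSE]
    fmt1 <- function(x) ifelse(is.na(x), ".", as.character(x))
    refReads <- calls$total_reads - calls$supporting_reads
    gt <- sprintf("1:%s,%s:%s", fmt1(refReads),
                  fmt1(calls$supporting_reads), fmt1(calls$total_reads))
    body <- sprintf("MT\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t%s",
                    calls$pos, calls$ref, calls$alt, gt)
  }
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write to ", path)
  invisible(path)
}

#' Substitution-calling filter on pileup summaries
#'
#' A substitution passes when at least \code{minReads} supporting reads
#' have mapping quality >= \code{minMq} and base quality >= \code{minBq}
#' (defaults 3/20/20). The upstream 10-bp read-end base-quality masking is
#' assumed already applied to the pileup.
#'
#' @param pileup data.frame with columns variant, mq, bq (one row per
#'   supporting read), or a named list of per-variant data.frames with
#'   columns mq, bq.
#' @param minReads,minMq,minBq filter thresholds.
#' @return named logical vector, one element per variant.
#' @export
filterSubstitutions <- function(pileup, minReads = 3L, minMq = 20,
                                minBq = 20) {
  if (is.data.frame(pileup)) {
    stopifnot(all(c("variant", "mq", "bq") %in% names(pileup)))
    pileup <- split(pileup[, c("mq", "bq")], pileup$variant)
  }
  vapply(pileup, function(p) {
    if (any(p$mq < 0 | p$bq < 0)) stop("qualities must be >= 0")
    sum(p$mq >= minMq & p$bq >= minBq) >= minReads
  }, logical(1L))
}

#' Left-align an indel on the circular genome
#'
#' Canonicalises anchored insertions and deletions by shifting them as far
#' left as the repeat context allows (wrapping through the origin), so
#' equivalent calls from different callers compare equal. Substitutions
#' are returned unchanged after a reference check. Idempotent.
#'
#' @param variant list or one-row data.frame with pos, ref, alt.
#' @param referenceSequence circular reference sequence (single string).
#' @return list with pos, ref, alt of the canonical representation.
#' @export
normaliseIndel <- function(variant, referenceSequence) {
  pos <- as.integer(variant$pos)
  ref <- toupper(variant$ref)
  alt <- toupper(variant$alt)
  L <- nchar(referenceSequence)
  baseAt <- function(p) substr(referenceSequence, circIndex(p, L),
                               circIndex(p, L))
  refAt <- function(p, n) paste(vapply(seq.int(p, length.out = n),
                                       baseAt, ""), collapse = "")
  if (refAt(pos, nchar(ref)) != ref)
    stop(sprintf("REF allele %s does not match reference at %d", ref, pos))
  kind <- variantKind(ref, alt)
  if (kind == "substitution") return(list(pos = pos, ref = ref, alt = alt))
  if (substr(alt, 1L, 1L) != substr(ref, 1L, 1L))
    stop("indel alleles must share their anchor base")

  ## the moving part: inserted sequence, or deleted sequence
  seqStr <- if (kind == "insertion") substr(alt, 2L, nchar(alt))
            else substr(ref, 2L, nchar(ref))
  s <- strsplit(seqStr, "")[[1L]]
  p <- pos
  for (i in seq_len(L)) {      # bounded walk; stops inside any real repeat
    lastChar <- s[length(s)]
    if (baseAt(p) != lastChar) break
    s <- c(lastChar, s[-length(s)])   # rotate right = shift edit left
    p <- circIndex(p - 1L, L)
  }
  seqStr <- paste(s, collapse = "")
  anchor <- baseAt(p)
  if (kind == "insertion")
    list(pos = circIndex(p, L), ref = anchor,
         alt = paste0(anchor, seqStr))
  else
    list(pos = circIndex(p, L), ref = paste0(anchor, seqStr), alt = anchor)
}
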