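#' @include AllClasses.R
NULL

#' Canonical variant keys
#'
#' A variant is identified throughout the package by the string
#' "pos:ref:alt" (1-based circular coordinate, anchored indel convention).
#'
#' @param pos,ref,alt vectors of equal length (or a data.frame via
#'   \code{variantKeysOf}).
#' @return character vector of keys.
#' @export
variantKey <- function(pos, ref, alt) paste(pos, ref, alt, sep = ":")

#' @rdname variantKey
#' @param x data.frame with pos, ref, alt columns, or a VariantTable.
#' @export
variantKeysOf <- function(x) {
  if (is(x, "VariantTable")) x <- x@calls
  variantKey(x$pos, x$ref, x$alt)
}

#' Classify a variant as substitution, insertion or deletion
#'
#' Uses the anchored-allele convention: equal-length single-base alleles
#' are substitutions; longer ALT is an insertion, longer REF a deletion.
#'
#' @param ref,alt allele strings.
#' @return character vector.
#' @export
variantKind <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt), "substitution",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

## Evaluate `expr` with a private RNG stream so deterministic builders
## (reference sequence, profiles) never perturb the user's global stream.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## 1-based circular index into a genome of length L.
circIndex <- function(i, L) ((i - 1L) %% L) + 1L

## Circular midpoint between ordered positions a -> b (walking forward).
circMidpoint <- function(a, b, L) {
  d <- (b - a) %% L
  circIndex(a + floor(d / 2), L)
}

#' Construct a VariantTable from a calls data.frame
#'
#' Validates columns and recomputes the VAF from read counts when it is
#' not supplied (calls without read counts default to VAF 1).
#'
#' @param calls data.frame with at least sample, pos, ref, alt; optional
#'   supporting_reads, total_reads, vaf.
#' @param genomeLength circular genome length in bp.
#' @return a \linkS4class{VariantTable}.
#' @export
makeVariantTable <- function(calls, genomeLength = .MT_GENOME_LENGTH) {
  if (is.null(calls$supporting_reads)) calls$supporting_reads <- NA_integer_
  if (is.null(calls$total_reads)) calls$total_reads <- NA_integer_
  if (is.null(calls$vaf)) {
    calls$vaf <- ifelse(!is.na(calls$total_reads) & calls$total_reads > 0,
                        calls$supporting_reads / calls$total_reads, 1)
  }
  calls <- calls[, .CALL_COLUMNS, drop = FALSE]
  calls$pos <- as.integer(calls$pos)
  rownames(calls) <- NULL
  new("VariantTable", calls = calls,
      genomeLength = as.integer(genomeLength))
}

#' Extract the calls of one sample
#'
#' @param object a VariantTable.
#' @param sample sample id.
#' @return data.frame of that sample's calls.
#' @export
sampleCalls <- function(object, sample) {
  stopifnot(is(object, "VariantTable"))
  object@calls[object@calls$sample == sample, , drop = FALSE]
}
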