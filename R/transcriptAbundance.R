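#' @include AllClasses.R utils.R
NULL

.assayMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x)
  else as.matrix(x)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: each sample's factor is the median
#' over genes of its count divided by the gene's geometric mean across
#' samples (computed over genes expressed in every sample), rescaled so
#' the factors have geometric mean 1.
#'
#' @param counts genes x samples count matrix or SummarizedExperiment.
#' @return named numeric vector of size factors.
#' @export
sizeFactors <- function(counts) {
  m <- .assayMatrix(counts)
  ok <- rowSums(m == 0) == 0L
  if (!any(ok)) stop("no gene expressed in all samples")
  logGeo <- rowMeans(log(m[ok, , drop = FALSE]))
  sf <- apply(m[ok, , drop = FALSE], 2L, function(cnt)
    exp(median(log(cnt) - logGeo)))
  sf / exp(mean(log(sf)))
}

#' Normalise counts by size factors
#'
#' @param counts genes x samples count matrix or SummarizedExperiment.
#' @param sf size factors; computed with \code{\link{sizeFactors}} when
#'   missing.
#' @return normalised abundance matrix.
#' @export
normaliseCounts <- function(counts, sf = NULL) {
  m <- .assayMatrix(counts)
  if (is.null(sf)) sf <- sizeFactors(m)
  sweep(m, 2L, sf, "/")
}

#' Remove additive batch effects from log abundances
#'
#' Fits, per gene, an additive least-squares model
#' (log abundance ~ group + batch) and subtracts the fitted batch terms;
#' the log transform (log2 of normalised count + 1) is then reversed and
#' each gene rescaled so its grand mean abundance is preserved. With a
#' single batch the input is returned unchanged; a group observed in
#' fewer than two batches skips correction with a warning; a design in
#' which group and batch are perfectly confounded is an error.
#'
#' @param logAbundances genes x samples matrix of log2(abundance + 1).
#' @param batchLabels per-sample batch labels.
#' @param groupLabels per-sample group labels.
#' @return genes x samples matrix of corrected linear-scale abundances.
#' @export
batchCorrect <- function(logAbundances, batchLabels, groupLabels) {
  m <- as.matrix(logAbundances)
  batch <- factor(batchLabels)
  group <- factor(groupLabels)
  stopifnot(ncol(m) == length(batch), ncol(m) == length(group))
  toLinear <- function(x) pmax(2^x - 1, 0)
  if (nlevels(batch) < 2L) return(toLinear(m))
  if (min(table(batch)) < 2L) stop("every batch needs >= 2 samples")

  cross <- table(group, batch)
  design <- model.matrix(~ group + batch)
  if (qr(design)$rank < ncol(design))
    stop("group is perfectly confounded with batch; cannot correct")
  if (any(rowSums(cross > 0) < 2L)) {
    warning("a group is present in fewer than 2 batches; ",
            "batch correction skipped")
    return(toLinear(m))
  }

  ## centred batch contrasts so the subtracted terms sum to zero and the
  ## group means stay on the original scale
  designC <- model.matrix(~ group + C(batch, stats::contr.sum))
  batchCols <- grep("batch", colnames(designC), fixed = TRUE)
  fit <- lm.fit(designC, t(m))
  beta <- t(fit$coefficients)
  batchTerm <- beta[, batchCols, drop = FALSE] %*%
    t(designC[, batchCols, drop = FALSE])
  corrected <- m - batchTerm

  lin0 <- toLinear(m)
  lin1 <- toLinear(corrected)
  scale <- ifelse(rowMeans(lin1) > 0, rowMeans(lin0) / rowMeans(lin1), 1)
  lin1 * scale
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact-enumeration p value when the pooled size is at most 16 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param valuesA,valuesB numeric vectors (each >= 1 value).
#' @return list with \code{U} and \code{p} (two-sided).
#' @export
mannWhitney <- function(valuesA, valuesB) {
  stopifnot(length(valuesA) >= 1L, length(valuesB) >= 1L)
  ties <- anyDuplicated(c(valuesA, valuesB)) > 0L
  exact <- (length(valuesA) + length(valuesB)) <= 16L && !ties
  fit <- suppressWarnings(
    wilcox.test(valuesA, valuesB, exact = exact, correct = TRUE,
                alternative = "two.sided"))
  p <- fit$p.value
  if (is.nan(p)) p <- 1   # zero-variance pooled sample: no evidence
  list(U = unname(fit$statistic), p = p)
}

#' Benjamini-Hochberg adjustment over a restricted hypothesis set
#'
#' Standard step-up false-discovery-rate control applied to exactly the
#' supplied p values (restricted hypothesis testing: only the genes under
#' consideration enter the correction).
#'
#' @param pValues numeric p values in [0, 1].
#' @return adjusted q values in input order.
#' @export
bhAdjust <- function(pValues) {
  if (any(is.na(pValues)) || any(pValues < 0 | pValues > 1))
    stop("p values must lie in [0, 1]")
  p.adjust(pValues, method = "BH")
}

#' Overall abundance change of a gene class between groups
#'
#' Percent change = (1 - meanA/meanB) x 100 computed on group means of
#' per-sample mean class-gene abundance (positive = decrease in group A).
#' The p value is a two-sided Mann-Whitney test on the per-gene group
#' mean abundances of the two groups (not on the per-sample means).
#'
#' @param corrected genes x samples batch-corrected abundance matrix.
#' @param groupLabels per-sample group labels.
#' @param groupA,groupB group names (A is the putatively affected group).
#' @param classGenes character vector of gene (row) names in the class.
#' @return list with \code{percentChange}, \code{U}, \code{p}.
#' @export
groupAbundanceChange <- function(corrected, groupLabels, groupA, groupB,
                                 classGenes = rownames(corrected)) {
  if (!length(classGenes)) stop("empty gene class")
  stopifnot(all(classGenes %in% rownames(corrected)))
  a <- groupLabels == groupA
  b <- groupLabels == groupB
  if (!any(a) || !any(b)) stop("both groups must be non-empty")
  m <- corrected[classGenes, , drop = FALSE]
  perSampleMean <- colMeans(m)
  pct <- (1 - mean(perSampleMean[a]) / mean(perSampleMean[b])) * 100
  perGeneA <- rowMeans(m[, a, drop = FALSE])
  perGeneB <- rowMeans(m[, b, drop = FALSE])
  mw <- mannWhitney(perGeneA, perGeneB)
  list(percentChange = pct, U = mw$U, p = mw$p)
}

#' Per-gene differential abundance over a restricted gene list
#'
#' Two-group rank test per gene (Mann-Whitney across samples) with
#' Benjamini-Hochberg adjustment over exactly the supplied gene list.
#'
#' @param corrected genes x samples batch-corrected abundance matrix.
#' @param groupLabels per-sample group labels.
#' @param groupA,groupB group names.
#' @param geneList genes to test (must all be rows of \code{corrected}).
#' @return data.frame with gene, U, p, q and direction ("down" = lower
#'   in group A).
#' @export
perGeneDifferential <- function(corrected, groupLabels, groupA, groupB,
                                geneList) {
  if (!length(geneList)) stop("empty gene list")
  absent <- setdiff(geneList, rownames(corrected))
  if (length(absent))
    stop("genes absent from matrix: ", paste(absent, collapse = ", "))
  a <- groupLabels == groupA
  b <- groupLabels == groupB
  res <- lapply(geneList, function(g) {
    mw <- mannWhitney(corrected[g, a], corrected[g, b])
    data.frame(gene = g, U = mw$U, p = mw$p,
               direction = if (mean(corrected[g, a]) <
                               mean(corrected[g, b])) "down" else "up",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bhAdjust(out$p)
  out[, c("gene", "U", "p", "q", "direction")]
}

#' Simulate expression counts with haplotype effect and batch structure
#'
#' Negative-binomial counts for mtDNA protein-coding genes (13) and
#' nuclear-encoded mitochondrially relevant genes (7): mtDNA-gene means
#' in the affected group are scaled by (1 - effectFraction); nuclear
#' genes are unaffected; batch effects are multiplicative per-batch
#' per-gene factors; samples get library-size factors.
#'
#' @param groups named character vector, sample -> group (each group
#'   needs >= 2 samples).
#' @param batchLabels per-sample batch labels; default alternates two
#'   batches within each group (a crossed design).
#' @param nGenesMt,nGenesNuclear gene counts per class.
#' @param nGenesOther unaffected background genes (the rest of the
#'   transcriptome at desk scale); they anchor the median-of-ratios
#'   normalisation so that a class-wide effect is not absorbed as a
#'   library-size difference.
#' @param effectFraction fractional decrease of mtDNA-gene expression in
#'   the affected group, in [0, 1).
#' @param affectedGroup group receiving the effect (default "A1d1a" when
#'   present, else the first group).
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param baseMeanMt,baseMeanNuclear,baseMeanOther baseline mean counts.
#' @param geneSpread standard deviation of per-gene log2 baseline means.
#' @param batchSd standard deviation of per-batch per-gene log2 factors.
#' @param seed integer seed.
#' @return a SummarizedExperiment with assay "counts", rowData gene
#'   class and colData group/batch.
#' @export
simulateExpressionCounts <- function(groups, batchLabels = NULL,
                                     nGenesMt = 13L, nGenesNuclear = 7L,
                                     nGenesOther = 200L,
                                     effectFraction = 0.39,
                                     affectedGroup = NULL,
                                     dispersion = 0.15,
                                     baseMeanMt = 2000,
                                     baseMeanNuclear = 1500,
                                     baseMeanOther = 1000,
                                     geneSpread = 0.4,
                                     batchSd = 0.3, seed = 1L) {
  if (effectFraction < 0 || effectFraction >= 1)
    stop("effectFraction must lie in [0, 1)")
  if (min(table(groups)) < 2L) stop("each group needs >= 2 samples")
  if (is.null(names(groups)))
    names(groups) <- sprintf("S%03d", seq_along(groups))
  set.seed(seed)
  if (is.null(affectedGroup))
    affectedGroup <- if ("A1d1a" %in% groups) "A1d1a" else groups[[1L]]
  if (is.null(batchLabels)) {
    batchLabels <- setNames(character(length(groups)), names(groups))
    for (idx in split(seq_along(groups), groups))
      batchLabels[idx] <- paste0("batch", (seq_along(idx) %% 2L) + 1L)
  } else if (is.null(names(batchLabels)))
    names(batchLabels) <- names(groups)
  genes <- c(sprintf("MT-G%02d", seq_len(nGenesMt)),
             sprintf("NUC-G%02d", seq_len(nGenesNuclear)),
             sprintf("OTH-G%03d", seq_len(nGenesOther)))
  geneClass <- rep(c("mtDNA", "nuclear", "other"),
                   c(nGenesMt, nGenesNuclear, nGenesOther))
  baseMean <- c(baseMeanMt * 2^rnorm(nGenesMt, 0, geneSpread),
                baseMeanNuclear * 2^rnorm(nGenesNuclear, 0, geneSpread),
                baseMeanOther * 2^rnorm(nGenesOther, 0, geneSpread))
  batches <- unique(batchLabels)
  batchFac <- matrix(2^rnorm(length(genes) * length(batches), 0, batchSd),
                     length(genes), dimnames = list(genes, batches))
  libFac <- runif(length(groups), 0.7, 1.4)
  mu <- outer(baseMean, libFac) * batchFac[, batchLabels]
  affected <- groups == affectedGroup
  mu[geneClass == "mtDNA", affected] <-
    mu[geneClass == "mtDNA", affected] * (1 - effectFraction)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow(mu), dimnames = list(genes, names(groups)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(geneClass = geneClass,
                                   row.names = genes),
    colData = S4Vectors::DataFrame(group = unname(groups),
                                   batch = unname(batchLabels[names(groups)]),
                                   row.names = names(groups)))
}

#' Haplotype-stratified transcript-abundance analysis
#'
#' The full expression stage: median-of-ratios normalisation, log2
#' transform, batch correction, overall mtDNA and nuclear gene-class
#' comparisons and per-gene differential testing over the restricted
#' gene list.
#'
#' @param se SummarizedExperiment from
#'   \code{\link{simulateExpressionCounts}} (or with the same layout).
#' @param groupA affected group; default "A1d1a" when present.
#' @param groupB reference group(s); default all other samples, pooled.
#' @return list with \code{mtChange}, \code{nuclearChange},
#'   \code{perGene} and the corrected abundance matrix.
#' @export
analyseTranscriptAbundance <- function(se, groupA = NULL, groupB = NULL) {
  counts <- SummarizedExperiment::assay(se)
  cls <- SummarizedExperiment::rowData(se)$geneClass
  grp <- SummarizedExperiment::colData(se)$group
  batch <- SummarizedExperiment::colData(se)$batch
  if (is.null(groupA))
    groupA <- if ("A1d1a" %in% grp) "A1d1a" else grp[1L]
  if (is.null(groupB)) {
    grp <- ifelse(grp == groupA, groupA, "other")
    groupB <- "other"
  }
  norm <- normaliseCounts(counts)
  corrected <- batchCorrect(log2(norm + 1), batch, grp)
  mtGenes <- rownames(counts)[cls == "mtDNA"]
  nucGenes <- rownames(counts)[cls == "nuclear"]
  list(mtChange = groupAbundanceChange(corrected, grp, groupA, groupB,
                                       mtGenes),
       nuclearChange = groupAbundanceChange(corrected, grp, groupA,
                                            groupB, nucGenes),
       perGene = perGeneDifferential(corrected, grp, groupA, groupB,
                                     c(mtGenes, nucGenes)),
       corrected = corrected)
}
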