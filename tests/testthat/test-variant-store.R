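test_that("VCF and TSV round trips preserve calls exactly", {
  set.seed(42)
  n <- 100L
  pos <- sort(sample(16727L, n))
  refBase <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  kind <- sample(c("sub", "ins", "del"), n, replace = TRUE,
                 prob = c(0.8, 0.1, 0.1))
  ref <- ifelse(kind == "del", paste0(refBase, "AC"), refBase)
  alt <- ifelse(kind == "sub", ifelse(refBase == "A", "G", "A"),
                ifelse(kind == "ins", paste0(refBase, "CC"), refBase))
  total <- sample(50:200, n, replace = TRUE)
  supp <- rbinom(n, total, 0.7)
  tab <- makeVariantTable(
    data.frame(sample = "T1", pos = pos, ref = ref, alt = alt,
               supporting_reads = supp, total_reads = total))

  tsv <- tempfile(fileext = ".tsv")
  writeVariantTable(tab, tsv, format = "tsv")
  back <- readVariantTable(tsv, format = "tsv")
  expect_equal(variantCalls(back), variantCalls(tab))

  vcf <- tempfile(fileext = ".vcf")
  writeVariantTable(tab, vcf, format = "vcf")
  back2 <- readVariantTable(vcf, format = "vcf")
  # VCF body is position-sorted; compare as sorted tables
  ord <- function(d) {
    d <- d[order(d$pos, d$ref, d$alt), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(variantCalls(back2)), ord(variantCalls(tab)))
})

test_that("a single VCF substitution record parses as one call", {
  tab <- makeVariantTable(
    data.frame(sample = "559T", pos = 7593L, ref = "T", alt = "C",
               supporting_reads = 30L, total_reads = 30L))
  vcf <- tempfile(fileext = ".vcf")
  writeVariantTable(tab, vcf, format = "vcf")
  back <- readVariantTable(vcf, format = "vcf")
  calls <- variantCalls(back)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 7593L)
  expect_equal(variantKind(calls$ref, calls$alt), "substitution")
  expect_equal(calls$vaf, 1)
})

test_that("an anchored insertion round-trips through VCF", {
  tab <- makeVariantTable(
    data.frame(sample = "T1", pos = 16660L, ref = "A", alt = "ACC",
               supporting_reads = 10L, total_reads = 20L))
  vcf <- tempfile(fileext = ".vcf")
  writeVariantTable(tab, vcf, format = "vcf")
  back <- variantCalls(readVariantTable(vcf, format = "vcf"))
  expect_equal(back$pos, 16660L)
  expect_equal(back$ref, "A")
  expect_equal(back$alt, "ACC")
  expect_equal(variantKind(back$ref, back$alt), "insertion")
})

test_that("empty tables survive the round trip", {
  tab <- new("VariantTable")
  tsv <- tempfile(fileext = ".tsv")
  writeVariantTable(tab, tsv)
  expect_equal(nrow(variantCalls(readVariantTable(tsv))), 0L)
  vcf <- tempfile(fileext = ".vcf")
  writeVariantTable(tab, vcf, format = "vcf")
  expect_equal(nrow(variantCalls(readVariantTable(vcf, format = "vcf"))),
               0L)
})

test_that("out-of-range positions and malformed input are rejected", {
  expect_error(makeVariantTable(
    data.frame(sample = "T1", pos = 20000L, ref = "A", alt = "G",
               supporting_reads = 1L, total_reads = 2L)),
    "position")
  expect_error(readVariantTable(tempfile(), format = "tsv"), "no such file")
  expect_error(makeVariantTable(
    data.frame(sample = "T1", pos = 5L, ref = "", alt = "G",
               supporting_reads = 1L, total_reads = 2L)),
    "non-empty")
  expect_error(makeVariantTable(
    data.frame(sample = "T1", pos = 5L, ref = "A", alt = "G",
               supporting_reads = 5L, total_reads = 2L)),
    "exceed")
})

test_that("substitution filter applies the >=3 reads at MQ/BQ >= 20 rule", {
  pp <- function(mq, bq) data.frame(mq = mq, bq = bq)
  expect_true(filterSubstitutions(list(v = pp(c(30, 30, 30),
                                              c(30, 30, 30))))[["v"]])
  expect_false(filterSubstitutions(list(v = pp(c(60, 60),
                                               c(40, 40))))[["v"]])
  # 4 reads but only 2 clear both thresholds
  expect_false(filterSubstitutions(list(v = pp(c(60, 60, 60, 60),
                                               c(30, 30, 10, 10))))[["v"]])
  # long-format interface
  long <- data.frame(variant = rep(c("a", "b"), c(3, 2)),
                     mq = c(25, 25, 25, 60, 60), bq = c(25, 25, 25, 40, 40))
  res <- filterSubstitutions(long)
  expect_true(res[["a"]])
  expect_false(res[["b"]])
  expect_error(filterSubstitutions(list(v = pp(-1, 30))), ">= 0")
})

test_that("the filter is monotone in qualifying reads", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    p <- data.frame(mq = sample(c(10, 30, 60), n, replace = TRUE),
                    bq = sample(c(10, 25, 40), n, replace = TRUE))
    before <- filterSubstitutions(list(v = p))[["v"]]
    augmented <- rbind(p, data.frame(mq = 60, bq = 40))
    after <- filterSubstitutions(list(v = augmented))[["v"]]
    expect_true(!before || after)
  }
})

test_that("indels are left-aligned within repeat context, circularly", {
  #       123456789012345
  ref <- "ATGACCCCTGAGGCA"
  # insertion of CC reported mid-run (anchor 7) shifts to run start
  v <- normaliseIndel(list(pos = 7, ref = "C", alt = "CCC"), ref)
  expect_equal(v$pos, 4L)
  expect_equal(v$ref, "A")
  expect_equal(v$alt, "ACC")
  # idempotent
  v2 <- normaliseIndel(v, ref)
  expect_equal(v2, v)
  # deletion of one C in the run shifts to the same anchor
  d <- normaliseIndel(list(pos = 6, ref = "CC", alt = "C"), ref)
  expect_equal(d$pos, 4L)
  expect_equal(d$ref, "AC")
  expect_equal(d$alt, "A")
  # substitutions pass through with a reference check
  s <- normaliseIndel(list(pos = 3, ref = "G", alt = "A"), ref)
  expect_equal(s, list(pos = 3L, ref = "G", alt = "A"))
  expect_error(normaliseIndel(list(pos = 3, ref = "T", alt = "A"), ref),
               "does not match")
})

test_that("left alignment matches an exhaustive-shift oracle", {
  # oracle: apply the edit at every candidate anchor and keep anchors
  # that reproduce the same edited sequence; canonical = leftmost of the
  # contiguous run containing the reported anchor
  applyIns <- function(ref, pos, ins) {
    n <- nchar(ref)
    paste0(substr(ref, 1, pos), ins, substr(ref, pos + 1, n))
  }
  set.seed(11)
  for (i in 1:25) {
    ref <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE,
                        prob = c(0.2, 0.4, 0.2, 0.2)), collapse = "")
    pos <- sample(5:35, 1)
    ins <- paste(sample(c("C", "A"), sample(1:2, 1), replace = TRUE),
                 collapse = "")
    target <- applyIns(ref, pos, ins)
    rotations <- unique(vapply(seq_len(nchar(ins)), function(k) {
      paste0(substr(ins, k + 1, nchar(ins)), substr(ins, 1, k))
    }, ""))
    equivalent <- vapply(1:39, function(p) {
      any(vapply(rotations, function(r) applyIns(ref, p, r) == target,
                 logical(1)))
    }, logical(1))
    oracle <- min(which(equivalent))
    got <- normaliseIndel(list(pos = pos, ref = substr(ref, pos, pos),
                               alt = paste0(substr(ref, pos, pos), ins)),
                          ref)
    # the result must reproduce the same edited sequence
    expect_equal(applyIns(ref, got$pos, substr(got$alt, 2, nchar(got$alt))),
                 target)
    # and sit at the leftmost equivalent anchor (skip origin-wrapping runs)
    if (oracle > 1) expect_equal(got$pos, oracle)
  }
})

test_that("an insertion shifting through the origin wraps correctly", {
  #       12345678
  ref <- "CCGATGCC"   # C-run wraps: positions 7,8,1,2
  v <- normaliseIndel(list(pos = 2, ref = "C", alt = "CCC"), ref)
  expect_lte(v$pos, 8L)
  expect_equal(v$pos, 6L)   # anchor G at 6, run start at 7 after wrap
  expect_equal(v$alt, paste0(v$ref, "CC"))
})

test_that("VAF is stable under read subsampling in expectation", {
  set.seed(3)
  trueVaf <- 0.3
  deep <- rbinom(200, 400, trueVaf) / 400
  shallow <- rbinom(200, 40, trueVaf) / 40
  se <- sqrt(trueVaf * (1 - trueVaf) * (1 / (200 * 400) + 1 / (200 * 40)))
  expect_lt(abs(mean(deep) - mean(shallow)), 3 * se)
})
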