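test_that("dog populations follow the configured frequencies", {
  # degenerate distribution
  cfg <- simulationConfig(nDogs = 10, haplotypeFreqs = c(A1e = 1.0),
                          nTumours = 2, nHtEvents = 1,
                          htDonorHaplotypes = "A1e",
                          memberCounts = integer(), eventAges = 0,
                          heteroplasmyFractions = NA_real_,
                          incumbentHaplotypes = NA_character_,
                          recombinantEventIndex = 0L)
  dogs <- simulateDogPopulation(cfg)
  expect_equal(nrow(dogs), 10L)
  expect_true(all(dogs$haplotype == "A1e"))
  # binomial moments at n = 10000
  cfg2 <- simulationConfig(nDogs = 10000,
                           haplotypeFreqs = c(A1e = 0.5, B1 = 0.5),
                           nTumours = 2, nHtEvents = 1,
                           htDonorHaplotypes = "A1e",
                           memberCounts = integer(), eventAges = 0,
                           heteroplasmyFractions = NA_real_,
                           incumbentHaplotypes = NA_character_,
                           recombinantEventIndex = 0L, seed = 20L)
  dogs2 <- simulateDogPopulation(cfg2)
  expect_equal(nrow(dogs2), 10000L)            # counts conserved exactly
  expect_lt(abs(sum(dogs2$haplotype == "A1e") - 5000), 4 * 50)
  # the full 18-haplotype population
  dogs3 <- simulateDogPopulation(simulationConfig())
  expect_equal(nrow(dogs3), 495L)
  expect_lte(length(unique(dogs3$haplotype)), 18L)
  # each dog's variant profile is its haplotype's profile
  pf <- syntheticProfiles()
  vt <- dogVariantTable(head(dogs3, 5), pf)
  for (i in 1:5) {
    calls <- sampleCalls(vt, dogs3$dog[i])
    expect_equal(variantKeysOf(calls),
                 variantKeysOf(profileVariants(pf, dogs3$haplotype[i])))
    expect_true(all(calls$vaf == 1))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(haplotypeFreqs = c(A1e = 0.5, B1 = 0.4)),
               "sum to 1")
  expect_error(simulationConfig(nTumours = 5, nHtEvents = 10,
                                htDonorHaplotypes = character(),
                                eventAges = rep(1, 10),
                                heteroplasmyFractions = rep(NA_real_, 10),
                                incumbentHaplotypes =
                                  rep(NA_character_, 10),
                                memberCounts = integer()),
               "exceeds")
  expect_error(simulationConfig(eventAges = c(-1, rep(30, 18))),
               "eventAges")
  expect_error(simulationConfig(heteroplasmyFractions =
                                  c(1.5, rep(NA_real_, 18))),
               "fractions")
})

test_that("cohorts are bit-reproducible under a fixed seed", {
  cfg <- cleanConfig(nTumours = 30, k = 4,
                     donors = c("A1e", "A1a1", "B1", "C1"), seed = 33L)
  a <- simulateCtvtCohort(cfg)
  b <- simulateCtvtCohort(cfg)
  expect_identical(variantCalls(cohortVariants(a)),
                   variantCalls(cohortVariants(b)))
  expect_identical(ape::write.tree(cohortTree(a)),
                   ape::write.tree(cohortTree(b)))
  expect_identical(groundTruth(a)$tumours, groundTruth(b)$tumours)
})

test_that("somatic burden follows the configured clock", {
  # age 0: no somatic mutations at all
  cfg0 <- cleanConfig(nTumours = 20, k = 2, donors = c("A1e", "B1"),
                      ages = c(0, 0), seed = 2L)
  co0 <- simulateCtvtCohort(cfg0)
  expect_true(all(groundTruth(co0)$tumours$somatic_count == 0L))
  # rate 0.0201 at the divergence anchor age: mean count near 9.437
  cfg <- cleanConfig(nTumours = 600, k = 2, donors = c("A1e", "A1a1"),
                     ages = c(469.28, 469.28), seed = 8L)
  co <- simulateCtvtCohort(cfg)
  counts <- groundTruth(co)$tumours$somatic_count
  expect_lt(abs(mean(counts) - 9.437), 3 * sqrt(9.437 / 600))
  # somatic variants land outside profile sites
  pf <- cohortProfiles(co)
  profileKeys <- unique(unlist(lapply(pf@profiles, variantKeysOf)))
  calls <- variantCalls(cohortVariants(co))
  somatic <- setdiff(variantKeysOf(calls), profileKeys)
  somPos <- as.integer(vapply(strsplit(somatic, ":"), `[[`, "", 1))
  profPos <- unique(unlist(lapply(pf@profiles, function(p) p$pos)))
  expect_length(intersect(somPos, profPos), 0L)
})

test_that("heteroplasmic events carry two haplotypes at the set fraction", {
  cfg <- simulationConfig(nTumours = 12, nHtEvents = 3,
                          htDonorHaplotypes = c("A1e", "B1", "A1a1"),
                          memberCounts = c(6L, 3L, 3L),
                          eventAges = rep(10, 3),
                          heteroplasmyFractions = c(NA, 0.55, NA),
                          incumbentHaplotypes = c(NA, "A1e", NA),
                          recombinantEventIndex = 0L, seed = 5L)
  co <- simulateCtvtCohort(cfg)
  het <- groundTruth(co)$tumours
  hetT <- het$tumour[het$heteroplasmy_fraction == 0.55][1]
  calls <- sampleCalls(cohortVariants(co), hetT)
  pf <- cohortProfiles(co)
  b1 <- variantKeysOf(profileVariants(pf, "B1"))
  a1e <- variantKeysOf(profileVariants(pf, "A1e"))
  keys <- variantKeysOf(calls)
  expect_equal(unique(calls$vaf[keys %in% b1]), 0.55)
  expect_equal(unique(calls$vaf[keys %in% a1e]), 0.45)
})

test_that("read support matches VAF and depth settings", {
  vt <- makeVariantTable(data.frame(
    sample = "T1", pos = c(100L, 200L, 300L), ref = "A", alt = "G",
    supporting_reads = c(10L, 10L, 5L), total_reads = c(10L, 10L, 10L)))
  rs <- simulateReadSupport(vt, meanMtDepth = 50, seed = 4L)
  calls <- variantCalls(rs$variants)
  # VAF-1 variants: every read supports the variant
  expect_true(all(calls$supporting_reads[1:2] == calls$total_reads[1:2]))
  # qualities attached per supporting read
  expect_equal(nrow(rs$pileup), sum(calls$supporting_reads))
  expect_true(all(rs$pileup$mq >= 0 & rs$pileup$bq >= 0))
  expect_error(simulateReadSupport(vt, meanMtDepth = 0), "> 0")
  expect_error(simulateReadSupport(vt, tumourFraction = 0), "\\(0, 1\\]")
  # nuclear somatic VAFs concentrate near half the tumour fraction
  rs2 <- simulateReadSupport(vt, tumourFraction = 0.8,
                             nNuclearVariants = 2000L, seed = 6L)
  expect_equal(estimateNuclearTumourFraction(rs2$nuclearVafs[["T1"]]),
               0.8, tolerance = 0.06)
})

test_that("fixture bundles round-trip the cohort", {
  cfg <- simulationConfig(nTumours = 16, nHtEvents = 3,
                          htDonorHaplotypes = c("A1e", "A1d1a", "B1"),
                          memberCounts = c(8L, 5L, 3L),
                          eventAges = c(100, 30, 30),
                          heteroplasmyFractions = c(NA, NA, 0.55),
                          incumbentHaplotypes = c(NA, NA, "A1e"),
                          recombinantEventIndex = 0L, seed = 7L)
  co <- simulateCtvtCohort(cfg)
  dir <- tempfile("bundle")
  writeFixtureBundle(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("variants.tsv", "tree.newick", "profiles.tsv", "truth_tumours.tsv",
      "truth_events.tsv", "config.yaml", "consensus.fasta",
      "reference.fasta")))))
  # single-sample VCFs parse back to the same calls
  vcfs <- list.files(file.path(dir, "vcf"), full.names = TRUE)
  expect_length(vcfs, 16L)
  s1 <- sub("[.]vcf$", "", basename(vcfs[1]))
  back1 <- variantCalls(readVariantTable(vcfs[1], format = "vcf"))
  orig1 <- sampleCalls(cohortVariants(co), s1)
  orig1 <- orig1[order(orig1$pos, orig1$ref, orig1$alt), ]
  rownames(orig1) <- NULL
  expect_equal(back1, orig1)
  # full bundle read-back
  back <- readFixtureBundle(dir)
  expect_equal(variantCalls(cohortVariants(back)),
               variantCalls(cohortVariants(co)))
  expect_equal(ape::write.tree(cohortTree(back)),
               ape::write.tree(cohortTree(co)))
  expect_equal(groundTruth(back)$tumours, groundTruth(co)$tumours)
  expect_equal(cohortConfig(back)@seed, cohortConfig(co)@seed)
  # consensus sequences embed each sample's substitutions
  fa <- Biostrings::readDNAStringSet(file.path(dir, "consensus.fasta"))
  expect_length(fa, 16L)
  calls1 <- orig1[nchar(orig1$ref) == 1 & nchar(orig1$alt) == 1 &
                    orig1$vaf > 0.5, ]
  seq1 <- as.character(fa[[s1]])
  expect_true(all(substring(seq1, calls1$pos, calls1$pos) == calls1$alt))
  expect_error(writeFixtureBundle(co, "/proc/nope"), "write")
})

test_that("expression counts carry the planted effect structure", {
  grp <- setNames(rep(c("A1d1a", "HT1"), each = 30),
                  sprintf("S%02d", 1:60))
  # null model: no group difference in expectation
  se0 <- simulateExpressionCounts(grp, effectFraction = 0, seed = 10L)
  m0 <- SummarizedExperiment::assay(se0)
  cls <- SummarizedExperiment::rowData(se0)$geneClass
  ratio0 <- mean(m0[cls == "mtDNA", grp == "A1d1a"]) /
    mean(m0[cls == "mtDNA", grp == "HT1"])
  expect_equal(ratio0, 1, tolerance = 0.25)
  # effect hits mtDNA genes only; nuclear genes stay balanced
  se <- simulateExpressionCounts(grp, effectFraction = 0.39, seed = 10L)
  m <- SummarizedExperiment::assay(se)
  mtRatio <- mean(m[cls == "mtDNA", grp == "A1d1a"]) /
    mean(m[cls == "mtDNA", grp == "HT1"])
  expect_equal(mtRatio, 0.61, tolerance = 0.25)
  nucRatio <- mean(m[cls == "nuclear", grp == "A1d1a"]) /
    mean(m[cls == "nuclear", grp == "HT1"])
  expect_equal(nucRatio, 1, tolerance = 0.25)
  expect_error(simulateExpressionCounts(grp, effectFraction = 1), "effect")
  expect_error(simulateExpressionCounts(c(a = "G1", b = "G2")), ">= 2")
})
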