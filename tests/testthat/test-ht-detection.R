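test_that("maximal same-donor clades become events", {
  # one haplotype, one clade
  tr <- ape::read.tree(text = "((t1,t2),t3);")
  ev <- detectHtEvents(tr, c(t1 = "A1e", t2 = "A1e", t3 = "A1e"))
  expect_length(ev, 1L)
  expect_setequal(eventMembers(ev[[1]]), c("t1", "t2", "t3"))
  # two same-haplotype tumours separated on the tree split into two
  # events (no clade contains them alone)
  labs <- c(t1 = "A1d1a", t2 = "B1", t3 = "A1d1a")
  ev2 <- detectHtEvents(tr, labs)
  donors <- vapply(ev2, eventDonor, "")
  expect_equal(sum(donors == "A1d1a"), 2L)
  expect_length(ev2, 3L)
  expect_error(detectHtEvents(tr, c(labs, t9 = "A1e")), "absent")
})

test_that("events partition the cohort on simulated trees", {
  pf <- syntheticProfiles()
  for (seed in 1:5) {
    k <- sample(4:8, 1)
    cfg <- cleanConfig(nTumours = 40, k = k,
                       donors = sample(profileNames(pf), k), seed = seed)
    co <- simulateCtvtCohort(cfg, pf)
    ev <- detectHtEvents(cohortTree(co), truthLabels(co))
    members <- unlist(lapply(ev, eventMembers))
    expect_length(members, 40L)
    expect_false(anyDuplicated(members) > 0)
  }
})

test_that("replaced haplotype comes from the parent's MPR state", {
  # nested introduced clade inside an A1e background
  tr <- ape::read.tree(text = "((((e1,(a1,a2)),e2),e3),e4);")
  labs <- c(e1 = "A1e", e2 = "A1e", e3 = "A1e", e4 = "A1e",
            a1 = "A1d1a", a2 = "A1d1a")
  ev <- detectHtEvents(tr, labs)
  a1d1a <- ev[[which(vapply(ev, eventDonor, "") == "A1d1a")]]
  expect_equal(inferReplacedHaplotype(a1d1a, tr, labs), "A1e")
  # event clade at the root
  whole <- detectHtEvents(tr, setNames(rep("A1e", 6), names(labs)))[[1]]
  expect_equal(inferReplacedHaplotype(whole, tr,
                                      setNames(rep("A1e", 6),
                                               names(labs))), "Unknown")
  # non-singleton parent state set
  tr2 <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  labs2 <- c(t1 = "A", t2 = "B", t3 = "C", t4 = "D")
  ev2 <- detectHtEvents(tr2, labs2)
  t1ev <- ev2[[which(vapply(ev2, function(e)
    identical(eventMembers(e), "t1"), TRUE))]]
  expect_equal(inferReplacedHaplotype(t1ev, tr2, labs2), "Unknown")
})

test_that("heteroplasmy calling follows the >10% non-host rule", {
  # introduced haplotype at 55%
  c1 <- callHeteroplasmy(c(B1 = 0.55, A1e = 0.45), "A1a1")
  expect_true(isHeteroplasmic(c1))
  # introduced at 15%
  c2 <- callHeteroplasmy(c(A1a1 = 0.15, A1e = 0.85), "B1")
  expect_true(isHeteroplasmic(c2))
  # minor component at 5% is below threshold
  expect_false(isHeteroplasmic(
    callHeteroplasmy(c(A1e = 0.95, A1a1 = 0.05), "B1")))
  # a 40% component explained by the matched host does not count
  expect_false(isHeteroplasmic(
    callHeteroplasmy(c(A1e = 0.60, B1 = 0.40), "B1")))
  # threshold is strict
  expect_false(isHeteroplasmic(
    callHeteroplasmy(c(A1e = 0.90, B1 = 0.10), NA_character_)))
  expect_error(callHeteroplasmy(numeric()), "non-empty")
  expect_error(callHeteroplasmy(c(A1e = 0.7, B1 = 0.1)), "sum")
})

test_that("group variants split into polymorphic-somatic and fixed", {
  donor <- data.frame(pos = 10L, ref = "A", alt = "G")
  mk <- function(sample, pos) {
    data.frame(sample = sample, pos = pos, ref = "C", alt = "T",
               supporting_reads = 10L, total_reads = 10L)
  }
  vt <- makeVariantTable(rbind(
    cbind(sample = c("t1", "t2", "t3"), donor,
          supporting_reads = 10L, total_reads = 10L),
    mk("t1", 100L), mk("t2", 100L),           # in 2 of 3: polymorphic
    mk("t1", 200L), mk("t2", 200L), mk("t3", 200L)))  # in all: fixed
  ev <- new("HTEvent", id = "HT1", donor = "X",
            members = c("t1", "t2", "t3"))
  cls <- classifyGroupVariants(ev, vt, donor)
  expect_equal(cls$fixedUnknown, "200:C:T")
  expect_equal(unname(cls$somaticCounts), c(1L, 1L, 0L))
  expect_equal(cls$somaticByMember$t1, "100:C:T")
  # singleton events classify every private variant as fixed-unknown
  solo <- new("HTEvent", id = "HT2", donor = "X", members = "t1")
  cls1 <- classifyGroupVariants(solo, vt, donor)
  expect_setequal(cls1$fixedUnknown, c("100:C:T", "200:C:T"))
  expect_equal(unname(cls1$somaticCounts), 0L)
  bad <- new("HTEvent", id = "HT3", donor = "X", members = "t9")
  expect_error(classifyGroupVariants(bad, vt, donor), "missing")
})

test_that("event locations use unanimity then parsimony", {
  ev <- new("HTEvent", id = "HT9", donor = "A1d1a",
            members = c("t1", "t2", "t3"))
  expect_equal(inferEventLocation(ev, c(t1 = "Nicaragua", t2 = "Nicaragua",
                                        t3 = "Nicaragua")), "Nicaragua")
  # 2 Belize / 1 Chile in a Belize-parsimonious clade
  tr <- ape::read.tree(text = "(((b1,b2),c1),o);")
  locs <- c(b1 = "Belize", b2 = "Belize", c1 = "Chile", o = "Belize")
  ev2 <- new("HTEvent", id = "HT8", donor = "A1d1a",
             members = c("b1", "b2", "c1"))
  expect_equal(inferEventLocation(ev2, locs, tr), "Belize")
  # two equally parsimonious locations
  tr3 <- ape::read.tree(text = "((b1,c1),(c2,b2));")
  locs3 <- c(b1 = "Belize", c1 = "Chile", c2 = "Chile", b2 = "Belize")
  ev3 <- new("HTEvent", id = "HTx", donor = "A1d1a",
             members = c("b1", "c1"))
  expect_equal(inferEventLocation(ev3, locs3, tr3), "ambiguous")
  expect_error(inferEventLocation(ev2, locs[1:2]), "missing")
})

test_that("somatic recurrence counts independent origins only", {
  pf <- syntheticProfiles()
  co <- simulateCtvtCohort(simulationConfig())
  truth <- groundTruth(co)
  key <- truth$recurrentInsertionKey
  expect_length(truth$recurrentInsertionCarriers, 2L)
  labels <- truthLabels(co)
  ev <- detectHtEvents(cohortTree(co), labels)
  n <- countSomaticRecurrence(key, cohortVariants(co), labels,
                              excludeHaplotypes = c("A1d1a", "A1d1"),
                              events = ev)
  # planted on one A1e-event member and one A1a1-event member, plus the
  # recombinant A1d1a tumours (excluded by haplotype)
  expect_equal(n, 2L)
  # a variant carried only on excluded backgrounds counts zero
  specific <- discoverHaplotypeSpecificVariants("A1d1a", pf,
                                                allowSharedWith = "A1d1")
  a1key <- grep("^7593:", specific, value = TRUE)
  expect_equal(countSomaticRecurrence(a1key, cohortVariants(co), labels,
                                      excludeHaplotypes = c("A1d1a",
                                                            "A1d1"),
                                      events = ev), 0L)
  # two carriers inside one event collapse to one occurrence
  vt <- makeVariantTable(data.frame(
    sample = c("t1", "t2"), pos = 500L, ref = "A", alt = "G",
    supporting_reads = 5L, total_reads = 5L))
  oneEvent <- list(new("HTEvent", id = "HT1", donor = "A1e",
                       members = c("t1", "t2")))
  expect_equal(countSomaticRecurrence("500:A:G", vt,
                                      c(t1 = "A1e", t2 = "A1e"),
                                      events = oneEvent), 1L)
})

test_that("detection count equals Fitch changes + 1 with distinct donors", {
  pf <- syntheticProfiles(nExtra = 6L)
  for (seed in 1:5) {
    k <- sample(5:12, 1)
    donors <- sample(profileNames(pf), k)   # distinct
    cfg <- cleanConfig(nTumours = 60, k = k, donors = donors, seed = seed)
    co <- simulateCtvtCohort(cfg, pf)
    labels <- truthLabels(co)
    ev <- detectHtEvents(cohortTree(co), labels)
    expect_length(ev, k)
    expect_equal(fitchParsimony(cohortTree(co), labels)$changes + 1L,
                 length(ev))
  }
})

test_that("introduced haplotypes resolve donors in heteroplasmic tumours", {
  co <- simulateCtvtCohort(simulationConfig())
  asg <- introducedHaplotypes(cohortVariants(co), cohortProfiles(co))
  truth <- groundTruth(co)$tumours
  expect_equal(setNames(asg$haplotype, asg$sample)[truth$tumour],
               setNames(truth$donor, truth$tumour))
  het <- asg[asg$heteroplasmic, ]
  # the two heteroplasmic single-tumour events and the recombinant pair
  expect_gte(nrow(het), 4L)
  f55 <- het$introduced_fraction[het$haplotype == "B1"]
  expect_equal(f55, 0.55, tolerance = 0.01)
  f15 <- het$introduced_fraction[het$haplotype == "A1a1"]
  expect_equal(f15, 0.15, tolerance = 0.01)
})
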