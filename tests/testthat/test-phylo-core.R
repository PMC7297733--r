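test_that("p-distance handles sequences and variant sets", {
  expect_equal(pDistance("ACGT", "ACGA"), 0.25)
  expect_equal(pDistance("ACGT", "ACGT"), 0)
  expect_equal(pDistance(c("1:A:G", "2:C:T", "3:G:A"),
                         c("4:T:C", "5:A:C"), nSites = 100), 0.05)
  expect_error(pDistance(c("1:A:G"), c("2:C:T"), nSites = 0), "> 0")
})

test_that("neighbour joining reproduces the three-taxon closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(len[["A"]], 1)
  expect_equal(len[["B"]], 1)
  expect_equal(len[["C"]], 3)
  expect_error(njTree(d[1:2, 1:2]), "3 taxa")
})

test_that("NJ recovers the generating topology of an additive matrix", {
  # true tree ((A,B),(C,D)) with internal branch 3
  tr0 <- ape::read.tree(text = "((A:1,B:2):3,(C:1.5,D:2.5):0);")
  d <- ape::cophenetic.phylo(tr0)
  tr <- njTree(d[c("A", "B", "C", "D"), c("A", "B", "C", "D")])
  # oracle: among the three possible unrooted 4-taxon topologies, the
  # generating one is the only one admitting an additive fit; NJ must
  # pair A with B
  pairs <- ape::prop.part(tr)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                         ape::unroot(tr0))), 0)
  # and reproduces the distances exactly (additivity)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
})

test_that("identical points give a star-like tree with zero lengths", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- njTree(d)
  expect_true(all(abs(tr$edge.length) < 1e-12))
})

test_that("newick I/O round-trips and validates", {
  p <- tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", p)
  tr <- readNewickTree(p)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  tr$edge.length <- c(1.5, 2.5, 3.5, 0.5)
  writeNewickTree(tr, p)
  back <- readNewickTree(p)
  expect_equal(back$tip.label, tr$tip.label)
  expect_equal(back$edge.length, tr$edge.length)
  writeLines("((A,B),A);", p)
  expect_error(readNewickTree(p), "duplicate")
  writeLines("((A,B,C);", p)
  expect_error(readNewickTree(p), "parse")
})

test_that("haplogroup assignment minimises set distance with tie flag", {
  pf <- syntheticProfiles()
  a1d1a <- variantKeysOf(profileVariants(pf, "A1d1a"))
  exact <- assignHaplotype(a1d1a, pf)
  expect_equal(exact, list(haplotype = "A1d1a", distance = 0,
                           ambiguous = FALSE))
  # one private somatic variant on top: distance 1, still unambiguous;
  # brute-force oracle over all profiles
  noisy <- c(a1d1a, "999:A:G")
  res <- assignHaplotype(noisy, pf)
  brute <- vapply(profileNames(pf), function(nm) {
    k <- variantKeysOf(profileVariants(pf, nm))
    length(setdiff(noisy, k)) + length(setdiff(k, noisy))
  }, numeric(1))
  expect_equal(res$haplotype, names(which.min(brute)))
  expect_equal(res$distance, 1)
  expect_false(res$ambiguous)
})

test_that("equidistant profiles set the ambiguity flag", {
  pf <- tinyProfiles()
  # sample midway between A1d1 {10,20} and A1d1a {10,20,30,40}:
  # carrying 10,20,30 is distance 1 from both
  mid <- c("10:A:G", "20:C:T", "30:G:A")
  res <- assignHaplotype(mid, pf)
  expect_true(res$ambiguous)
  expect_equal(res$distance, 1)
  expect_equal(res$haplotype, "A1d1")    # lexicographic tie-break
  # empty sample: nearest-to-reference profile, no ambiguity change
  res0 <- assignHaplotype(character(), pf)
  expect_equal(res0$haplotype, "A1d1")
  expect_equal(res0$distance, 2)
})

test_that("assignment is invariant to profile order", {
  pf <- tinyProfiles()
  rev <- new("HaplotypeProfileSet", profiles = base::rev(pf@profiles),
             reference = "", genomeLength = 100L)
  x <- c("10:A:G", "20:C:T", "30:G:A", "40:T:C")
  expect_equal(assignHaplotype(x, pf), assignHaplotype(x, rev))
})

test_that("Fitch parsimony counts changes correctly", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitchParsimony(tr, c(A = "h1", B = "h1", C = "h1",
                                    D = "h2"))$changes, 1L)
  expect_equal(fitchParsimony(tr, c(A = "x", B = "x", C = "x",
                                    D = "x"))$changes, 0L)
  expect_error(fitchParsimony(tr, c(A = "x", B = "x", C = "x")), "label")
})

test_that("Fitch equals the exhaustive minimum on small trees", {
  set.seed(5)
  for (i in 1:12) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n)
    labs <- setNames(sample(c("a", "b", "c"), n, replace = TRUE),
                     tr$tip.label)
    expect_equal(fitchParsimony(tr, labs)$changes,
                 bruteForceParsimony(tr, labs))
  }
  # the alternating 6-tip caterpillar from first principles
  tr <- ape::read.tree(text = "(((((A,B),C),D),E),F);")
  labs <- setNames(rep(c("h1", "h2"), 3), c("A", "B", "C", "D", "E", "F"))
  expect_equal(fitchParsimony(tr, labs)$changes,
               bruteForceParsimony(tr, labs))
})

test_that("Fitch agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(9)
  for (i in 1:8) {
    n <- sample(6:20, 1)
    tr <- ape::rtree(n)
    states <- c("a", "c", "g", "t")
    labs <- setNames(sample(states, n, replace = TRUE), tr$tip.label)
    dat <- phangorn::phyDat(matrix(labs[tr$tip.label], ncol = 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "DNA")
    expect_equal(fitchParsimony(tr, labs)$changes,
                 as.integer(phangorn::fitch(tr, dat)))
  }
})

test_that("MPR state sets refine to the surrounding background", {
  # an introduced clade nested inside a uniform background: the parent
  # of the clade takes the background state
  tr <- ape::read.tree(text = "((((e1,(a1,a2)),e2),e3),e4);")
  labs <- c(e1 = "A1e", e2 = "A1e", e3 = "A1e", e4 = "A1e",
            a1 = "A1d1a", a2 = "A1d1a")
  fit <- fitchParsimony(tr, labs)
  mrca <- ape::getMRCA(tr, c("a1", "a2"))
  parent <- tr$edge[tr$edge[, 2] == mrca, 1]
  expect_equal(fit$final[[parent]], "A1e")
  expect_equal(fit$rootStates, "A1e")
  expect_equal(fit$changes, 1L)
})
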