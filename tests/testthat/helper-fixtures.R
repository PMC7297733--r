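# Shared fixtures, all built in code.

# Minimal profile set over a short circular genome for controlled tests.
tinyProfiles <- function() {
  mk <- function(pos, ref, alt)
    data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
  new("HaplotypeProfileSet",
      profiles = list(
        A1d1  = mk(c(10L, 20L), c("A", "C"), c("G", "T")),
        A1d1a = mk(c(10L, 20L, 30L, 40L), c("A", "C", "G", "T"),
                   c("G", "T", "A", "C")),
        A1e   = mk(c(50L, 60L), c("A", "A"), c("G", "C")),
        B1    = mk(c(70L, 80L), c("C", "G"), c("A", "T"))),
      reference = "", genomeLength = 100L)
}

# A small clean partition cohort: k events with distinct donors, no
# heteroplasmy, no recombination.
cleanConfig <- function(nTumours, k, donors, ages = rep(30, k),
                        seed = 1L, ...) {
  simulationConfig(nTumours = nTumours, nHtEvents = k,
                   htDonorHaplotypes = donors,
                   memberCounts = integer(),
                   eventAges = ages,
                   heteroplasmyFractions = rep(NA_real_, k),
                   incumbentHaplotypes = rep(NA_character_, k),
                   recombinantEventIndex = 0L, seed = seed, ...)
}

# Truth labels of a cohort (tumour -> donor haplotype).
truthLabels <- function(cohort) {
  tt <- groundTruth(cohort)$tumours
  setNames(tt$donor, tt$tumour)
}

# Exhaustive-minimum parsimony oracle for small trees: tries every
# assignment of observed states to internal nodes.
bruteForceParsimony <- function(tree, tipLabels) {
  states <- sort(unique(unname(tipLabels)))
  nTip <- length(tree$tip.label)
  nInt <- tree$Nnode
  edges <- tree$edge
  tipState <- match(tipLabels[tree$tip.label], states)
  grid <- do.call(expand.grid, rep(list(seq_along(states)), nInt))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign <- c(tipState, as.integer(grid[r, ]))
    cost <- sum(assign[edges[, 1L]] != assign[edges[, 2L]])
    if (cost < best) best <- cost
  }
  best
}
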