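---
title: "Models and methods behind mtHijack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtHijack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtHijack)
```

# Overview

CTVT (canine transmissible venereal tumour) is a clonal cancer lineage
transmitted between dogs as living cells. Its mitochondrial genomes are
periodically replaced by host mtDNA ("horizontal transfer", HT), and the
canine haplotype A1d1a is captured far more often than its population
frequency predicts, consistent with selfish selection driven by a
control-region insertion (16660insCC). `mtHijack` implements the full
computational chain of such an analysis — detection, enrichment testing,
dating, copy number, recombinant phasing and transcript abundance — with
a synthetic-cohort generator so that every stage is testable against
known ground truth. This vignette records the models, the tunable
parameters, and the choices made where the underlying procedures were
open.

# Horizontal-transfer detection

**Model.** HT is inferred from discordance between the nuclear phylogeny
(clonal tumour history) and per-tumour mtDNA haplotype assignments. We
formalise "tumours clustering together on both trees" as: tumours
sharing a donor haplotype are partitioned into maximal subsets, each of
which is the complete tip set of a nuclear-tree clade containing only
members of that subset. Each subset is one HT event. mtDNA-side
clustering is implied by the shared haplotype assignment, so only the
nuclear tree enters the partition.

*Assumptions and edge behaviour.* The rule is exact when each true
event's members form an uncontaminated nuclear clade. If tree error (or
an incumbent "background" lineage pierced by nested captures) makes an
event paraphyletic, the rule splits it into several reported events
rather than merging across clades; the split is visible in the event
table. This is deliberate: merging heuristics would hide tree conflict.

**Replaced haplotype.** The incumbent haplotype an event displaced is
read off the final Fitch most-parsimonious-reconstruction (MPR) state of
the *parent* of the event's clade; a non-singleton MPR set, or a clade
at the root, yields `"Unknown"`. `fitchParsimony()` implements the
two-pass algorithm (Hartigan's counting rule bottom-up, so
multifurcations are scored exactly; the standard refinement rules
top-down). An independent implementation (`phangorn::fitch`) and an
exhaustive enumeration over small trees serve as test oracles.

Note that in a cohort where *every* tumour belongs to some clean event
clade and donors are pairwise distinct, all internal MPR sets are
unions, so the honest answer for every event is `"Unknown"`; a
recoverable replaced haplotype requires the event to be nested inside a
background of incumbent-haplotype tumours, as in the real tumour
phylogeny.

**Heteroplasmy.** A tumour is heteroplasmic when two or more haplotypes
each exceed 10% frequency (strict inequality) *after* removing any
haplotype explained by the matched host's germline — host removal
precedes the threshold test, since host contamination would otherwise
mimic heteroplasmic transfer.

Per-tumour haplotype fractions are estimated from variant allele
fractions (VAFs): for each haplotype, the median VAF over **all** of its
private marker variants (variants belonging to exactly one profile),
with unobserved markers counting as zero. Counting absent markers is
what makes the estimate robust: a single somatic mutation that happens
to coincide with another haplotype's marker (e.g. a recurrent somatic
16660insCC on an incumbent background) cannot fake a haplotype.

**Which haplotype was introduced?** For a heteroplasmic tumour the
introduced (donated) haplotype is the carried haplotype that is *not*
one of the long-established incumbent lineage haplotypes; when both
carried haplotypes are incumbent-lineage (as for a recent capture of one
incumbent haplotype into a tumour carrying the other), the *minor*
haplotype is taken, on the reasoning that a recent transfer has not yet
reached fixation. This deterministic rule reproduces manual table
assignments on the default cohort, including the 15%-minor capture.

# Enrichment of A1d1a captures

Under the null that every haplotype has equal transfer opportunity
relative to its population frequency, each of the `n` observed events
draws its donor i.i.d. from the host-population haplotype frequencies.
`enrichmentTest()` performs the simulation (default 10,000 replicates,
seed 76) and reports the raw empirical upper-tail p — the proportion of
replicates with target count ≥ observed, which can legitimately be 0 —
alongside a clearly labelled (k+1)/(n+1) estimator for users who need a
strictly positive value. Because only the target's marginal matters, the
exact binomial tail `exactTailProbability()` (direct summation of
probability mass terms) is the closed-form oracle; tests require the
empirical value to sit within 3 Monte-Carlo standard errors of it.
Whether the original simulation drew per-event categories or one
multinomial per replicate is immaterial for this marginal; we draw
per-event. A `restrictedToPairs` flag records the conservative variant
in which only events with a sampled matched host enter `n` and `k`.

The shipped 18-haplotype frequency table (A1d1a at 99/495 = 0.20) is a
synthetic stand-in shaped like a global host-dog survey; with 11 of 19
events from a haplotype at frequency 0.20 the exact tail is 3.1e-4,
comfortably below the 0.001 headline threshold.

# Molecular clock

The somatic mtDNA mutation rate is anchored on a dated divergence of the
two oldest tumour lineages: rate = mean somatic count / divergence years
= 9.437 / 469.28 = 0.0201 mutations/year, with the interval obtained by
dividing by the divergence-time 95% HPD bounds (240.34–744.31 years →
0.0127–0.0393/yr). An event's age is its mean somatic burden divided by
the rate. Only *polymorphic* somatic variants enter the burden: a
variant absent from the donor profile but present in **all** members of
an event is "fixed-unknown" (germline or somatic status undetermined)
and excluded; a variant in a strict subset of members is confidently
somatic. A singleton event therefore has burden 0 and cannot be dated —
an honest limitation of the published rule, inherited here.

# mtDNA copy number

Copies per cell = (mtCOV × T~mt~) / (nuclCOV × T~nuc~) × P with ploidy
P = 2. The nuclear tumour fraction T~nuc~ is 2 × the modal somatic VAF
(diploid heterozygous somatic variants sit at half the tumour fraction).
The original mode procedure is unstated, so we fix a reproducible one: a
histogram over (0.05, 0.95] with bin width 0.02, mode = midpoint of the
maximal bin, ties resolving to the lower bin. The mtDNA tumour fraction
T~mt~ is the median VAF of tumour-specific homoplasmic mtDNA variants
(host-derived molecules dilute each one equally); the median is our
choice where the source states only "estimated from VAF". The estimate
is invariant under uniform scaling of both coverages, and cohorts
generated at known copy number (50–500) are recovered within 5% mean
error through the full estimator chain.

# Recombinant-haplotype phasing

The HT3-like situation — a donor haplotype recombined with the incumbent
mtDNA, leaving a heteroplasmic pool of recombinant haplotypes — is
phased from long-read allele patterns at informative sites (sites
diagnostic between the two parents). The original phasing was done by
visual inspection; we formalise it as clustering by exact allele-pattern
agreement, with missing calls acting as wildcards: complete reads seed
clusters (largest first, lexicographic tie-break), a partial read joins
the largest compatible cluster, ties leave it unassigned, and
incompatible partial patterns open their own clusters. Haplotypes below
5% frequency are flagged low-level but never dropped, because the
fixed-variant analysis must quantify over *all* haplotypes: the variant
fixed across every phased haplotype (the 16660insCC analogue in the
synthetic mixtures) is the intersection of the donor-specific variant
set with each haplotype's carried variants.

Ancestry segments are the runs of same-parent sites around the circular
genome; breakpoints are placed midway between adjacent discordant
informative sites (no finer resolution exists in the data) and may wrap
through the origin. On a circle the breakpoint count is necessarily
even, and equals the exhaustive minimum over segmentations.

*Noise model.* Sequencing noise in the read generator is per-site allele
dropout (default 2%), which the wildcard matching absorbs exactly.
Substitution-type read errors are *not* simulated: under exact-pattern
clustering they would surface as spurious low-level haplotypes, so real
data should be error-filtered upstream (e.g. by requiring duplicate
support per pattern) before phasing. This is a known limitation of the
formalisation, documented rather than hidden behind a filter the
original analysis did not describe.

# Transcript abundance

Counts are normalised by median-of-ratios size factors (rescaled to
geometric mean 1), transformed as log2(normalised + 1), batch-corrected
per gene by an additive least-squares model (group + batch, sum-to-zero
batch contrasts), then mapped back to the linear scale with each gene's
grand mean preserved — the exact post-correction scaling is unstated in
the source, and grand-mean preservation is our convention. A regularised
log transform and negative-binomial Wald tests are deliberately *not*
re-implemented: the package's claims are about parameter recovery on
synthetic data, and a rank test over log-scale corrected abundances is
the appropriately assumption-light replacement (a documented
simplification).

The class-level comparison reports the percent change of group means of
per-sample mean mtDNA-gene abundance, with a two-sided Mann–Whitney test
on the per-gene group means (13 values per group for the mtDNA class),
exact by enumeration when the pooled size is ≤ 16 and tie-free, normal
approximation with tie and continuity corrections otherwise. Per-gene
tests are Mann–Whitney across samples with Benjamini–Hochberg adjustment
restricted to exactly the supplied gene list (13 mtDNA + 7 nuclear),
mirroring restricted hypothesis testing.

*Generator realism.* `simulateExpressionCounts()` draws
negative-binomial counts (dispersion 0.15, a typical bulk RNA-seq
value), multiplies mtDNA-gene means in the affected group by
(1 − effect), leaves nuclear genes untouched, and adds per-batch
per-gene multiplicative factors (log2 s.d. 0.3) plus per-sample library
factors. It also includes 200 unaffected background genes: real
normalisation is transcriptome-wide, and without a background the
median-of-ratios factors would absorb a class-wide effect touching 13 of
20 genes — a composition artefact of the reduced gene universe, not of
the method. With 15 samples per group the planted 39% decrease is
recovered within a few percentage points and detected at p < 0.05 in
essentially every run; gene-level base means spread by a factor ~2
(log2 s.d. 0.4), which is what makes the 13-vs-13 rank test powerful at
this effect size.

# The synthetic cohort generator

Defaults are the study conditions: 539 tumours in 19 HT events whose
donors, member counts, heteroplasmic fractions (0.55 and 0.15 with an
incumbent complement) and one recombinant event mirror the published
event table; a 495-dog host population over 18 haplotype frequencies;
somatic mutations as Poisson(rate × age) per tumour with rate
0.0201/yr, placed uniformly on the circular 16,727-bp genome outside
profile sites (no positional model is claimed in the source); and two
planted independent somatic copies of the control-region insertion on
incumbent backgrounds, mirroring its observed recurrence. Event ages
default to 469.28 years for the old second lineage (so its mean burden
reproduces the 9.437 calibration anchor) and 29.35 years for recent
captures (0.59 expected somatic mutations). The nuclear tree joins each
event's member caterpillar along a caterpillar backbone, making every
event a clean clade; when donors are sampled rather than given, the
first two events are forced to differ so that no same-donor sibling
clades merge.

Haplogroup profiles are synthetic stand-ins for the 18 published
haplotype names, nested cladistically (shared blocks for the A, A1,
A1d and A1d1 branches and the B and C groups) with ≥ 8 private markers
per haplotype; A1d1a carries exactly eight private substitutions (one at
the published non-synonymous locus 7593) plus the private 16660
two-cytosine insertion, and shares 16672C>T with A1d1. Extra synthetic
haplogroups (`nExtra`) extend the panel when stress tests need more
than 18 distinct donors. Profiles and frequencies are deterministic
fixtures (private random stream, constant across sessions) and are not
the real supplementary tables; user-supplied TSVs drop in everywhere.

What the generator does **not** emulate: within-tumour mtDNA population
drift (heteroplasmy fractions are set directly, since the capture-time
population size is unknown), read-level FASTQ/BAM artefacts, alignment
and caller idiosyncrasies, nuclear-tree reconstruction error, and
selection dynamics within a cell. Passing tests therefore demonstrate
correctness of the *analysis logic* under clean trees and calibrated
noise, not robustness to upstream bioinformatics error.

# Numerical and I/O conventions

* Coordinates are 1-based, inclusive, circular, genome length 16,727
  (matching published variant positions such as 16660 and 7593).
* Indels are anchored at the base preceding the inserted/deleted
  sequence and left-aligned within repeat context, wrapping through the
  origin; canonicalisation is idempotent and matched against an
  exhaustive-shift oracle in tests. Left alignment is a repository
  convention (the source does not state its representation).
* VCF output is v4.2, single-sample, contig `MT`, with GT:AD:DP
  carrying supporting/total reads; `vcfR` is the reader, so write→read
  round trips cross two implementations.
* Substitution calls require ≥ 3 supporting reads with mapping quality
  ≥ 20 and base quality ≥ 20; the 10-bp read-end base-quality masking
  happens upstream at the alignment level and is out of scope here.
* Neighbour joining and newick I/O use `ape`; NJ output is
  deterministic in taxon order with Q-criterion ties resolved by the
  first pair in input order. Haplogroup assignment breaks distance ties
  lexicographically and flags them as ambiguous.
* All generator functions consume a single seed recorded in their
  configuration; fixture bundles embed it in `config.yaml`. Replicate
  streams are generator-specific: the original analysis seed cannot
  reproduce the same replicate stream in another language, so only
  distributional equivalence is claimed, and the enrichment report says
  so in its metadata.

# Problem sizes used by the test suite

The suite exercises: 200 simulated cohorts of 100–600 tumours with 5–20
distinct-donor events for detection recovery (with the cross-algorithm
identity "event count = Fitch changes + 1", which holds exactly when
donors are pairwise distinct — repeated donors let parsimony reuse an
ancestral state, so the identity is checked only there); 1,000
two-member events at age 100 years for dating coverage against the
Poisson 95% envelope; 10,000-replicate enrichment runs plus 50
randomised oracle comparisons at 4,000 replicates; copy-number recovery
at 50–500 copies across 20 samples each; 100 seeded recombinant
mixtures; and 60 expression cohorts at n = 15 per group. These sizes
were chosen as the smallest that make the statistical assertions sharp.

# Known limitations

* Background (incumbent-lineage) tumours paraphyletic around nested
  captures are reported as split events; the event table is the place
  to notice and, if appropriate, manually merge them.
* Singleton events cannot be dated (their private variants are
  fixed-unknown by the classification rule).
* The enrichment test conditions on the observed number of events; it
  does not model the transfer process through time.
* Phasing assumes pre-extracted allele patterns at sites diagnostic
  between exactly two parents; three-way recombination or non-diagnostic
  sites are rejected rather than modelled.
* ML tree inference and bootstrap support are intentionally out of
  scope; trees are ingested (newick) or built by neighbour joining.
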