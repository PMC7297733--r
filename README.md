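# mtHijack

Detection, dating and characterisation of mitochondrial DNA horizontal
transfer in transmissible cancer.

## The scientific problem

Canine transmissible venereal tumour (CTVT) is a cancer lineage that
spreads between dogs as living cells. During its history, tumour cells
have repeatedly captured mitochondrial genomes from their host dogs
("horizontal transfer", HT). Strikingly, one canine mtDNA haplotype —
A1d1a — accounts for a disproportionate share of these captures, and a
two-cytosine insertion in its control region (16660insCC) near the light
strand promoter is the leading candidate for a *selfish* replicative
advantage that sweeps the incoming haplotype to fixation.

`mtHijack` implements the complete computational analysis behind this
kind of study, exercisable end to end on synthetic cohorts with known
ground truth:

* **HT detection** from discordance between nuclear and mtDNA
  phylogenies: tumours sharing a donor haplotype are partitioned into
  maximal monophyletic groups on the nuclear tree
  (`detectHtEvents()`), with the replaced incumbent haplotype read off
  the parent clade's Fitch most-parsimonious-reconstruction state
  (`inferReplacedHaplotype()`, `fitchParsimony()`).
* **Haplogroup assignment** of dogs and tumours by minimum
  symmetric-difference distance to named variant profiles
  (`assignHaplotype()`), plus heteroplasmy calling: two or more
  haplotypes each above 10% frequency, not explained by the matched
  host (`callHeteroplasmy()`).
* **Enrichment testing**: the probability of observing `k` of `n` HT
  events from one haplotype under equal transfer opportunity, by
  multinomial simulation with an exact binomial-tail oracle
  (`enrichmentTest()`, `exactTailProbability()`):
  empirical p = #{replicates with count ≥ k} / replicates.
* **Molecular-clock dating**: rate = mean somatic mutations /
  divergence years (0.0201/yr from 9.437 / 469.28), age = somatic count
  / rate (`calibrateRate()`, `dateHtEvent()`), counting only
  polymorphic somatic variants (`classifyGroupVariants()`).
* **mtDNA copy number** per cell as (mtCOV·T<sub>mt</sub>) /
  (nuclCOV·T<sub>nuc</sub>) × ploidy, with the nuclear tumour fraction
  from the somatic VAF mode × 2 (`mtdnaCopyNumber()`,
  `estimateNuclearTumourFraction()`).
* **Recombinant-haplotype phasing** from long-read allele patterns on
  the circular genome, with minimal-breakpoint ancestry segments and
  the variant fixed across all haplotypes (`phaseLongReads()`,
  `segmentAncestry()`, `fixedVariants()`).
* **Transcript abundance**: median-of-ratios normalisation, linear-model
  batch correction, Mann–Whitney group comparison and
  Benjamini–Hochberg-restricted per-gene testing
  (`analyseTranscriptAbundance()`).
* **Synthetic cohorts** (`simulateCtvtCohort()` and friends) whose
  defaults mirror the published study conditions: 539 tumours in 19 HT
  events (11 with donor A1d1a), heteroplasmic fractions 0.55 and 0.15,
  one recombinant event, a 495-dog host population over 18 haplotype
  frequencies, and a somatic clock of 0.0201 mutations/year.

The shipped haplogroup profiles and host-population frequencies are
synthetic stand-ins with the published structure; real tables can be
supplied as TSV (`readHaplotypeProfiles()`,
`readHaplotypeFrequencies()`).

## Worked example

```r
library(mtHijack)

cohort <- simulateCtvtCohort(simulationConfig(seed = 76))
cohort
#> CtvtCohort: 539 tumours, 19 HT events, 19638 variant calls

asg <- introducedHaplotypes(cohortVariants(cohort), cohortProfiles(cohort))
events <- detectHtEvents(cohortTree(cohort),
                         setNames(asg$haplotype, asg$sample),
                         setNames(asg$introduced_fraction, asg$sample))
head(htEventTable(events), 5)
#>   event donor replaced n_tumours percent_heteroplasmy  location
#> 1   HT1  A1a1  Unknown       285                  100 ambiguous
#> 2   HT2   A1e  Unknown       205                  100 ambiguous
#> 3   HT3 A1d1a  Unknown        14                  100 ambiguous
#> 4   HT4 A1d1a  Unknown         7                  100 ambiguous
#> 5   HT5  A1a1  Unknown         6                  100 ambiguous

enrichmentTest(syntheticHostFrequencies(), nEvents = length(events),
               observedCount = sum(sapply(events, eventDonor) == "A1d1a"),
               target = "A1d1a")
#> EnrichmentResult: 11/19 events for A1d1a; empirical p = 0.0002 (exact 0.0003095)

rate <- calibrateRate(9.437, 469.28, c(240.34, 744.31))
rate
#> RateEstimate: 0.0201 mutations/yr (0.0127-0.0393)
dateHtEvent(0.59, rate)$years    # a recent A1d1a capture
#> [1] 29.33932
```

The detection recovers all 19 embedded events with 11 A1d1a donors; the
empirical enrichment p-value (0.0002 at 10,000 replicates) sits within
Monte-Carlo error of the exact binomial tail, far below 0.001; and the
calibrated clock dates a mean burden of 0.59 somatic mutations to about
29 years — a capture within recent decades.

A YAML-configured pipeline runs every stage and writes TSV/JSON reports
plus a digest manifest:

```r
runPipeline(system.file("extdata", "demo_config.yaml",
                        package = "mtHijack"), "reports")
```

or from a shell via `inst/scripts/mthijack run --config cfg.yaml --out
reports` (subcommands `validate`, `simulate` and `enrich` are also
available; the remaining stages are the exported R functions).

## Vignette

`vignettes/mtHijack-methods.Rmd` documents the models, rules and
numerical choices behind each stage, what the synthetic generator does
and does not emulate, and known limitations.
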