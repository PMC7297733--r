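#' @include AllClasses.R syntheticCohort.R htDetection.R selectionStats.R
#' @include copyNumber.R recombination.R transcriptAbundance.R
NULL

#' Validate a pipeline configuration
#'
#' Checks the YAML configuration for a pipeline run and returns all
#' problems at once (cross-field constraints, stage dependencies); no
#' stage is executed.
#'
#' @param configPath path to a YAML configuration file.
#' @return list with \code{ok} (logical) and \code{errors} (character).
#' @export
validateConfig <- function(configPath) {
  errors <- character()
  cfg <- tryCatch(yaml::read_yaml(configPath), error = function(e) {
    errors <<- c(errors, paste("cannot parse config:",
                               conditionMessage(e)))
    NULL
  })
  if (is.null(cfg)) return(list(ok = FALSE, errors = errors, config = NULL))
  seed <- cfg$seed
  if (is.null(seed) || !is.numeric(seed))
    errors <- c(errors, "seed: must be a number")
  stages <- unlist(cfg$stages)
  known <- c("simulate", "assign", "detect", "enrich", "date",
             "copy_number", "phase", "expression")
  bad <- setdiff(stages, known)
  if (length(bad))
    errors <- c(errors, paste("unknown stage(s):",
                              paste(bad, collapse = ", ")))
  simulate <- "simulate" %in% stages
  freqs <- unlist(cfg$cohort$haplotype_freqs)
  if (!is.null(freqs) && abs(sum(freqs) - 1) > 1e-6)
    errors <- c(errors, sprintf(
      "cohort.haplotype_freqs: must sum to 1 (got %.6f)", sum(freqs)))
  mr <- cfg$cohort$mutation_rate
  if (!is.null(mr) && mr < 0)
    errors <- c(errors, "cohort.mutation_rate: must be >= 0")
  if (!simulate) {
    needInputs <- c("variants", "tree", "profiles")
    for (x in intersect(c("assign", "detect", "date"), stages)) {
      missing <- needInputs[!vapply(cfg$inputs[needInputs], function(p)
        !is.null(p) && file.exists(p), TRUE)]
      if (length(missing)) {
        errors <- c(errors, paste0("stage '", x, "' needs inputs: ",
                                   paste(missing, collapse = ", ")))
        break
      }
    }
    if (any(c("copy_number", "phase", "expression") %in% stages))
      errors <- c(errors,
                  "copy_number/phase/expression need the simulate stage ",
                  "or dedicated inputs (not configured)")
  }
  rate <- cfg$rate
  if (!is.null(rate)) {
    if (!is.null(rate$divergence_years) && rate$divergence_years <= 0)
      errors <- c(errors, "rate.divergence_years: must be > 0")
  }
  ef <- cfg$expression$effect_fraction
  if (!is.null(ef) && (ef < 0 || ef >= 1))
    errors <- c(errors, "expression.effect_fraction: must lie in [0, 1)")
  list(ok = !length(errors), errors = errors, config = cfg)
}

.stageTimer <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[mtHijack] stage %s ...", name))
  res <- force(expr)
  message(sprintf("[mtHijack] stage %s done (%.2fs)", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (simulate, assign haplotypes,
#' detect horizontal transfers with heteroplasmy, enrichment, dating,
#' copy number, recombinant phasing, expression), writing a Table-style
#' event TSV, machine-readable JSON reports and a run manifest with file
#' digests. All randomness flows from the single configured seed; two
#' runs with the same configuration produce identical reports (the
#' manifest records the timestamp separately).
#'
#' @param configPath path to a YAML configuration file (see
#'   \code{system.file("extdata", "demo_config.yaml",
#'   package = "mtHijack")}).
#' @param outDir report directory (created).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(configPath, outDir) {
  val <- validateConfig(configPath)
  if (!val$ok)
    stop("invalid configuration:\n  ",
         paste(val$errors, collapse = "\n  "))
  cfg <- val$config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  stages <- unlist(cfg$stages)
  warnings <- character()
  outputs <- character()
  emit <- function(x, file) {
    path <- file.path(outDir, file)
    if (is.data.frame(x))
      write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    outputs <<- c(outputs, path)
    path
  }

  co <- cfg$cohort
  profiles <- if (!is.null(cfg$inputs$profiles))
    readHaplotypeProfiles(cfg$inputs$profiles) else syntheticProfiles()
  freqs <- if (!is.null(co$haplotype_freqs)) unlist(co$haplotype_freqs)
           else if (!is.null(cfg$inputs$frequencies))
             readHaplotypeFrequencies(cfg$inputs$frequencies)
           else syntheticHostFrequencies()

  cohort <- NULL
  if ("simulate" %in% stages) {
    simConfig <- .stageTimer("simulate", {
      args <- list(haplotypeFreqs = freqs, seed = seed)
      for (nm in c("n_dogs", "n_tumours", "n_ht_events", "mutation_rate",
                   "genome_length")) {
        if (!is.null(co[[nm]])) {
          arg <- c(n_dogs = "nDogs", n_tumours = "nTumours",
                   n_ht_events = "nHtEvents",
                   mutation_rate = "mutationRate",
                   genome_length = "genomeLength")[[nm]]
          args[[arg]] <- co[[nm]]
        }
      }
      do.call(simulationConfig, args)
    })
    cohort <- simulateCtvtCohort(simConfig, profiles)
    writeFixtureBundle(cohort, file.path(outDir, "cohort"),
                       writeVcf = isTRUE(co$write_vcf),
                       writeFasta = isTRUE(co$write_fasta))
    variants <- cohort@variants
    tree <- cohort@tree
  } else {
    variants <- readVariantTable(cfg$inputs$variants)
    tree <- readNewickTree(cfg$inputs$tree)
  }

  assignments <- NULL
  if (any(c("assign", "detect", "date", "enrich") %in% stages)) {
    assignments <- .stageTimer("assign",
      introducedHaplotypes(variants, profiles))
    emit(assignments, "assignments.tsv")
  }

  events <- NULL
  if (any(c("detect", "date", "enrich") %in% stages)) {
    events <- .stageTimer("detect", {
      labels <- setNames(assignments$haplotype, assignments$sample)
      hf <- setNames(assignments$introduced_fraction, assignments$sample)
      ev <- detectHtEvents(tree, labels, hf)
      for (i in seq_along(ev))
        ev[[i]]@replaced <- inferReplacedHaplotype(ev[[i]], tree, labels)
      ev
    })
    emit(htEventTable(events), "events.tsv")
  }

  if ("enrich" %in% stages) {
    en <- cfg$enrichment
    target <- if (!is.null(en$target)) en$target else "A1d1a"
    nEvents <- if (!is.null(en$n_events)) en$n_events else length(events)
    observed <- if (!is.null(en$observed)) en$observed
                else sum(vapply(events, eventDonor, "") == target)
    reps <- if (!is.null(en$replicates)) en$replicates else 10000L
    res <- .stageTimer("enrich",
      enrichmentTest(freqs, nEvents, observed, target,
                     replicates = reps, seed = seed))
    emit(list(target = res@target, n_events = res@nEvents,
              observed = res@observedCount, replicates = res@replicates,
              seed = res@seed, empirical_p = res@empiricalP,
              empirical_p_smoothed = res@empiricalPSmoothed,
              exact_p = res@exactP,
              note = paste("replicate streams are generator-specific;",
                           "only distributional equivalence with other",
                           "implementations is claimed")),
         "enrichment.json")
  }

  if ("date" %in% stages) {
    rt <- cfg$rate
    rate <- calibrateRate(
      if (is.null(rt$mean_mutations)) 9.437 else rt$mean_mutations,
      if (is.null(rt$divergence_years)) 469.28 else rt$divergence_years,
      if (is.null(rt$divergence_interval)) c(240.34, 744.31)
      else unlist(rt$divergence_interval))
    dating <- .stageTimer("date", do.call(rbind, lapply(events, function(e) {
      cls <- classifyGroupVariants(e, variants,
                                   profileVariants(profiles, e@donor))
      meanCount <- mean(cls$somaticCounts)
      d <- dateHtEvent(meanCount, rate)
      data.frame(event = e@id, donor = e@donor,
                 mean_somatic = meanCount,
                 n_fixed_unknown = length(cls$fixedUnknown),
                 years = d$years, years_low = d$interval[["low"]],
                 years_high = d$interval[["high"]])
    })))
    emit(dating, "dating.tsv")
  }

  if ("copy_number" %in% stages && !is.null(cohort)) {
    cn <- .stageTimer("copy_number", {
      idx <- head(sampleNames(variants), 12L)
      sub <- makeVariantTable(
        variants@calls[variants@calls$sample %in% idx, , drop = FALSE],
        variants@genomeLength)
      rs <- simulateReadSupport(sub, seed = seed + 1L)
      do.call(rbind, lapply(seq_along(idx), function(i) {
        s <- idx[i]
        calls <- sampleCalls(rs$variants, s)
        nf <- estimateNuclearTumourFraction(rs$nuclearVafs[[s]])
        mf <- estimateMtTumourFraction(calls$vaf[calls$vaf > 0.5])
        cov <- rs$coverage[rs$coverage$sample == s, ]
        data.frame(sample = s,
                   copy_number = mtdnaCopyNumber(cov$mt_cov, cov$nuc_cov,
                                                 mf, nf))
      }))
    })
    emit(cn, "copy_number.tsv")
  }

  if ("phase" %in% stages && !is.null(cohort) &&
      cohort@config@recombinantEventIndex > 0L) {
    rec <- .stageTimer("phase", {
      mix <- simulateRecombinantMixture(seed = seed + 2L)
      reads <- simulateRecombinantReads(mix, seed = seed + 3L)
      ph <- phaseLongReads(reads)
      donorSpecific <- discoverHaplotypeSpecificVariants(
        "A1d1a", profiles, allowSharedWith = "A1d1")
      siteKeys <- setNames(
        paste0(mix$sites, ":."), as.character(mix$sites))
      insRow <- cohort@truth$recurrentInsertionKey
      if (!is.null(insRow))
        siteKeys[as.character(mix$universalSite)] <- insRow
      fx <- fixedVariants(carriedVariants(ph, siteKeys), donorSpecific)
      list(n_haplotypes = nrow(haplotypePatterns(ph)),
           frequencies = haplotypeFrequencies(ph),
           low_level = sum(ph@lowLevel),
           fixed_donor_variants = as.list(fx))
    })
    emit(rec, "recombination.json")
  }

  if ("expression" %in% stages) {
    ex <- cfg$expression
    nPer <- if (is.null(ex$n_per_group)) 15L else ex$n_per_group
    eff <- if (is.null(ex$effect_fraction)) 0.39 else ex$effect_fraction
    res <- .stageTimer("expression", {
      grp <- setNames(rep(c("A1d1a", "CTVT_HT1", "CTVT_HT2"),
                          c(nPer, ceiling(nPer / 2), floor(nPer / 2))),
                      NULL)
      se <- simulateExpressionCounts(grp, effectFraction = eff,
                                     seed = seed + 4L)
      analyseTranscriptAbundance(se, groupA = "A1d1a")
    })
    emit(list(mt_percent_decrease = res$mtChange$percentChange,
              mt_p = res$mtChange$p,
              nuclear_percent_change = res$nuclearChange$percentChange,
              nuclear_p = res$nuclearChange$p,
              n_genes_q_lt_0.05 =
                sum(res$perGene$q < 0.05 &
                      grepl("^MT", res$perGene$gene))),
         "expression.json")
  }

  manifest <- list(
    package = as.character(packageVersion("mtHijack")),
    seed = seed, stages = as.list(stages),
    config = cfg,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    warnings = as.list(warnings),
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
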