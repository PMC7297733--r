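#' @include AllClasses.R utils.R profiles.R variantStore.R phyloCore.R
NULL

## Table-style default study conditions: 19 horizontal-transfer events
## (11 with donor A1d1a), member counts summing to 539 tumours, two
## heteroplasmic events (0.55, 0.15) and one recombinant event nested on
## the A1e incumbent background.
.DEFAULT_DONORS <- c("A1e", "A1a1", "A1d1a", "A1a1", "A1d1", "A1a1",
                     "A1a1", "A1d1a", "A1d1a", "A1d1a", "A1d1a", "A1d1a",
                     "A1d1a", "A1d1a", "A1d1a", "A1d1a", "A1d1a", "B1",
                     "A1a1")
.DEFAULT_MEMBERS <- c(205L, 285L, 2L, 6L, 2L, 2L, 1L, 7L, 14L, 1L, 1L,
                      1L, 1L, 1L, 1L, 3L, 4L, 1L, 1L)
## ages: the two ancient incumbent lineages, two intermediate events and
## recent captures at 0.59/0.0201 = 29.35 years (so the recent events
## carry very few somatic mutations)
.DEFAULT_AGES <- c(500, 469.28, 29.35, 200, 150, 29.35, 29.35,
                   rep(29.35, 10), 29.35, 29.35)
.DEFAULT_HET <- c(rep(NA_real_, 17), 0.55, 0.15)
.DEFAULT_INCUMBENTS <- c(rep(NA_character_, 2), "A1e",
                         rep(NA_character_, 14), "A1e", "A1e")

#' Build a simulation configuration
#'
#' Defaults are the study conditions of the published cohort: 495 host
#' dogs over 18 haplotype frequencies, 539 tumours in 19
#' horizontal-transfer events with the published donor haplotypes (11
#' A1d1a), member counts, heteroplasmic fractions 0.55 and 0.15, the
#' recombinant third event, and a somatic mtDNA clock of 0.0201
#' mutations/year. Every field can be overridden for scaled-down or
#' randomised cohorts.
#'
#' @param nDogs host-dog population size.
#' @param haplotypeFreqs named frequencies summing to 1.
#' @param nTumours,nHtEvents cohort size and event count.
#' @param htDonorHaplotypes donor per event (character(0) = sample).
#' @param memberCounts tumours per event (integer(0) = random split).
#' @param mutationRate somatic mutations per year.
#' @param eventAges event ages in years.
#' @param heteroplasmyFractions introduced-haplotype fraction per event
#'   (NA = homoplasmic).
#' @param incumbentHaplotypes incumbent haplotype per event (used for
#'   heteroplasmic and recombinant events).
#' @param recombinantEventIndex which event is recombinant (0 = none).
#' @param recombinantBreakpoints two circular breakpoints delimiting the
#'   donor-fixed segment (walking forward from the first to the second).
#' @param genomeLength circular genome length (bp).
#' @param seed integer seed of the run's single random stream.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nDogs = 495L,
                             haplotypeFreqs = syntheticHostFrequencies(),
                             nTumours = 539L, nHtEvents = 19L,
                             htDonorHaplotypes = .DEFAULT_DONORS,
                             memberCounts = .DEFAULT_MEMBERS,
                             mutationRate = 0.0201,
                             eventAges = .DEFAULT_AGES,
                             heteroplasmyFractions = .DEFAULT_HET,
                             incumbentHaplotypes = .DEFAULT_INCUMBENTS,
                             recombinantEventIndex = 3L,
                             recombinantBreakpoints = c(15900, 700),
                             genomeLength = 16727L, seed = 76L) {
  ## when the caller shrinks the cohort, drop the Table-style defaults
  if (nHtEvents != length(htDonorHaplotypes) &&
      identical(htDonorHaplotypes, .DEFAULT_DONORS))
    htDonorHaplotypes <- character()
  if (length(memberCounts) && identical(memberCounts, .DEFAULT_MEMBERS) &&
      (nHtEvents != length(.DEFAULT_MEMBERS) ||
       nTumours != sum(.DEFAULT_MEMBERS)))
    memberCounts <- integer()
  if (nHtEvents != length(eventAges) &&
      identical(eventAges, .DEFAULT_AGES))
    eventAges <- rep(30, nHtEvents)
  if (nHtEvents != length(heteroplasmyFractions) &&
      identical(heteroplasmyFractions, .DEFAULT_HET))
    heteroplasmyFractions <- rep(NA_real_, nHtEvents)
  if (nHtEvents != length(incumbentHaplotypes) &&
      identical(incumbentHaplotypes, .DEFAULT_INCUMBENTS))
    incumbentHaplotypes <- rep(NA_character_, nHtEvents)
  if (recombinantEventIndex > nHtEvents) recombinantEventIndex <- 0L
  new("SimulationConfig", nDogs = as.integer(nDogs),
      haplotypeFreqs = haplotypeFreqs, nTumours = as.integer(nTumours),
      nHtEvents = as.integer(nHtEvents),
      htDonorHaplotypes = htDonorHaplotypes,
      memberCounts = as.integer(memberCounts),
      mutationRate = mutationRate, eventAges = eventAges,
      heteroplasmyFractions = heteroplasmyFractions,
      incumbentHaplotypes = incumbentHaplotypes,
      recombinantEventIndex = as.integer(recombinantEventIndex),
      recombinantBreakpoints = recombinantBreakpoints,
      genomeLength = as.integer(genomeLength), seed = as.integer(seed))
}

#' Simulate a host-dog population
#'
#' Draws each dog's germline haplotype i.i.d. from the configured
#' haplotype frequencies (a multinomial draw over the population); each
#' dog's mtDNA variant profile is its haplotype's reference profile.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame with columns dog, haplotype.
#' @export
simulateDogPopulation <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  f <- config@haplotypeFreqs
  data.frame(dog = sprintf("D%04d", seq_len(config@nDogs)),
             haplotype = sample(names(f), config@nDogs, replace = TRUE,
                                prob = f),
             stringsAsFactors = FALSE)
}

#' Variant table of a dog population
#'
#' @param dogs data.frame from \code{\link{simulateDogPopulation}}.
#' @param profiles a \linkS4class{HaplotypeProfileSet}.
#' @return a \linkS4class{VariantTable} (each dog carries exactly its
#'   haplotype's profile at VAF 1).
#' @export
dogVariantTable <- function(dogs, profiles) {
  stopifnot(is(profiles, "HaplotypeProfileSet"))
  rows <- lapply(seq_len(nrow(dogs)), function(i) {
    p <- profiles@profiles[[dogs$haplotype[i]]]
    if (is.null(p)) stop("no profile for haplotype ", dogs$haplotype[i])
    cbind(sample = dogs$dog[i], p, supporting_reads = 1000L,
          total_reads = 1000L, vaf = 1)
  })
  makeVariantTable(do.call(rbind, rows), profiles@genomeLength)
}

## circular membership of pos in the forward arc (from, to]
.inArc <- function(pos, from, to, L) {
  ((pos - from) %% L) <= ((to - from) %% L) & pos != from
}

#' Simulate a clonal tumour cohort with embedded horizontal transfers
#'
#' Builds a clonal nuclear tree in which each horizontal-transfer event
#' is a clade (event subtrees joined along a caterpillar backbone), and
#' a per-tumour mtDNA variant table: each member carries its event's
#' donor profile (at the configured heteroplasmic fraction, with the
#' incumbent haplotype at the complement), plus Poisson(rate x age)
#' private somatic mutations placed uniformly on the circular genome
#' outside profile sites. A recombinant event carries a donor-fixed
#' circular segment (VAF 1, containing the 16660 insertion) with mosaic
#' donor/incumbent variants elsewhere. By default the control-region
#' insertion is additionally planted as a somatic mutation on one member
#' of the first A1e event and one member of the first A1a1 event,
#' mirroring its observed recurrent somatic occurrence.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param profiles a \linkS4class{HaplotypeProfileSet}; defaults to
#'   \code{\link{syntheticProfiles}()}.
#' @param plantRecurrentInsertion plant two independent somatic copies
#'   of the 16660 insertion on non-donor backgrounds (skipped when no
#'   suitable event exists).
#' @return a \linkS4class{CtvtCohort}.
#' @export
simulateCtvtCohort <- function(config, profiles = syntheticProfiles(),
                               plantRecurrentInsertion = TRUE) {
  stopifnot(is(config, "SimulationConfig"),
            is(profiles, "HaplotypeProfileSet"))
  set.seed(config@seed)
  k <- config@nHtEvents
  L <- config@genomeLength

  donors <- config@htDonorHaplotypes
  if (!length(donors)) {
    pool <- names(config@haplotypeFreqs)
    pool <- pool[pool %in% names(profiles@profiles)]
    donors <- if (k <= length(pool)) sample(pool, k)
              else sample(pool, k, replace = TRUE)
    if (k >= 2L && donors[1L] == donors[2L]) {   # avoid sibling merge
      alt <- which(donors != donors[1L])
      if (length(alt)) {
        j <- alt[1L]
        donors[c(2L, j)] <- donors[c(j, 2L)]
      }
    }
  }
  if (!all(donors %in% names(profiles@profiles)))
    stop("donor haplotypes missing from profiles: ",
         paste(setdiff(donors, names(profiles@profiles)), collapse = ", "))

  sizes <- config@memberCounts
  if (!length(sizes)) {
    extra <- as.vector(rmultinom(1L, config@nTumours - k, rep(1 / k, k)))
    sizes <- extra + 1L
  }
  tumours <- sprintf("T%03d", seq_len(config@nTumours))
  eventOf <- rep(seq_len(k), sizes)
  membersOf <- split(tumours, eventOf)

  ## caterpillar backbone of caterpillar event clades -> every event is
  ## the complete tip set of exactly one nuclear clade
  caterpillar <- function(labs) {
    s <- paste0(labs[1L], ":1")
    for (lab in labs[-1L]) s <- sprintf("(%s,%s:1):1", s, lab)
    s
  }
  nwk <- paste0(caterpillar(vapply(membersOf, caterpillar, "")), ";")
  nwk <- sub(":1;$", ";", nwk)
  tree <- ape::read.tree(text = nwk)

  hetFrac <- config@heteroplasmyFractions
  incumbents <- config@incumbentHaplotypes
  recIdx <- config@recombinantEventIndex
  bp <- config@recombinantBreakpoints
  profilePos <- sort(unique(unlist(lapply(profiles@profiles,
                                          function(p) p$pos))))
  ref <- profiles@reference
  baseAt <- function(p) substr(ref, p, p)

  callRows <- vector("list", config@nTumours)
  somaticCount <- integer(config@nTumours)
  names(somaticCount) <- tumours
  for (j in seq_len(k)) {
    donorP <- profiles@profiles[[donors[j]]]
    h <- hetFrac[j]
    inc <- incumbents[j]
    if ((!is.na(h) || recIdx == j) && is.na(inc)) inc <- "A1e"
    recomb <- (recIdx == j)
    for (t in membersOf[[j]]) {
      ti <- match(t, tumours)
      vafDonor <- if (recomb || is.na(h)) 1 else h
      if (recomb) {
        inSeg <- .inArc(donorP$pos, bp[1L], bp[2L], L)
        dRows <- cbind(sample = t, donorP,
                       vaf = ifelse(inSeg, 1, 0.55))
        incP <- profiles@profiles[[inc]]
        iRows <- cbind(sample = t,
                       incP[!.inArc(incP$pos, bp[1L], bp[2L], L), ,
                            drop = FALSE],
                       vaf = 0.45)
        rows <- rbind(dRows, iRows)
        vafSomatic <- 0.55
      } else if (!is.na(h)) {
        incP <- profiles@profiles[[inc]]
        rows <- rbind(cbind(sample = t, donorP, vaf = h),
                      cbind(sample = t, incP, vaf = 1 - h))
        vafSomatic <- h
      } else {
        rows <- cbind(sample = t, donorP, vaf = 1)
        vafSomatic <- 1
      }
      nSom <- rpois(1L, config@mutationRate * config@eventAges[j])
      somaticCount[ti] <- nSom
      if (nSom > 0L) {
        avail <- setdiff(seq_len(L), c(profilePos, rows$pos))
        pos <- sample(avail, nSom)
        sref <- vapply(pos, baseAt, "")
        rows <- rbind(rows,
                      data.frame(sample = t, pos = pos, ref = sref,
                                 alt = unname(.transition[sref]),
                                 vaf = vafSomatic))
      }
      callRows[[ti]] <- rows
    }
  }

  insKey <- NULL
  recurrentCarriers <- character()
  if (plantRecurrentInsertion && "A1d1a" %in% names(profiles@profiles)) {
    a1 <- profiles@profiles[["A1d1a"]]
    insRow <- a1[nchar(a1$alt) > nchar(a1$ref), , drop = FALSE]
    if (nrow(insRow) == 1L) {
      insKey <- variantKey(insRow$pos, insRow$ref, insRow$alt)
      for (bg in c("A1e", "A1a1")) {
        cand <- which(donors == bg & is.na(hetFrac) &
                        seq_len(k) != recIdx)
        if (length(cand)) {
          t <- membersOf[[cand[1L]]][1L]
          ti <- match(t, tumours)
          callRows[[ti]] <- rbind(callRows[[ti]],
                                  cbind(sample = t, insRow, vaf = 1))
          recurrentCarriers <- c(recurrentCarriers, t)
        }
      }
    }
  }

  calls <- do.call(rbind, callRows)
  ## nominal read support consistent with the simulated VAFs, so the
  ## table survives TSV/VCF round trips exactly
  calls$total_reads <- 1000L
  calls$supporting_reads <- as.integer(round(calls$vaf * 1000))
  calls$vaf <- calls$supporting_reads / calls$total_reads
  vt <- makeVariantTable(calls, L)

  hetTum <- ifelse(is.na(hetFrac[eventOf]), 1, hetFrac[eventOf])
  truth <- list(
    tumours = data.frame(tumour = tumours,
                         event = paste0("HT", eventOf),
                         donor = donors[eventOf],
                         heteroplasmy_fraction = hetTum,
                         somatic_count = unname(somaticCount),
                         stringsAsFactors = FALSE),
    events = data.frame(event = paste0("HT", seq_len(k)),
                        donor = donors, age = config@eventAges,
                        n_members = as.integer(sizes),
                        heteroplasmy_fraction = ifelse(is.na(hetFrac), 1,
                                                       hetFrac),
                        incumbent = incumbents,
                        replaced = "Unknown",
                        recombinant = seq_len(k) == recIdx,
                        stringsAsFactors = FALSE),
    recombinantBreakpoints = if (recIdx > 0L) bp else numeric(),
    recurrentInsertionCarriers = recurrentCarriers,
    recurrentInsertionKey = insKey)
  new("CtvtCohort", tree = tree, variants = vt, profiles = profiles,
      truth = truth, config = config)
}

#' Per-tumour introduced haplotype and heteroplasmy
#'
#' Runs haplotype-fraction estimation and heteroplasmy calling for every
#' sample and reports the introduced (donated) haplotype: for
#' homoplasmic tumours the single carried haplotype; for heteroplasmic
#' tumours the carried haplotype that is not an incumbent tumour-lineage
#' haplotype, falling back to the minor haplotype when both carried
#' haplotypes are incumbent-lineage (a recent transfer has not yet
#' reached fixation).
#'
#' @param object a \linkS4class{VariantTable}.
#' @param profiles a \linkS4class{HaplotypeProfileSet}.
#' @param hostHaplotypes optional named vector of matched host germline
#'   haplotypes, removed before heteroplasmy calling.
#' @param incumbentLineages haplotypes of the long-established tumour
#'   lineages.
#' @param threshold heteroplasmy frequency threshold.
#' @return data.frame with sample, haplotype, heteroplasmic,
#'   introduced_fraction.
#' @export
introducedHaplotypes <- function(object, profiles, hostHaplotypes = NULL,
                                 incumbentLineages = c("A1e", "A1a1"),
                                 threshold = 0.10) {
  stopifnot(is(object, "VariantTable"))
  samples <- sampleNames(object)
  rows <- lapply(samples, function(s) {
    fr <- haplotypeFractions(object, s, profiles)
    if (!length(fr))
      return(data.frame(sample = s, haplotype = NA_character_,
                        heteroplasmic = FALSE,
                        introduced_fraction = NA_real_))
    host <- if (!is.null(hostHaplotypes)) hostHaplotypes[s]
            else NA_character_
    call <- callHeteroplasmy(fr, host, threshold, tumour = s)
    carried <- fr[fr > threshold]
    if (!call@heteroplasmic || length(carried) < 2L) {
      hap <- names(fr)[which.max(fr)]
      return(data.frame(sample = s, haplotype = hap,
                        heteroplasmic = call@heteroplasmic,
                        introduced_fraction = unname(fr[hap])))
    }
    nonInc <- carried[!names(carried) %in% incumbentLineages]
    hap <- if (length(nonInc) == 1L) names(nonInc)
           else names(carried)[which.min(carried)]
    data.frame(sample = s, haplotype = hap,
               heteroplasmic = TRUE,
               introduced_fraction = unname(carried[hap]))
  })
  do.call(rbind, rows)
}

#' Simulate read support for variant calls
#'
#' Adds binomial read support to every mtDNA call (depth Poisson around
#' the mean mtDNA coverage; success probability VAF times the mtDNA
#' tumour fraction), read-level mapping/base qualities for the
#' substitution filter, nuclear somatic VAFs concentrated at half the
#' nuclear tumour fraction, and realised coverage summaries.
#'
#' @param object a \linkS4class{VariantTable}.
#' @param meanMtDepth,meanNucDepth mean coverages (> 0).
#' @param tumourFraction nuclear tumour fraction in (0, 1].
#' @param mtTumourFraction mtDNA tumour fraction in (0, 1].
#' @param nNuclearVariants somatic nuclear variants per sample.
#' @param withPileup also emit the per-read quality pileup (switch off
#'   for very deep coverage where only VAFs and coverages are needed).
#' @param seed integer seed.
#' @return list with \code{variants} (VariantTable with read counts),
#'   \code{pileup} (long data.frame sample/variant/mq/bq),
#'   \code{nuclearVafs} (named list of per-sample VAF vectors) and
#'   \code{coverage} (data.frame sample, mt_cov, nuc_cov).
#' @export
simulateReadSupport <- function(object, meanMtDepth = 2000,
                                meanNucDepth = 100, tumourFraction = 0.8,
                                mtTumourFraction = 1.0,
                                nNuclearVariants = 500L,
                                withPileup = TRUE, seed = 1L) {
  stopifnot(is(object, "VariantTable"))
  if (meanMtDepth <= 0 || meanNucDepth <= 0)
    stop("mean depths must be > 0")
  if (tumourFraction <= 0 || tumourFraction > 1 ||
      mtTumourFraction <= 0 || mtTumourFraction > 1)
    stop("tumour fractions must lie in (0, 1]")
  set.seed(seed)
  calls <- object@calls
  n <- nrow(calls)
  depth <- pmax(1L, rpois(n, meanMtDepth))
  supp <- rbinom(n, depth, pmin(1, calls$vaf * mtTumourFraction))
  calls$supporting_reads <- supp
  calls$total_reads <- depth
  calls$vaf <- supp / depth
  pileup <- NULL
  if (withPileup) {
    key <- variantKeysOf(calls)
    pileup <- data.frame(
      sample = rep(calls$sample, supp), variant = rep(key, supp),
      mq = sample(c(60, 10), sum(supp), replace = TRUE,
                  prob = c(0.93, 0.07)),
      bq = pmin(pmax(round(rnorm(sum(supp), 35, 6)), 2), 45))
  }
  samples <- unique(calls$sample)
  nuclearVafs <- lapply(samples, function(s) {
    d <- pmax(1L, rpois(nNuclearVariants, meanNucDepth))
    rbinom(nNuclearVariants, d, tumourFraction / 2) / d
  })
  names(nuclearVafs) <- samples
  coverage <- data.frame(
    sample = samples,
    mt_cov = vapply(samples, function(s)
      mean(depth[calls$sample == s]), numeric(1L)),
    nuc_cov = meanNucDepth, row.names = NULL)
  list(variants = makeVariantTable(calls, object@genomeLength),
       pileup = pileup, nuclearVafs = nuclearVafs, coverage = coverage)
}

#' Write / read a fixture bundle
#'
#' Serialises a cohort to plain-text files: the variant table (TSV), the
#' nuclear tree (newick), per-sample single-sample VCFs, per-sample
#' mtDNA consensus FASTA (substitutions applied to the reference),
#' haplogroup profiles (TSV), ground truth (TSV) and the configuration
#' (YAML, including the seed). \code{readFixtureBundle} reproduces the
#' in-memory cohort.
#'
#' @param cohort a \linkS4class{CtvtCohort}.
#' @param dir output directory (created if needed).
#' @param writeVcf,writeFasta also emit per-sample VCF / consensus FASTA
#'   (on by default).
#' @return \code{dir}, invisibly.
#' @export
writeFixtureBundle <- function(cohort, dir, writeVcf = TRUE,
                               writeFasta = TRUE) {
  stopifnot(is(cohort, "CtvtCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop("cannot write to directory: ", dir)
  writeVariantTable(cohort@variants, file.path(dir, "variants.tsv"))
  writeNewickTree(cohort@tree, file.path(dir, "tree.newick"))
  writeHaplotypeProfiles(cohort@profiles, file.path(dir, "profiles.tsv"))
  write.table(cohort@truth$tumours, file.path(dir, "truth_tumours.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort@truth$events, file.path(dir, "truth_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort@config
  yaml::write_yaml(list(
    n_dogs = cfg@nDogs, haplotype_freqs = as.list(cfg@haplotypeFreqs),
    n_tumours = cfg@nTumours, n_ht_events = cfg@nHtEvents,
    ht_donor_haplotypes = cfg@htDonorHaplotypes,
    member_counts = cfg@memberCounts, mutation_rate = cfg@mutationRate,
    event_ages = cfg@eventAges,
    heteroplasmy_fractions = cfg@heteroplasmyFractions,
    incumbent_haplotypes = cfg@incumbentHaplotypes,
    recombinant_event_index = cfg@recombinantEventIndex,
    recombinant_breakpoints = cfg@recombinantBreakpoints,
    genome_length = cfg@genomeLength, seed = cfg@seed),
    file.path(dir, "config.yaml"))
  if (writeVcf) {
    vdir <- file.path(dir, "vcf")
    dir.create(vdir, showWarnings = FALSE)
    calls <- cohort@variants@calls
    for (s in unique(calls$sample))
      writeVariantTable(
        makeVariantTable(calls[calls$sample == s, , drop = FALSE],
                         cohort@variants@genomeLength),
        file.path(vdir, paste0(s, ".vcf")), format = "vcf")
  }
  if (writeFasta && nzchar(cohort@profiles@reference)) {
    seqs <- .consensusSequences(cohort)
    Biostrings::writeXStringSet(seqs, file.path(dir, "consensus.fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(c(MT = cohort@profiles@reference)),
      file.path(dir, "reference.fasta"))
  }
  invisible(dir)
}

## per-sample consensus: substitutions with VAF > 0.5 applied to the
## reference (indels are kept in the VCF/TSV, not the consensus)
.consensusSequences <- function(cohort) {
  refChars <- strsplit(cohort@profiles@reference, "")[[1L]]
  calls <- cohort@variants@calls
  subs <- calls[nchar(calls$ref) == 1L & nchar(calls$alt) == 1L &
                  calls$vaf > 0.5, , drop = FALSE]
  samples <- unique(calls$sample)
  seqs <- vapply(samples, function(s) {
    ch <- refChars
    rows <- subs[subs$sample == s, , drop = FALSE]
    ch[rows$pos] <- rows$alt
    paste(ch, collapse = "")
  }, "")
  Biostrings::DNAStringSet(setNames(seqs, samples))
}

#' @rdname writeFixtureBundle
#' @export
readFixtureBundle <- function(dir) {
  cfgList <- yaml::read_yaml(file.path(dir, "config.yaml"))
  freqs <- unlist(cfgList$haplotype_freqs)
  cfg <- simulationConfig(
    nDogs = cfgList$n_dogs,
    haplotypeFreqs = freqs / sum(freqs),   # YAML rounds floats
    nTumours = cfgList$n_tumours, nHtEvents = cfgList$n_ht_events,
    htDonorHaplotypes = as.character(unlist(cfgList$ht_donor_haplotypes)),
    memberCounts = as.integer(unlist(cfgList$member_counts)),
    mutationRate = cfgList$mutation_rate,
    eventAges = as.numeric(unlist(cfgList$event_ages)),
    heteroplasmyFractions =
      as.numeric(unlist(cfgList$heteroplasmy_fractions)),
    incumbentHaplotypes =
      as.character(unlist(cfgList$incumbent_haplotypes)),
    recombinantEventIndex = cfgList$recombinant_event_index,
    recombinantBreakpoints =
      as.numeric(unlist(cfgList$recombinant_breakpoints)),
    genomeLength = cfgList$genome_length, seed = cfgList$seed)
  refPath <- file.path(dir, "reference.fasta")
  reference <- if (file.exists(refPath))
    as.character(Biostrings::readDNAStringSet(refPath)[[1L]]) else ""
  profiles <- readHaplotypeProfiles(file.path(dir, "profiles.tsv"),
                                    reference = reference,
                                    genomeLength = cfgList$genome_length)
  truth <- list(
    tumours = read.table(file.path(dir, "truth_tumours.tsv"),
                         header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE),
    events = read.table(file.path(dir, "truth_events.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE))
  new("CtvtCohort",
      tree = readNewickTree(file.path(dir, "tree.newick")),
      variants = readVariantTable(file.path(dir, "variants.tsv"),
                                  genomeLength = cfgList$genome_length),
      profiles = profiles, truth = truth, config = cfg)
}
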