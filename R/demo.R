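## End-to-end demo scenarios chaining simulate -> count -> normalize ->
## score -> qc, mirroring the platform's three validation experiments: a
## focused 20-line NSCLC panel with an EGFR inhibitor and EGFR knockout, a
## full 368-line panel with a KRAS G12C inhibitor and KRAS knockout, and the
## 20-barcode 5-tier dilution series.

DEMO_DOSES <- c(0, 0.1, 0.3, 1, 3, 10)     # uM, 6-dose scheme
DEMO_SCENARIOS <- c("focused_egfr", "full_kras", "dilution")

.makeIndexPairs <- function(n, seed) {
  stopifnot(n <= 96L)
  .withSeed(seed, {
    rnd8 <- function(k) {
      vapply(seq_len(k), function(i)
        paste(sample(DNA_BASES, 8L, replace = TRUE), collapse = ""),
        character(1))
    }
    i5 <- rnd8(8L)
    i7 <- rnd8(12L)
    grid <- expand.grid(i5 = i5, i7 = i7, stringsAsFactors = FALSE)
    grid[seq_len(n), ]
  })
}

.demoSheet <- function(compoundAgent, sgrnas, seed,
                       compoundDay = 5, crisprDay = 10, nRep = 3L) {
  rows <- list()
  for (rep in seq_len(nRep)) {
    for (d in DEMO_DOSES) {
      rows[[length(rows) + 1L]] <- data.frame(
        arm_type = "compound",
        agent = if (d == 0) "DMSO" else compoundAgent,
        dose = d, timepoint = compoundDay, replicate = rep,
        is_control = d == 0)
    }
    for (sg in c("sgNT", sgrnas)) {
      rows[[length(rows) + 1L]] <- data.frame(
        arm_type = "crispr", agent = sg, dose = 0,
        timepoint = crisprDay, replicate = rep,
        is_control = sg == "sgNT")
    }
  }
  df <- do.call(rbind, rows)
  df <- cbind(sample_id = sprintf("S%03d", seq_len(nrow(df))), df)
  idx <- .makeIndexPairs(nrow(df), .childSeed(seed, 7L))
  df$i5_index <- idx$i5
  df$i7_index <- idx$i7
  SampleSheet(df)
}

## Panel parameter conventions for the demo worlds (documented in the
## methods vignette): doubling rates 0.5-1.0 dbl/day; sensitive lines get a
## sub-dose-range EC50 and a deep curve, insensitive lines an EC50 far above
## 10 uM; editing fraction 0.9 everywhere; knockout costs planted per
## genotype.
.demoPanelDF <- function(lib, flags, sensitive, ec50Sens, spikeinErlotinib,
                         koCost, seed) {
  lines <- cellLineIds(lib)
  spk <- isSpikein(lib)
  n <- length(lines)
  .withSeed(seed, {
    g <- stats::runif(n, 0.5, 1.0)
    eff <- stats::runif(n, 0.86, 0.99)
    df <- data.frame(
      cell_line_id = lines,
      lineage = ifelse(spk, "embryonic_kidney", "lung"),
      genotype_flags = flags,
      cas9_efficiency = ifelse(spk, NA_real_, eff),
      is_spikein = spk,
      doubling_rate = ifelse(spk, 0.9, g),
      ec50 = ifelse(sensitive, ec50Sens, 1000),
      hill = ifelse(sensitive, 1.5, 1.0),
      residual = ifelse(sensitive, 0.05, 0.0),
      ko_cost = koCost,
      edit_frac = ifelse(spk, 0, 0.9))
    if (spikeinErlotinib) {
      ## 293T spike-in hit by the compound at the top doses
      df$ec50[spk] <- 4
      df$hill[spk] <- 2
      df$residual[spk] <- 0.1
    }
    df
  })
}

.ctgForSpikeins <- function(panel, agent) {
  pan <- as.data.frame(panel)
  spk <- pan[pan$is_spikein, ]
  rows <- do.call(rbind, lapply(seq_len(nrow(spk)), function(i) {
    data.frame(line_id = spk$cell_line_id[i], agent = agent,
               dose = DEMO_DOSES,
               fitness = ifelse(DEMO_DOSES == 0, 1,
                                doseViability(DEMO_DOSES, spk$ec50[i],
                                              spk$hill[i], spk$residual[i])))
  }))
  CTGFitness(rows)
}

#' Build the inputs of a demo scenario
#'
#' \describe{
#' \item{focused_egfr}{20-line NSCLC panel plus 2 spike-ins; 3 lines planted
#'   EGFR-exon19del-like (sensitive to the compound and to EGFR knockout);
#'   the spike-in is drug-killed at the top doses, exercising the CTG
#'   adjustment.}
#' \item{full_kras}{368-line panel (17 KRAS G12C / 61 other KRAS mutant /
#'   290 wild-type) plus 2 spike-ins; compound sensitivity planted only in
#'   the G12C group, knockout cost planted in both mutant groups.}
#' \item{dilution}{the 20-barcode, 5-tier (100/10/1/0.1/0.01) plasmid pool.}
#' }
#'
#' @param scenario one of \code{"focused_egfr"}, \code{"full_kras"},
#'   \code{"dilution"}.
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return list with \code{library}, and per scenario: \code{panel},
#'   \code{sheet}, \code{ctg}, \code{compoundAgent}, \code{gene},
#'   \code{sgrnas}, or \code{designed} for the dilution pool.
#' @export
demoPanel <- function(scenario = DEMO_SCENARIOS, seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario == "dilution") {
    lib <- designLibrary(20L, 0L, seed = .childSeed(seed, 1L))
    return(list(scenario = scenario, library = lib,
                designed = makeDilutionPool(lib)))
  }
  if (scenario == "focused_egfr") {
    lib <- designLibrary(20L, 2L, seed = .childSeed(seed, 1L))
    spk <- isSpikein(lib)
    sensitive <- c(rep(TRUE, 3L), rep(FALSE, 17L), rep(FALSE, 2L))
    flags <- ifelse(spk, "spikein",
                    ifelse(sensitive, "EGFR_ex19del", "EGFR_WT"))
    panel <- PanelAnnotation(.demoPanelDF(
      lib, flags, sensitive, ec50Sens = 0.05, spikeinErlotinib = TRUE,
      koCost = ifelse(sensitive, 0.6, ifelse(spk, 0, 0.05)),
      seed = .childSeed(seed, 2L)))
    sheet <- .demoSheet("Erlotinib", c("sgNC", "sgEGFR1", "sgEGFR2"),
                        seed = seed)
    list(scenario = scenario, library = lib, panel = panel, sheet = sheet,
         ctg = .ctgForSpikeins(panel, "Erlotinib"),
         compoundAgent = "Erlotinib", gene = "EGFR",
         sgrnas = c("sgEGFR1", "sgEGFR2"))
  } else {
    nG12C <- 17L; nOther <- 61L; nWT <- 290L
    lib <- designLibrary(nG12C + nOther + nWT, 2L,
                         seed = .childSeed(seed, 1L))
    spk <- isSpikein(lib)
    flags <- c(rep("KRAS_G12C", nG12C), rep("KRAS_other", nOther),
               rep("KRAS_WT", nWT), rep("spikein", 2L))
    sensitive <- flags == "KRAS_G12C"
    mutant <- flags %in% c("KRAS_G12C", "KRAS_other")
    panel <- PanelAnnotation(.demoPanelDF(
      lib, flags, sensitive, ec50Sens = 0.1, spikeinErlotinib = FALSE,
      koCost = ifelse(spk, 0, ifelse(mutant, 0.5, 0.02)),
      seed = .childSeed(seed, 2L)))
    sheet <- .demoSheet("AMG-510", c("sgNC", "sgKRAS1", "sgKRAS2"),
                        seed = seed)
    list(scenario = scenario, library = lib, panel = panel, sheet = sheet,
         ctg = .ctgForSpikeins(panel, "AMG-510"),
         compoundAgent = "AMG-510", gene = "KRAS",
         sgrnas = c("sgKRAS1", "sgKRAS2"))
  }
}

#' Run a packaged demo scenario end to end
#'
#' Simulates every sample of the scenario's sheet (pool growth with Poisson
#' end-point noise, then reads), counts barcodes, normalizes (fractions,
#' spike-in/CTG adjustment, control anchoring), scores the compound and
#' CRISPR arms, and runs QC.  All outputs are written as TSV under
#' \code{outdir}; runs are byte-identical given the same seed.
#'
#' @param scenario demo scenario name.
#' @param outdir output directory (created).
#' @param seed integer master seed.
#' @param depth reads per sample (dilution: total reads); defaults 2e5 for
#'   focused_egfr, 1e5 for full_kras, 1e6 for dilution.
#' @param perBaseError substitution error rate.
#' @param cellsPerLine pool seeding density (cells per line).
#' @return (invisibly) a result bundle: inputs plus \code{counts} (a
#'   \linkS4class{BarcodeCounts}), \code{auc}, \code{dependency},
#'   \code{groupStats}, \code{concordance}, \code{cas9}, or
#'   \code{linearity} for the dilution scenario.
#' @export
runDemo <- function(scenario = DEMO_SCENARIOS, outdir = tempfile("demo"),
                    seed = 1L, depth = NULL, perBaseError = 0.001,
                    cellsPerLine = 1000) {
  scenario <- match.arg(scenario)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  world <- demoPanel(scenario, seed)
  lib <- world$library
  writeBarcodeLibrary(lib, file.path(outdir, "library.tsv"))
  if (scenario == "dilution") {
    if (is.null(depth)) depth <- 1e6
    cells <- stats::setNames(world$designed$designed_fraction * 1e6,
                             cellLineIds(lib))
    pool <- PoolState(cells, day = 0)
    fq <- file.path(outdir, "dilution.fastq.gz")
    simulateReads(pool, lib, depth = depth, path = fq,
                  perBaseError = perBaseError, seed = .childSeed(seed, 11L))
    counts <- countFastq(c(dilution = fq), lib)
    lin <- linearityCheck(world$designed, counts)
    writeBarcodeCounts(counts, file.path(outdir, "counts.tsv"))
    .writeTableAtomic(as.data.frame(lin@table),
                      file.path(outdir, "linearity.tsv"),
                      "linearity_report")
    bundle <- list(scenario = scenario, outdir = outdir, seed = seed,
                   library = lib, designed = world$designed,
                   counts = counts, linearity = lin)
    writeReport(bundle, file.path(outdir, "report.md"))
    return(invisible(bundle))
  }
  if (is.null(depth)) {
    depth <- if (scenario == "focused_egfr") 2e5 else 1e5
  }
  sheet <- world$sheet
  panel <- world$panel
  issues <- validateSampleSheet(sheet)
  if (length(issues) > 0L) stop("invalid demo sheet: ", issues[1L])
  writePanelAnnotation(panel, file.path(outdir, "panel.tsv"))
  writeSampleSheet(sheet, file.path(outdir, "samplesheet.tsv"))
  writeCTGFitness(world$ctg, file.path(outdir, "ctg.tsv"))
  sh <- as.data.frame(sheet)
  fqDir <- file.path(outdir, "fastq")
  fq <- character(nrow(sh))
  pool0 <- seedPool(panel, cellsPerLine)
  for (i in seq_len(nrow(sh))) {
    pool <- simulatePoolGrowth(
      panel, pool0, armType = sh$arm_type[i], agent = sh$agent[i],
      dose = sh$dose[i], t = sh$timepoint[i],
      seed = .childSeed(seed, 100L + i))
    fq[i] <- file.path(fqDir, paste0(sh$sample_id[i], ".fastq.gz"))
    simulateReads(pool, lib, depth = depth, path = fq[i],
                  perBaseError = perBaseError,
                  seed = .childSeed(seed, 500L + i))
  }
  names(fq) <- sh$sample_id
  counts <- countFastq(fq, lib, sampleSheet = sheet)
  counts <- barcodeFractions(counts)
  counts <- spikeinAdjust(counts, world$ctg)
  counts <- controlNormalize(counts)
  writeBarcodeCounts(counts, file.path(outdir, "counts.tsv"))
  writeAbundance(counts, file.path(outdir, "abundance.tsv"))
  auc <- scoreCompound(counts, world$compoundAgent)
  dep <- scoreCrispr(counts, world$gene, world$sgrnas)
  .writeTableAtomic(as.data.frame(auc), file.path(outdir, "auc.tsv"),
                    "compound_auc")
  .writeTableAtomic(as.data.frame(dep), file.path(outdir, "dependency.tsv"),
                    "crispr_dependency")
  pan <- as.data.frame(panel)
  grp <- pan$genotype_flags[match(auc$cell_line_id, pan$cell_line_id)]
  keep <- grp != "spikein"
  groupStats <- list(
    auc = groupCompare(auc$auc[keep], grp[keep]),
    dependency = groupCompare(dep$score[keep], grp[keep]))
  concord <- replicateConcordance(counts)
  .writeTableAtomic(as.data.frame(concord),
                    file.path(outdir, "concordance.tsv"),
                    "replicate_concordance")
  cas9 <- cas9QCFilter(panel)
  bundle <- list(scenario = scenario, outdir = outdir, seed = seed,
                 library = lib, panel = panel, sheet = sheet,
                 ctg = world$ctg, counts = counts, auc = auc,
                 dependency = dep, groupStats = groupStats,
                 concordance = concord, cas9 = cas9)
  writeReport(bundle, file.path(outdir, "report.md"))
  invisible(bundle)
}

.fmtGroupStats <- function(gs, label) {
  tab <- gs$groups
  c(sprintf("### %s by genotype (%s)", label, gs$method),
    sprintf("- %s: mean %.4f +/- %.4f SEM (n=%d)",
            tab$group, tab$mean, tab$sem, tab$n),
    sprintf("- p = %.3g%s", gs$p.value,
            if (gs$zero_variance) " (zero-variance groups)" else ""))
}

#' Write a markdown summary of a demo bundle
#'
#' Tables of top depleted lines, per-group mean +/- SEM, replicate
#' concordance and QC flags; components missing from the bundle are listed
#' as absent rather than failing.
#'
#' @param bundle result of [runDemo()].
#' @param path output markdown file.
#' @export
writeReport <- function(bundle, path) {
  ln <- c(sprintf("# Screen summary: %s (seed %s)", bundle$scenario,
                  bundle$seed), "")
  if (!is.null(bundle$linearity)) {
    lin <- bundle$linearity
    ln <- c(ln, "## Dilution-series linearity",
            sprintf("- detected: %d / %d barcodes (>= %d reads)",
                    sum(lin@table$detected), nrow(lin@table),
                    lin@detectMinReads),
            sprintf("- log-log slope %.4f, Pearson r %.4f", lin@slope, lin@r),
            sprintf("- dynamic_range_detected: %.4g-fold", lin@dynamicRange),
            "")
  } else {
    ln <- c(ln, "## Dilution-series linearity", "- absent", "")
  }
  if (!is.null(bundle$auc)) {
    a <- bundle$auc[order(bundle$auc$auc), ]
    top <- utils::head(a, 5L)
    ln <- c(ln, "## Compound arm: most sensitive lines (lowest AUC)",
            sprintf("- %s: AUC %.4f", top$cell_line_id, top$auc), "")
  } else {
    ln <- c(ln, "## Compound arm", "- absent", "")
  }
  if (!is.null(bundle$dependency)) {
    d <- bundle$dependency[order(bundle$dependency$score), ]
    top <- utils::head(d, 5L)
    ln <- c(ln, "## CRISPR arm: most depleted lines (lowest score)",
            sprintf("- %s: score %.4f%s", top$cell_line_id, top$score,
                    ifelse(top$dna_damage_flag, " [DNA-damage flag]", "")),
            "")
  } else {
    ln <- c(ln, "## CRISPR arm", "- absent", "")
  }
  if (!is.null(bundle$groupStats)) {
    ln <- c(ln, .fmtGroupStats(bundle$groupStats$auc, "Compound AUC"), "",
            .fmtGroupStats(bundle$groupStats$dependency, "Dependency score"),
            "")
  }
  if (!is.null(bundle$concordance)) {
    cc <- bundle$concordance
    ln <- c(ln, "## Replicate concordance",
            sprintf("- min pairwise r across strata: %.4f", min(cc$min_r)),
            sprintf("- median of stratum median r: %.4f",
                    stats::median(cc$median_r)), "")
  }
  if (!is.null(bundle$cas9)) {
    ln <- c(ln, "## Cas9 QC gate (> 85% editing)",
            sprintf("- passing: %d, failing: %d",
                    length(bundle$cas9$passing), length(bundle$cas9$failing)),
            "")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(ln, path)
  invisible(path)
}
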