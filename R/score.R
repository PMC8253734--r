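## Per-line drug-sensitivity AUC, CRISPR dependency scores, competition-assay
## arithmetic, group statistics and correlations.

#' Normalized dose-response AUC
#'
#' The central scoring convention: the dose-0 point is the normalization
#' anchor and is excluded; relative viabilities are clipped to \code{[0,1]}
#' (over-proliferation under drug capped so the index stays comparable);
#' the trapezoidal integral is taken over \code{x = log10(dose)} and divided
#' by \code{x_max - x_min}.  An insensitive line (rv = 1 everywhere) scores
#' 1; a fully killed line scores 0.  The same rule applies to 10-point
#' individual-assay data and 6-dose pooled-screen data so AUCs are
#' comparable.
#'
#' @param doses dose vector in uM; a leading 0 (DMSO anchor) is allowed and
#'   dropped.
#' @param rv matching relative viabilities (>= 0).
#' @return AUC in \code{[0, 1]}.
#' @examples
#' aucDoseResponse(c(0.1, 0.3, 1, 3, 10), c(1, 1, 0.5, 0, 0))
#' @export
aucDoseResponse <- function(doses, rv) {
  stopifnot(length(doses) == length(rv), all(doses >= 0), all(rv >= 0))
  keep <- doses > 0
  doses <- doses[keep]
  rv <- rv[keep]
  if (length(doses) < 2L) {
    stop("need at least 2 nonzero doses for AUC, got ", length(doses))
  }
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly increasing")
  }
  rv <- pmin(pmax(rv, 0), 1)
  x <- log10(doses)
  area <- sum(diff(x) * (utils::head(rv, -1) + utils::tail(rv, -1)) / 2)
  area / (x[length(x)] - x[1L])
}

#' Per-line compound AUC from a normalized screen
#'
#' Averages the relative-viability assay over replicates at each dose of the
#' given compound arm and integrates with [aucDoseResponse()].  Lines are
#' reported by \code{cell_line_id}; per-line low-count flags are carried
#' along (any flagged entry among the samples used).
#'
#' @param counts a \linkS4class{BarcodeCounts} with assay \code{rv}.
#' @param agent compound name to score.
#' @param timepoint restrict to one timepoint (default: all rows of the arm).
#' @return DataFrame: cell_line_id, auc, n_doses_used, low_count.
#' @export
scoreCompound <- function(counts, agent, timepoint = NULL) {
  cd <- SummarizedExperiment::colData(counts)
  RV <- SummarizedExperiment::assay(counts, "rv")
  sel <- cd$arm_type == "compound" & cd$agent == agent & !cd$is_control &
    cd$dose > 0
  if (!is.null(timepoint)) sel <- sel & cd$timepoint == timepoint
  if (!any(sel)) stop("no treated compound samples for agent '", agent, "'")
  doses <- sort(unique(cd$dose[sel]))
  rvMean <- vapply(doses, function(d) {
    rowMeans(RV[, sel & cd$dose == d, drop = FALSE])
  }, numeric(nrow(counts)))
  auc <- apply(rvMean, 1L, function(rv) aucDoseResponse(doses, rv))
  lc <- SummarizedExperiment::assay(counts, "low_count")
  S4Vectors::DataFrame(
    cell_line_id = SummarizedExperiment::rowData(counts)$cell_line_id,
    auc = auc,
    n_doses_used = length(doses),
    low_count = apply(lc[, sel, drop = FALSE], 1L, any),
    row.names = rownames(counts))
}

#' sgRNA-averaged dependency score
#'
#' Per targeting sgRNA the log2 relative viability is taken; the score is
#' their unweighted mean.  The sgNC log2 RV (the DNA-damage-response
#' control: a guide cutting a non-expressed intron) is recorded, and a
#' warning flag is set when it drops below -1, marking a line whose apparent
#' dependency may reflect DNA-damage sensitivity rather than target loss.
#'
#' @param rvBySgrna named numeric: relative viability per targeting sgRNA.
#' @param sgncRV relative viability under sgNC (NA if not measured).
#' @return list: \code{score}, \code{per_sgrna_lfc}, \code{sgnc_lfc},
#'   \code{dna_damage_flag}.
#' @export
dependencyScore <- function(rvBySgrna, sgncRV = NA_real_) {
  if (length(rvBySgrna) < 1L) stop("need at least one targeting sgRNA")
  if (any(rvBySgrna <= 0) || (!is.na(sgncRV) && sgncRV <= 0)) {
    stop("relative viability must be > 0 (use a pseudocount upstream)")
  }
  lfc <- log2(rvBySgrna)
  sgnc <- if (is.na(sgncRV)) NA_real_ else log2(sgncRV)
  list(score = mean(lfc), per_sgrna_lfc = lfc, sgnc_lfc = sgnc,
       dna_damage_flag = !is.na(sgnc) && sgnc < -1)
}

#' Per-line CRISPR dependency from a normalized screen
#'
#' @param counts a \linkS4class{BarcodeCounts} with assay \code{rv}.
#' @param gene gene symbol (reported, not used for matching).
#' @param sgrnas targeting sgRNA agent names (e.g. two guides per gene).
#' @param nc sgNC agent name (DNA-damage control), or NULL.
#' @param timepoint day to score; default the latest timepoint common to all
#'   requested sgRNA arms.
#' @return DataFrame: cell_line_id, gene, per-sgRNA lfc columns, score,
#'   sgnc_lfc, dna_damage_flag.
#' @export
scoreCrispr <- function(counts, gene, sgrnas, nc = "sgNC", timepoint = NULL) {
  cd <- SummarizedExperiment::colData(counts)
  RV <- SummarizedExperiment::assay(counts, "rv")
  if (is.null(timepoint)) {
    tps <- lapply(sgrnas, function(a) unique(cd$timepoint[cd$agent == a]))
    common <- Reduce(intersect, tps)
    if (length(common) == 0L) stop("no common timepoint across sgRNAs")
    timepoint <- max(common)
  }
  rvFor <- function(agent) {
    sel <- cd$arm_type == "crispr" & cd$agent == agent &
      cd$timepoint == timepoint
    if (!any(sel)) return(NULL)
    rowMeans(RV[, sel, drop = FALSE])
  }
  rvT <- lapply(sgrnas, rvFor)
  if (any(vapply(rvT, is.null, logical(1)))) {
    stop("no samples at day ", timepoint, " for sgRNA(s): ",
         paste(sgrnas[vapply(rvT, is.null, logical(1))], collapse = ", "))
  }
  rvNC <- if (!is.null(nc)) rvFor(nc) else NULL
  lfc <- vapply(rvT, log2, numeric(nrow(counts)))
  colnames(lfc) <- paste0("lfc_", sgrnas)
  score <- rowMeans(lfc)
  sgnc <- if (is.null(rvNC)) rep(NA_real_, nrow(counts)) else log2(rvNC)
  out <- S4Vectors::DataFrame(
    cell_line_id = SummarizedExperiment::rowData(counts)$cell_line_id,
    gene = gene, lfc, score = score, sgnc_lfc = sgnc,
    dna_damage_flag = !is.na(sgnc) & sgnc < -1,
    timepoint = timepoint,
    row.names = rownames(counts))
  out
}

#' Competition-assay normalized ratio
#'
#' \code{(RFP_targeting / GFP_NT) / (RFP_sgNT / GFP_sgNT)}: the RFP/GFP
#' ratio of the targeting-sgRNA co-culture normalized by the sgNT
#' co-culture, typically read on day 10.  1 means no essentiality; values
#' below 1 mean depletion upon knockout.
#'
#' @param rfpTargeting,gfpNt RFP and GFP measurements of the targeting mix.
#' @param rfpSgNt,gfpSgNt RFP and GFP measurements of the sgNT control mix.
#' @return normalized ratio (> 0).
#' @export
competitionRatio <- function(rfpTargeting, gfpNt, rfpSgNt, gfpSgNt) {
  vals <- c(rfpTargeting, gfpNt, rfpSgNt, gfpSgNt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all four fluorescence quantities must be positive")
  }
  (rfpTargeting / gfpNt) / (rfpSgNt / gfpSgNt)
}

#' Compare per-line scores between genotype groups
#'
#' Two groups are compared by an unpaired two-tailed Student's t test; three
#' or more by one-way ANOVA.  Per-group mean, SEM (= sd / sqrt(n)) and n are
#' reported.  Degenerate all-constant groups are handled explicitly: equal
#' means give p = 1, separated means give p = 0 with the zero-variance flag
#' set.
#'
#' @param scores numeric per-line values (e.g. AUC or dependency score).
#' @param groups factor/character partition, same length.
#' @return list: \code{groups} (data.frame group/n/mean/sem), \code{p.value},
#'   \code{method}, \code{zero_variance}.
#' @export
groupCompare <- function(scores, groups) {
  groups <- as.factor(groups)
  keep <- is.finite(scores) & !is.na(groups)
  scores <- scores[keep]
  groups <- droplevels(groups[keep])
  ng <- nlevels(groups)
  if (ng < 2L) stop("need at least 2 groups")
  n <- tapply(scores, groups, length)
  if (any(n < 2L)) {
    stop("group(s) with fewer than 2 members: ",
         paste(levels(groups)[n < 2L], collapse = ", "))
  }
  gm <- tapply(scores, groups, mean)
  gsd <- tapply(scores, groups, stats::sd)
  tab <- data.frame(group = levels(groups), n = as.integer(n),
                    mean = as.numeric(gm),
                    sem = as.numeric(gsd / sqrt(n)))
  zeroVar <- all(gsd == 0)
  if (zeroVar) {
    p <- if (length(unique(gm)) == 1L) 1 else 0
    method <- if (ng == 2L) "Welch two-sample t test" else "one-way ANOVA"
    return(list(groups = tab, p.value = p, method = method,
                zero_variance = TRUE))
  }
  if (ng == 2L) {
    ht <- stats::t.test(scores ~ groups)
    list(groups = tab, p.value = ht$p.value, method = "Welch two-sample t test",
         zero_variance = FALSE)
  } else {
    fit <- stats::aov(scores ~ groups)
    p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    list(groups = tab, p.value = p, method = "one-way ANOVA",
         zero_variance = FALSE)
  }
}

#' Simple linear regression with Pearson correlation
#'
#' Ordinary least squares slope and intercept plus the product-moment
#' Pearson r, the convention used for cross-platform concordance analyses.
#'
#' @param x,y numeric vectors, \code{length >= 3}; \code{x} must vary.
#' @return list: \code{r}, \code{slope}, \code{intercept}, \code{n}.
#' @export
pearsonFit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 finite (x, y) pairs")
  if (stats::sd(x) == 0) stop("x is constant; regression undefined")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  list(r = r, slope = slope, intercept = intercept, n = length(x))
}
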