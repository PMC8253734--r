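## Quality control: Cas9 efficiency gating, dilution-series linearity,
## replicate concordance.

#' Gate cell lines on Cas9 editing efficiency
#'
#' Only lines whose editing efficiency strictly exceeds the threshold pass
#' (the archival rule is ">85%", so 0.85 itself fails).  Idempotent:
#' filtering the passing set again returns it unchanged.
#'
#' @param efficiencies named numeric in \code{[0,1]} per line, or a
#'   \linkS4class{PanelAnnotation} (spike-in lines, being Cas9-dead, are
#'   excluded from gating).
#' @param threshold efficiency floor (default 0.85).
#' @return list with character vectors \code{passing} and \code{failing}.
#' @export
cas9QCFilter <- function(efficiencies, threshold = 0.85) {
  if (is(efficiencies, "PanelAnnotation")) {
    keep <- !efficiencies$is_spikein
    efficiencies <- stats::setNames(efficiencies$cas9_efficiency[keep],
                                    efficiencies$cell_line_id[keep])
  }
  if (length(efficiencies) == 0L) {
    return(list(passing = character(0), failing = character(0)))
  }
  if (any(is.na(efficiencies)) ||
      any(efficiencies < 0 | efficiencies > 1)) {
    stop("efficiencies must lie in [0, 1]")
  }
  pass <- efficiencies > threshold
  list(passing = names(efficiencies)[pass],
       failing = names(efficiencies)[!pass])
}

#' Dilution-series linearity check
#'
#' Compares designed against estimated barcode fractions from the 5-tier
#' dilution pool.  A barcode is detected iff its raw count reaches
#' \code{detectMinReads} (a count floor, not a fraction: detection limits
#' are Poisson-governed).  Slope and Pearson r are computed on
#' log10-log10 pairs of detected barcodes via [pearsonFit()]; the detected
#' dynamic range is the ratio of the largest to the smallest designed
#' fraction among detected barcodes.
#'
#' @param designed named numeric designed fractions (or the data.frame from
#'   [makeDilutionPool()]).
#' @param counts named numeric raw counts over the same barcodes (or a
#'   one-sample \linkS4class{BarcodeCounts}).
#' @param detectMinReads detection floor in reads (default 10).
#' @return a \linkS4class{LinearityReport}.
#' @export
linearityCheck <- function(designed, counts, detectMinReads = 10L) {
  if (is.data.frame(designed)) {
    designed <- stats::setNames(designed$designed_fraction,
                                designed$barcode_id)
  }
  if (is(counts, "BarcodeCounts")) {
    stopifnot(ncol(counts) == 1L)
    counts <- SummarizedExperiment::assay(counts, "counts")[, 1L]
  }
  stopifnot(detectMinReads >= 1L)
  ids <- names(designed)
  if (!setequal(ids, names(counts))) {
    stop("designed and counted barcode sets differ")
  }
  counts <- counts[ids]
  est <- counts / sum(counts)
  detected <- counts >= detectMinReads
  if (sum(detected) < 3L) {
    stop("only ", sum(detected), " barcode(s) detected; need >= 3 for a fit")
  }
  fit <- pearsonFit(log10(designed[detected]), log10(est[detected]))
  new("LinearityReport",
      table = S4Vectors::DataFrame(
        barcode_id = ids,
        designed_fraction = unname(designed),
        estimated_fraction = unname(est),
        count = unname(counts),
        detected = unname(detected)),
      slope = fit$slope, r = fit$r,
      dynamicRange = max(designed[detected]) / min(designed[detected]),
      detectMinReads = as.integer(detectMinReads))
}

#' Replicate concordance per treatment stratum
#'
#' Within each (arm_type, agent, dose, timepoint) stratum with >= 2
#' replicates, computes all pairwise Pearson correlations of log10 adjusted
#' abundances across lines and summarizes the minimum and median r.
#' Strata with fewer than 2 replicates are skipped with a message.
#'
#' @param counts a \linkS4class{BarcodeCounts} with assay \code{abundance}
#'   (falls back to \code{fraction}).
#' @return DataFrame: arm_type, agent, dose, timepoint, n_replicates,
#'   min_r, median_r.
#' @export
replicateConcordance <- function(counts) {
  anames <- SummarizedExperiment::assayNames(counts)
  A <- SummarizedExperiment::assay(
    counts, if ("abundance" %in% anames) "abundance" else "fraction")
  cd <- SummarizedExperiment::colData(counts)
  key <- paste(cd$arm_type, cd$agent, cd$dose, cd$timepoint, sep = "|")
  out <- list()
  for (k in unique(key)) {
    sel <- which(key == k)
    if (length(sel) < 2L) {
      .msg("stratum %s: fewer than 2 replicates, skipped", k)
      next
    }
    lg <- log10(A[, sel, drop = FALSE])
    rs <- stats::cor(lg)[upper.tri(diag(length(sel)))]
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    out[[k]] <- S4Vectors::DataFrame(
      arm_type = parts[1L], agent = parts[2L],
      dose = as.numeric(parts[3L]), timepoint = as.numeric(parts[4L]),
      n_replicates = length(sel),
      min_r = min(rs), median_r = stats::median(rs))
  }
  if (length(out) == 0L) stop("no stratum with >= 2 replicates")
  do.call(rbind, unname(out))
}
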