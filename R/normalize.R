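## Spike-in-referenced and control-anchored normalization.
##
## Raw counts -> assigned-read fractions -> abundances relative to a
## viability-corrected spike-in reference -> relative viabilities against the
## matched control stratum (DMSO for compound arms, sgNT for CRISPR arms,
## collected at every timepoint).

#' Assigned-read fractions per sample
#'
#' \code{f[i,s] = (c[i,s] + pc) / sum_j (c[j,s] + pc)} over assigned,
#' non-ambiguous counts.  The symmetric pseudocount (default 0.5) keeps
#' downstream log-ratios finite for fully depleted lines.  Also sets the
#' per-(barcode, sample) low-count flag (\code{count < lowCountMin}).
#'
#' @param counts a \linkS4class{BarcodeCounts}.
#' @param pseudocount added to every count before normalizing.
#' @param lowCountMin raw-count floor below which an entry is flagged.
#' @return the object with assays \code{fraction} and \code{low_count} added.
#' @export
barcodeFractions <- function(counts, pseudocount = 0.5, lowCountMin = 10L) {
  cnt <- SummarizedExperiment::assay(counts, "counts")
  zero <- colSums(cnt) == 0
  if (any(zero)) {
    stop("sample(s) with zero assigned reads: ",
         paste(colnames(cnt)[zero], collapse = ", "))
  }
  f <- sweep(cnt + pseudocount, 2L, colSums(cnt + pseudocount), "/")
  SummarizedExperiment::assay(counts, "fraction") <- f
  SummarizedExperiment::assay(counts, "low_count") <- cnt < lowCountMin
  counts
}

## CTG fitness lookup for one line under one condition; control conditions
## (is_control or dose 0) have fitness 1 by definition.
.ctgLookup <- function(ctg, line, agent, dose, isControl) {
  if (isControl || dose == 0) return(1)
  if (is.null(ctg)) return(NA_real_)
  tab <- as.data.frame(ctg)
  hit <- tab$line_id == line & tab$agent == agent & tab$dose == dose
  if (!any(hit)) return(NA_real_)
  tab$fitness[which(hit)[1L]]
}

#' Spike-in-referenced abundance
#'
#' For each sample the reference is the mean over spike-in lines of
#' \code{f[spike, s] / v[spike, condition(s)]}, where \code{v} is the
#' spike-in's 5-day CTG fitness under the same \code{(agent, dose)}
#' condition; adjusted abundance is \code{A[i,s] = f[i,s] / r[s]}.  Dividing
#' the spike-in fraction by its fitness restores the reference a drug-
#' sensitive spike-in would have shown untreated, so a line untouched by the
#' treatment keeps \code{A} (and downstream relative viability) at 1 even
#' when the spike-in itself is partially killed.  Missing fitness values
#' default to 1 with a warning.  If \code{colData} has a \code{spikein_set}
#' column (";"-separated cell_line_ids), the reference for that sample uses
#' only the named spike-in lines (e.g. CRBN-knockout 293T for a CRBN-
#' modulator arm).
#'
#' @param counts a \linkS4class{BarcodeCounts} with assay \code{fraction} and
#'   \code{agent}/\code{dose}/\code{is_control} in \code{colData}.
#' @param ctg a \linkS4class{CTGFitness} table, or NULL (all fitness 1, with
#'   a warning for treated samples).
#' @return the object with assay \code{abundance} added; per-sample
#'   references are logged.
#' @export
spikeinAdjust <- function(counts, ctg = NULL) {
  f <- SummarizedExperiment::assay(counts, "fraction")
  rd <- SummarizedExperiment::rowData(counts)
  cd <- SummarizedExperiment::colData(counts)
  if (!"is_spikein" %in% colnames(rd)) {
    stop("rowData lacks is_spikein; build counts with the barcode library")
  }
  need <- c("agent", "dose", "is_control")
  if (!all(need %in% colnames(cd))) {
    stop("colData lacks ", paste(setdiff(need, colnames(cd)), collapse = ", "),
         "; build counts with the sample sheet")
  }
  spikeAll <- which(rd$is_spikein)
  if (length(spikeAll) == 0L) stop("library contains no spike-in line")
  A <- f
  for (s in seq_len(ncol(counts))) {
    spike <- spikeAll
    if ("spikein_set" %in% colnames(cd) && !is.na(cd$spikein_set[s]) &&
        nzchar(cd$spikein_set[s])) {
      keep <- strsplit(cd$spikein_set[s], ";", fixed = TRUE)[[1L]]
      spike <- spikeAll[rd$cell_line_id[spikeAll] %in% keep]
      if (length(spike) == 0L) {
        stop("sample '", colnames(counts)[s],
             "': spikein_set names no library spike-in line")
      }
    }
    fs <- f[spike, s]
    if (any(fs <= 0)) {
      stop("sample '", colnames(counts)[s],
           "': zero spike-in fraction for ",
           paste(rownames(counts)[spike][fs <= 0], collapse = ", "))
    }
    v <- vapply(rd$cell_line_id[spike], .ctgLookup, numeric(1),
                ctg = ctg, agent = cd$agent[s], dose = cd$dose[s],
                isControl = cd$is_control[s])
    if (anyNA(v)) {
      warning("sample '", colnames(counts)[s],
              "': no CTG fitness for spike-in(s) ",
              paste(rd$cell_line_id[spike][is.na(v)], collapse = ", "),
              " under (", cd$agent[s], ", ", cd$dose[s],
              " uM); assuming fitness 1")
      v[is.na(v)] <- 1
    }
    if (any(v <= 0)) stop("CTG fitness must be > 0")
    r <- mean(fs / v)
    A[, s] <- f[, s] / r
    .msg("sample %s: spike-in reference r=%.4g (%d spike-in lines)",
         colnames(counts)[s], r, length(spike))
  }
  SummarizedExperiment::assay(counts, "abundance") <- A
  counts
}

#' Control-anchored relative viability
#'
#' \code{RV[i,s] = A[i,s] / median_ctrl A[i,ctrl]}, where the matched
#' controls are the control-designated samples sharing the sample's
#' \code{arm_type} and \code{timepoint} (replicates pooled; the median is
#' robust to one outlier replicate).  Control samples are normalized against
#' their own stratum median, so their RV sits near 1.
#'
#' @param counts a \linkS4class{BarcodeCounts} with assay \code{abundance}
#'   and \code{arm_type}/\code{timepoint}/\code{is_control} in \code{colData}.
#' @return the object with assay \code{rv} added.
#' @export
controlNormalize <- function(counts) {
  A <- SummarizedExperiment::assay(counts, "abundance")
  cd <- SummarizedExperiment::colData(counts)
  need <- c("arm_type", "timepoint", "is_control")
  if (!all(need %in% colnames(cd))) {
    stop("colData lacks ", paste(setdiff(need, colnames(cd)), collapse = ", "))
  }
  RV <- A
  for (s in seq_len(ncol(counts))) {
    ctrl <- which(cd$is_control & cd$arm_type == cd$arm_type[s] &
                    cd$timepoint == cd$timepoint[s])
    if (length(ctrl) == 0L) {
      stop("no matched control stratum (", cd$arm_type[s], ", day ",
           cd$timepoint[s], ") for sample '", colnames(counts)[s], "'")
    }
    ref <- apply(A[, ctrl, drop = FALSE], 1L, stats::median)
    RV[, s] <- A[, s] / ref
  }
  SummarizedExperiment::assay(counts, "rv") <- RV
  counts
}
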