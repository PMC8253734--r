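## Readers and writers for the pipeline's tabular artifacts.  All tables are
## delimiter-separated text with a header row (TSV by default, CSV by file
## extension) and a schema comment line; writes are atomic.

#' Read a barcode library table
#'
#' Expects columns \code{barcode_id}, \code{sequence}, \code{cell_line_id},
#' \code{is_spikein}.  All \linkS4class{BarcodeLibrary} invariants are
#' enforced: 26-nt ACGT sequences, unique ids and sequences, and minimum
#' pairwise Hamming distance \code{>= 2*kAssign + 1}.
#'
#' @param path TSV/CSV file.
#' @param kAssign Hamming assignment radius the library must support.
#' @return a \linkS4class{BarcodeLibrary}.
#' @export
readBarcodeLibrary <- function(path, kAssign = 2L) {
  df <- .readTable(path, c("barcode_id", "sequence", "cell_line_id",
                           "is_spikein"))
  w <- nchar(df$sequence)
  if (any(w != BARCODE_LEN)) {
    bad <- which(w != BARCODE_LEN)[1L]
    stop(sprintf("row %d ('%s'): sequence length %d, expected %d",
                 bad, df$barcode_id[bad], w[bad], BARCODE_LEN))
  }
  BarcodeLibrary(df$barcode_id, df$sequence, df$cell_line_id,
                 as.logical(df$is_spikein), kAssign)
}

#' @rdname readBarcodeLibrary
#' @param library a BarcodeLibrary to write.
#' @export
writeBarcodeLibrary <- function(library, path) {
  df <- data.frame(barcode_id = barcodeIds(library),
                   sequence = as.character(barcodeSequences(library)),
                   cell_line_id = cellLineIds(library),
                   is_spikein = isSpikein(library))
  .writeTableAtomic(df, path, "barcode_library")
}

#' Read/write panel annotation
#' @param path TSV/CSV file with the \linkS4class{PanelAnnotation} columns.
#' @return a \linkS4class{PanelAnnotation}.
#' @export
readPanelAnnotation <- function(path) {
  PanelAnnotation(.readTable(path, PANEL_COLS))
}

#' @rdname readPanelAnnotation
#' @param panel a PanelAnnotation to write.
#' @export
writePanelAnnotation <- function(panel, path) {
  .writeTableAtomic(as.data.frame(panel), path, "panel_annotation")
}

#' Read/write a sample sheet
#' @param path TSV/CSV file with the \linkS4class{SampleSheet} columns.
#' @return a \linkS4class{SampleSheet}.
#' @export
readSampleSheet <- function(path) {
  SampleSheet(.readTable(path, SHEET_COLS))
}

#' @rdname readSampleSheet
#' @param sheet a SampleSheet to write.
#' @export
writeSampleSheet <- function(sheet, path) {
  .writeTableAtomic(as.data.frame(sheet), path, "sample_sheet")
}

#' Read/write a CTG fitness table
#' @param path TSV/CSV file with columns line_id, agent, dose, fitness.
#' @return a \linkS4class{CTGFitness}.
#' @export
readCTGFitness <- function(path) {
  CTGFitness(.readTable(path, CTG_COLS))
}

#' @rdname readCTGFitness
#' @param ctg a CTGFitness to write.
#' @export
writeCTGFitness <- function(ctg, path) {
  .writeTableAtomic(as.data.frame(ctg), path, "ctg_fitness")
}

#' Read/write barcode counts (long format)
#'
#' Counts are stored long (\code{barcode_id}, \code{sample_id}, \code{count});
#' the per-sample read accounting (total, ambiguous, unassigned and the
#' sample-sheet metadata present in \code{colData}) goes to a companion QC
#' table.
#'
#' @param path counts TSV/CSV.
#' @param qcPath per-sample QC table; defaults to \code{<path>} with a
#'   \code{.qc} suffix inserted before the extension.
#' @param library optional \linkS4class{BarcodeLibrary} to attach rowData.
#' @return a \linkS4class{BarcodeCounts}.
#' @export
readBarcodeCounts <- function(path, qcPath = .qcPathFor(path), library = NULL) {
  long <- .readTable(path, c("barcode_id", "sample_id", "count"))
  qc <- .readTable(qcPath, c("sample_id", "total", "ambiguous", "unassigned"))
  bids <- unique(long$barcode_id)
  sids <- qc$sample_id
  mat <- matrix(0, nrow = length(bids), ncol = length(sids),
                dimnames = list(bids, sids))
  mat[cbind(match(long$barcode_id, bids), match(long$sample_id, sids))] <-
    long$count
  BarcodeCounts(mat, library = library, sampleData = qc,
                ambiguous = qc$ambiguous, unassigned = qc$unassigned)
}

.qcPathFor <- function(path) {
  sub("(\\.[ct]sv)$", ".qc\\1", path, ignore.case = TRUE)
}

#' @rdname readBarcodeCounts
#' @param counts a BarcodeCounts to write.
#' @export
writeBarcodeCounts <- function(counts, path, qcPath = .qcPathFor(path)) {
  cnt <- SummarizedExperiment::assay(counts, "counts")
  long <- data.frame(
    barcode_id = rep(rownames(cnt), times = ncol(cnt)),
    sample_id = rep(colnames(cnt), each = nrow(cnt)),
    count = as.vector(cnt))
  .writeTableAtomic(long, path, "barcode_counts_long")
  cd <- as.data.frame(SummarizedExperiment::colData(counts))
  qc <- cbind(sample_id = colnames(counts), cd)
  .writeTableAtomic(qc, qcPath, "barcode_counts_sample_qc")
  invisible(path)
}

#' Write the normalized abundance table
#'
#' Long-format output with one row per (barcode, sample):
#' \code{fraction}, \code{adjusted_abundance}, \code{relative_viability}
#' (empty where not computed) and the low-count flag.
#'
#' @param counts a \linkS4class{BarcodeCounts} after normalization.
#' @param path output TSV/CSV.
#' @export
writeAbundance <- function(counts, path) {
  getA <- function(nm) {
    if (nm %in% SummarizedExperiment::assayNames(counts)) {
      as.vector(SummarizedExperiment::assay(counts, nm))
    } else rep(NA_real_, nrow(counts) * ncol(counts))
  }
  long <- data.frame(
    barcode_id = rep(rownames(counts), times = ncol(counts)),
    sample_id = rep(colnames(counts), each = nrow(counts)),
    fraction = getA("fraction"),
    adjusted_abundance = getA("abundance"),
    relative_viability = getA("rv"),
    low_count = as.vector(getA("low_count")) > 0)
  .writeTableAtomic(long, path, "abundance_long")
}

#' Diagnose sample-sheet structural problems
#'
#' Checks, without erroring, that (i) every (arm_type, timepoint) stratum
#' containing a non-control sample also contains at least one control sample
#' (DMSO for compound arms, sgNT for CRISPR arms, collected at every
#' timepoint), (ii) (i5, i7) index pairs are unique within the pool, and
#' (iii) at most 96 distinct dual-index combinations are used.
#'
#' @param sheet a \linkS4class{SampleSheet}.
#' @return character vector of human-readable issues; empty iff the sheet is
#'   structurally valid.
#' @export
validateSampleSheet <- function(sheet) {
  sheet <- as.data.frame(sheet)
  issues <- character(0)
  strata <- unique(sheet[, c("arm_type", "timepoint")])
  for (i in seq_len(nrow(strata))) {
    sel <- sheet$arm_type == strata$arm_type[i] &
      sheet$timepoint == strata$timepoint[i]
    if (any(!sheet$is_control[sel]) && !any(sheet$is_control[sel])) {
      offenders <- sheet$sample_id[sel & !sheet$is_control]
      issues <- c(issues, sprintf(
        "missing-control: stratum (%s, day %g) has treated sample(s) %s but no control",
        strata$arm_type[i], strata$timepoint[i],
        paste(offenders, collapse = ",")))
    }
  }
  pairs <- paste(sheet$i5_index, sheet$i7_index, sep = "+")
  dup <- unique(pairs[duplicated(pairs)])
  for (p in dup) {
    issues <- c(issues, sprintf(
      "duplicate-index: (i5,i7) pair %s shared by samples %s", p,
      paste(sheet$sample_id[pairs == p], collapse = ",")))
  }
  if (length(unique(pairs)) > 96L) {
    issues <- c(issues, sprintf(
      "index-capacity: %d distinct (i5,i7) pairs exceed the 96 dual-index combinations available per pool",
      length(unique(pairs))))
  }
  badIdx <- nchar(sheet$i5_index) != 8L | nchar(sheet$i7_index) != 8L
  if (any(badIdx)) {
    issues <- c(issues, sprintf(
      "index-length: sample %s has non-8-nt index",
      sheet$sample_id[badIdx]))
  }
  issues
}
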