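#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAStringSet
NULL

## ---------------------------------------------------------------------------
## BarcodeLibrary
## ---------------------------------------------------------------------------

#' Library of 26-nt cell-line barcodes
#'
#' Maps fixed-length DNA barcodes to cell-line identifiers, including spike-in
#' control lines.  Validity enforces the design constraints that make
#' mismatch-tolerant assignment unambiguous: all sequences exactly 26 nt over
#' \{A,C,G,T\}, unique ids and sequences, and minimum pairwise Hamming
#' distance of at least \code{2 * kAssign(x) + 1}, so that every observed
#' barcode within \code{kAssign} substitutions of a true barcode has a unique
#' nearest library entry.
#'
#' @slot sequences [Biostrings::DNAStringSet] of width 26, named by barcode id.
#' @slot cellLineId character, cell line per barcode.
#' @slot isSpikein logical, spike-in control flag per barcode.
#' @slot kAssign integer, the Hamming assignment radius this library is
#'   validated for.
#'
#' @seealso [readBarcodeLibrary()], [designLibrary()], [assignBarcode()]
#' @export
setClass("BarcodeLibrary",
  slots = c(
    sequences = "DNAStringSet",
    cellLineId = "character",
    isSpikein = "logical",
    kAssign = "integer"
  )
)

BARCODE_LEN <- 26L

setValidity("BarcodeLibrary", function(object) {
  n <- length(object@sequences)
  if (length(object@cellLineId) != n || length(object@isSpikein) != n) {
    return("sequences, cellLineId and isSpikein must have equal length")
  }
  if (n == 0L) return("library is empty")
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    return("every barcode needs a non-empty barcode_id (names of sequences)")
  }
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1L]
    return(sprintf("duplicate barcode_id '%s'", d))
  }
  w <- Biostrings::width(object@sequences)
  if (any(w != BARCODE_LEN)) {
    bad <- which(w != BARCODE_LEN)[1L]
    return(sprintf("barcode '%s' (row %d) has length %d, expected %d",
                   ids[bad], bad, w[bad], BARCODE_LEN))
  }
  seqs <- as.character(object@sequences)
  if (any(grepl("[^ACGT]", seqs))) {
    bad <- which(grepl("[^ACGT]", seqs))[1L]
    return(sprintf("barcode '%s' contains a letter outside {A,C,G,T}",
                   ids[bad]))
  }
  if (anyDuplicated(seqs)) {
    dup <- seqs[duplicated(seqs)][1L]
    pair <- ids[seqs == dup]
    return(sprintf("duplicate barcode sequence shared by '%s' and '%s'",
                   pair[1L], pair[2L]))
  }
  if (length(object@kAssign) != 1L || is.na(object@kAssign) ||
      object@kAssign < 0L) {
    return("kAssign must be a single non-negative integer")
  }
  floorDist <- 2L * object@kAssign + 1L
  mp <- .minPairwiseHamming(object@sequences)
  if (is.finite(mp$min) && mp$min < floorDist) {
    return(sprintf(
      "minimum pairwise Hamming distance %d < required %d (kAssign=%d); closest pair: '%s' vs '%s'",
      mp$min, floorDist, object@kAssign, mp$pair[1L], mp$pair[2L]))
  }
  TRUE
})

#' @param barcodeId character vector of unique barcode identifiers.
#' @param sequence character vector or DNAStringSet of 26-nt sequences.
#' @param cellLineId character vector of cell-line identifiers.
#' @param isSpikein logical vector flagging spike-in control lines.
#' @param kAssign integer Hamming assignment radius the library must support.
#' @rdname BarcodeLibrary-class
#' @export
BarcodeLibrary <- function(barcodeId, sequence, cellLineId,
                           isSpikein = logical(length(barcodeId)),
                           kAssign = 2L) {
  seqs <- Biostrings::DNAStringSet(as.character(sequence))
  names(seqs) <- as.character(barcodeId)
  new("BarcodeLibrary",
      sequences = seqs,
      cellLineId = as.character(cellLineId),
      isSpikein = as.logical(isSpikein),
      kAssign = as.integer(kAssign))
}

## ---------------------------------------------------------------------------
## PanelAnnotation / SampleSheet / CTGFitness: thin DataFrame subclasses
## ---------------------------------------------------------------------------

#' Per-line panel annotation
#'
#' A \linkS4class{DataFrame} with one row per cell line carrying lineage,
#' genotype flags (";"-separated), Cas9 editing efficiency, the spike-in flag
#' and the simulation parameters of the generative model: doubling rate
#' (doublings/day), compound EC50 (uM), Hill coefficient, residual viability
#' fraction, knockout fitness cost and editing fraction.
#'
#' @export
setClass("PanelAnnotation", contains = "DFrame")

PANEL_COLS <- c("cell_line_id", "lineage", "genotype_flags", "cas9_efficiency",
                "is_spikein", "doubling_rate", "ec50", "hill", "residual",
                "ko_cost", "edit_frac")

setValidity("PanelAnnotation", function(object) {
  miss <- setdiff(PANEL_COLS, colnames(object))
  if (length(miss) > 0L) {
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(object$cell_line_id)) return("duplicate cell_line_id")
  frac <- c("cas9_efficiency", "residual", "ko_cost", "edit_frac")
  for (cn in frac) {
    v <- object[[cn]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      return(sprintf("%s must lie in [0,1]", cn))
    }
  }
  if (any(!is.na(object$ec50) & object$ec50 <= 0)) return("ec50 must be > 0")
  if (any(!is.na(object$doubling_rate) & object$doubling_rate <= 0)) {
    return("doubling_rate must be > 0")
  }
  spk <- object$is_spikein
  eff <- object$cas9_efficiency
  if (any(spk & !is.na(eff) & eff > 0)) {
    return("spike-in lines are Cas9-dead: cas9_efficiency must be 0 or NA")
  }
  TRUE
})

#' @param df data.frame or DataFrame with the panel columns.
#' @rdname PanelAnnotation-class
#' @export
PanelAnnotation <- function(df) {
  df <- as(as.data.frame(df), "DFrame")
  new("PanelAnnotation", df)
}

#' Sample sheet for a sequencing pool
#'
#' One row per sequencing sample: treatment arm (\code{"compound"} or
#' \code{"crispr"}), agent (compound name or sgRNA), dose in uM (0 for DMSO),
#' timepoint in days, replicate, control designation (DMSO for compound arms,
#' sgNT for CRISPR arms) and the 8-nt i5/i7 dual indexes.  Structural
#' invariants (matched controls per stratum, index uniqueness and the 96-pair
#' capacity) are checked diagnostically by [validateSampleSheet()].
#'
#' @export
setClass("SampleSheet", contains = "DFrame")

SHEET_COLS <- c("sample_id", "arm_type", "agent", "dose", "timepoint",
                "replicate", "is_control", "i5_index", "i7_index")

setValidity("SampleSheet", function(object) {
  miss <- setdiff(SHEET_COLS, colnames(object))
  if (length(miss) > 0L) {
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(object$sample_id)) return("duplicate sample_id")
  if (!all(object$arm_type %in% c("compound", "crispr"))) {
    return("arm_type must be 'compound' or 'crispr'")
  }
  TRUE
})

#' @param df data.frame or DataFrame with the sample-sheet columns.
#' @rdname SampleSheet-class
#' @export
SampleSheet <- function(df) {
  df <- as(as.data.frame(df), "DFrame")
  new("SampleSheet", df)
}

#' CTG fitness table for spike-in lines
#'
#' Relative 5-day CTG viability of each spike-in line per treatment condition
#' \code{(agent, dose)}, used to viability-correct the spike-in reference in
#' [spikeinAdjust()].  Fitness must be positive and equal 1 in the control
#' (dose 0) condition.
#'
#' @export
setClass("CTGFitness", contains = "DFrame")

CTG_COLS <- c("line_id", "agent", "dose", "fitness")

setValidity("CTGFitness", function(object) {
  miss <- setdiff(CTG_COLS, colnames(object))
  if (length(miss) > 0L) {
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  v <- object$fitness
  if (any(!is.finite(v) | v <= 0)) return("fitness must be finite and > 0")
  if (any(v > 1.5)) return("fitness must be <= 1.5")
  ctrl <- object$dose == 0
  if (any(ctrl) && any(abs(v[ctrl] - 1) > 1e-9)) {
    return("control (dose 0) fitness must equal 1")
  }
  TRUE
})

#' @param df data.frame or DataFrame with columns line_id, agent, dose, fitness.
#' @rdname CTGFitness-class
#' @export
CTGFitness <- function(df) {
  df <- as(as.data.frame(df), "DFrame")
  new("CTGFitness", df)
}

## ---------------------------------------------------------------------------
## BarcodeCounts: SummarizedExperiment subclass
## ---------------------------------------------------------------------------

#' Barcode-by-sample count matrix
#'
#' A \linkS4class{SummarizedExperiment} whose \code{counts} assay holds
#' non-negative integer read counts per (barcode, sample).  \code{colData}
#' carries the per-sample read accounting (\code{total}, \code{ambiguous},
#' \code{unassigned}) plus any sample-sheet columns; \code{rowData} carries
#' \code{cell_line_id} and \code{is_spikein} from the barcode library.
#' Validity enforces conservation: per sample,
#' assigned + ambiguous + unassigned = total reads processed.
#' Normalization adds assays \code{fraction}, \code{abundance} (spike-in
#' adjusted), \code{rv} (control-anchored relative viability) and
#' \code{low_count}.
#'
#' @export
setClass("BarcodeCounts", contains = "SummarizedExperiment")

setValidity("BarcodeCounts", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'counts' is required")
  }
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(!is.finite(cnt)) || any(cnt < 0)) {
    return("counts must be finite and non-negative")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("total", "ambiguous", "unassigned")
  miss <- setdiff(need, colnames(cd))
  if (length(miss) > 0L) {
    return(paste("colData lacks:", paste(miss, collapse = ", ")))
  }
  tot <- colSums(cnt) + cd$ambiguous + cd$unassigned
  if (any(abs(tot - cd$total) > 1e-6)) {
    bad <- colnames(object)[which(abs(tot - cd$total) > 1e-6)[1L]]
    return(sprintf(
      "read conservation violated in sample '%s': assigned+ambiguous+unassigned != total",
      bad))
  }
  TRUE
})

#' @param counts numeric matrix, barcodes x samples.
#' @param library optional \linkS4class{BarcodeLibrary} supplying rowData.
#' @param sampleData optional data.frame/DataFrame of per-sample metadata
#'   (matched by \code{sample_id} to \code{colnames(counts)}).
#' @param ambiguous,unassigned per-sample integer vectors (default 0).
#' @rdname BarcodeCounts-class
#' @export
BarcodeCounts <- function(counts, library = NULL, sampleData = NULL,
                          ambiguous = NULL, unassigned = NULL) {
  counts <- as.matrix(counts)
  ns <- ncol(counts)
  if (is.null(ambiguous)) ambiguous <- integer(ns)
  if (is.null(unassigned)) unassigned <- integer(ns)
  cd <- S4Vectors::DataFrame(
    total = colSums(counts) + ambiguous + unassigned,
    ambiguous = ambiguous,
    unassigned = unassigned,
    row.names = colnames(counts))
  if (!is.null(sampleData)) {
    sd <- as(as.data.frame(sampleData), "DFrame")
    m <- match(colnames(counts), sd$sample_id)
    if (anyNA(m)) {
      stop("sampleData lacks sample(s): ",
           paste(colnames(counts)[is.na(m)], collapse = ", "))
    }
    cd <- cbind(cd, sd[m, setdiff(colnames(sd), "sample_id"), drop = FALSE])
  }
  rd <- NULL
  if (!is.null(library)) {
    m <- match(rownames(counts), barcodeIds(library))
    if (anyNA(m)) {
      stop("library lacks barcode(s): ",
           paste(rownames(counts)[is.na(m)], collapse = ", "))
    }
    rd <- S4Vectors::DataFrame(
      cell_line_id = cellLineIds(library)[m],
      is_spikein = isSpikein(library)[m],
      row.names = rownames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  if (!is.null(rd)) SummarizedExperiment::rowData(se) <- rd
  new("BarcodeCounts", se)
}

## ---------------------------------------------------------------------------
## PoolState, ExtractionConfig, AmpliconTemplate, LinearityReport
## ---------------------------------------------------------------------------

#' State of a growing barcoded cell pool
#'
#' Expected cell numbers per line at a given day under one condition.  The
#' generative model works with expectations; Poisson end-point noise is
#' applied when a pool is realized (see [simulatePoolGrowth()]).
#'
#' @slot cellNumbers named non-negative numeric, expected cells per
#'   cell_line_id.
#' @slot day numeric, days since seeding.
#' @slot armType,agent character; \code{dose} numeric (uM): the condition.
#' @export
setClass("PoolState",
  slots = c(cellNumbers = "numeric", day = "numeric",
            armType = "character", agent = "character", dose = "numeric"))

setValidity("PoolState", function(object) {
  v <- object@cellNumbers
  if (is.null(names(v)) || anyDuplicated(names(v))) {
    return("cellNumbers must be uniquely named by cell_line_id")
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    return("cellNumbers must be finite and >= 0")
  }
  if (sum(v) <= 0) return("pool is empty (all cell numbers zero)")
  TRUE
})

#' @param cellNumbers named numeric vector of cells per line.
#' @param day numeric day.
#' @param armType,agent,dose the condition applied so far.
#' @rdname PoolState-class
#' @export
PoolState <- function(cellNumbers, day = 0,
                      armType = "compound", agent = "DMSO", dose = 0) {
  new("PoolState", cellNumbers = cellNumbers, day = as.numeric(day),
      armType = armType, agent = agent, dose = as.numeric(dose))
}

#' Barcode extraction settings
#'
#' @slot anchorFwd 20-nt forward anchor (the forward amplification primer).
#' @slot anchorMaxMismatch maximum substitutions tolerated in the anchor.
#' @slot barcodeLen barcode length (26).
#' @slot kAssign Hamming radius for barcode-to-library assignment.
#' @slot searchWindow integer(2), 0-based half-open window searched for the
#'   anchor.
#' @slot scanRevComp also scan the reverse complement of each read and keep
#'   the better anchor hit.
#' @export
setClass("ExtractionConfig",
  slots = c(anchorFwd = "character", anchorMaxMismatch = "integer",
            barcodeLen = "integer", kAssign = "integer",
            searchWindow = "integer", scanRevComp = "logical"))

setValidity("ExtractionConfig", function(object) {
  if (object@anchorMaxMismatch < 0L) return("anchorMaxMismatch must be >= 0")
  if (object@kAssign < 0L) return("kAssign must be >= 0")
  if (length(object@searchWindow) != 2L ||
      object@searchWindow[1L] < 0L ||
      object@searchWindow[2L] <= object@searchWindow[1L]) {
    return("searchWindow must be [start, end) with 0 <= start < end")
  }
  TRUE
})

ANCHOR_FWD <- "ACAACAAGCACCGGGATAAG"
PRIMER_REV <- "AGGAACTGCTTCCTTCACGA"

#' @param anchorFwd,anchorMaxMismatch,barcodeLen,kAssign,searchWindow,scanRevComp
#'   see slots.
#' @rdname ExtractionConfig-class
#' @export
ExtractionConfig <- function(anchorFwd = ANCHOR_FWD,
                             anchorMaxMismatch = 2L,
                             barcodeLen = BARCODE_LEN,
                             kAssign = 2L,
                             searchWindow = c(0L, 150L),
                             scanRevComp = FALSE) {
  new("ExtractionConfig", anchorFwd = anchorFwd,
      anchorMaxMismatch = as.integer(anchorMaxMismatch),
      barcodeLen = as.integer(barcodeLen),
      kAssign = as.integer(kAssign),
      searchWindow = as.integer(searchWindow),
      scanRevComp = scanRevComp)
}

#' Two-step PCR amplicon layout
#'
#' The first PCR amplifies a 550-bp product spanning the barcode using the
#' universal primer pair; the second (indexing) PCR produces the final 332-bp
#' sequencing library nested inside it.  Sequences hold an
#' \code{NNNN...} placeholder of width 26 at the barcode slot.
#'
#' @slot firstProduct 550-nt template of the first PCR product.
#' @slot secondProduct 332-nt template of the indexed sequencing product.
#' @slot barcodeStart 1-based start of the 26-nt barcode slot within
#'   \code{secondProduct}.
#' @slot anchorFwd,primerRev the universal primer pair.
#' @export
setClass("AmpliconTemplate",
  slots = c(firstProduct = "character", secondProduct = "character",
            barcodeStart = "integer", anchorFwd = "character",
            primerRev = "character"))

setValidity("AmpliconTemplate", function(object) {
  if (nchar(object@firstProduct) != 550L) {
    return("first PCR product must be 550 bp")
  }
  if (nchar(object@secondProduct) != 332L) {
    return("second (indexed) PCR product must be 332 bp")
  }
  slot2 <- substr(object@secondProduct, object@barcodeStart,
                  object@barcodeStart + BARCODE_LEN - 1L)
  if (slot2 != strrep("N", BARCODE_LEN)) {
    return("barcode slot must be a 26-nt N placeholder in secondProduct")
  }
  if (!grepl(object@anchorFwd, object@secondProduct, fixed = TRUE)) {
    return("forward anchor not present in secondProduct")
  }
  if (!grepl(strrep("N", BARCODE_LEN), object@firstProduct, fixed = TRUE)) {
    return("barcode slot not present in firstProduct")
  }
  TRUE
})

#' Dilution-series linearity report
#'
#' @slot table DataFrame with designed_fraction, estimated_fraction, count and
#'   detected per barcode.
#' @slot slope,r log10-log10 regression slope and Pearson r over detected
#'   barcodes.
#' @slot dynamicRange ratio of largest to smallest designed fraction among
#'   detected barcodes.
#' @slot detectMinReads raw-count detection floor used.
#' @export
setClass("LinearityReport",
  slots = c(table = "DFrame", slope = "numeric", r = "numeric",
            dynamicRange = "numeric", detectMinReads = "integer"))

setValidity("LinearityReport", function(object) {
  if (object@dynamicRange < 1) return("dynamicRange must be >= 1")
  est <- object@table$estimated_fraction[object@table$detected]
  if (any(est <= 0)) return("detected barcodes must have estimated_fraction > 0")
  TRUE
})
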