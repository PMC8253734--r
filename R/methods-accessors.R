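#' @rdname BarcodeLibrary-class
#' @export
setMethod("barcodeIds", "BarcodeLibrary", function(x) names(x@sequences))

#' @rdname BarcodeLibrary-class
#' @export
setMethod("barcodeSequences", "BarcodeLibrary", function(x) x@sequences)

#' @rdname BarcodeLibrary-class
#' @export
setMethod("cellLineIds", "BarcodeLibrary", function(x) x@cellLineId)

#' @rdname BarcodeLibrary-class
#' @export
setMethod("isSpikein", "BarcodeLibrary", function(x) x@isSpikein)

#' @rdname BarcodeLibrary-class
#' @export
setMethod("isSpikein", "PanelAnnotation", function(x) x$is_spikein)

#' @rdname BarcodeLibrary-class
#' @export
setMethod("cellLineIds", "PanelAnnotation", function(x) x$cell_line_id)

#' @rdname BarcodeLibrary-class
#' @export
setMethod("kAssign", "BarcodeLibrary", function(x) x@kAssign)

#' @rdname BarcodeLibrary-class
#' @export
setMethod("kAssign", "ExtractionConfig", function(x) x@kAssign)

#' @rdname BarcodeLibrary-class
#' @export
setMethod("minPairwiseDistance", "BarcodeLibrary",
          function(x) .minPairwiseHamming(x@sequences)$min)

setMethod("length", "BarcodeLibrary", function(x) length(x@sequences))

#' Subset a barcode library by index, id or logical mask
#' @param x a BarcodeLibrary.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "BarcodeLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, barcodeIds(x))
  BarcodeLibrary(barcodeIds(x)[i], x@sequences[i], x@cellLineId[i],
                 x@isSpikein[i], x@kAssign)
})

#' @rdname PoolState-class
#' @export
setMethod("cellNumbers", "PoolState", function(x) x@cellNumbers)

setMethod("show", "BarcodeLibrary", function(object) {
  cat(sprintf(
    "BarcodeLibrary: %d barcodes (%d spike-in), width %d, kAssign=%d\n",
    length(object), sum(object@isSpikein), BARCODE_LEN, object@kAssign))
  n <- min(3L, length(object))
  for (i in seq_len(n)) {
    cat(sprintf("  %s  %s  %s%s\n", barcodeIds(object)[i],
                as.character(object@sequences[[i]]),
                object@cellLineId[i],
                if (object@isSpikein[i]) " [spike-in]" else ""))
  }
  if (length(object) > n) cat(sprintf("  ... and %d more\n", length(object) - n))
})

setMethod("show", "PoolState", function(object) {
  cat(sprintf(
    "PoolState: %d lines, %.3g total cells, day %g, %s/%s dose %g uM\n",
    length(object@cellNumbers), sum(object@cellNumbers), object@day,
    object@armType, object@agent, object@dose))
})

setMethod("show", "LinearityReport", function(object) {
  cat(sprintf(
    "LinearityReport: %d/%d detected (>= %d reads); slope %.4f, r %.4f, dynamic range %.4g-fold\n",
    sum(object@table$detected), nrow(object@table), object@detectMinReads,
    object@slope, object@r, object@dynamicRange))
})

#' @rdname LinearityReport-class
#' @param x a LinearityReport.
#' @export
linearitySlope <- function(x) x@slope

#' @rdname LinearityReport-class
#' @export
linearityR <- function(x) x@r

#' @rdname LinearityReport-class
#' @export
dynamicRangeDetected <- function(x) x@dynamicRange

#' @rdname LinearityReport-class
#' @export
detectedBarcodes <- function(x) x@table$barcode_id[x@table$detected]
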