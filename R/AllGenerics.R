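#' @rdname BarcodeLibrary-class
#' @param x a BarcodeLibrary (or object with barcode annotation).
#' @export
setGeneric("barcodeIds", function(x) standardGeneric("barcodeIds"))

#' @rdname BarcodeLibrary-class
#' @export
setGeneric("barcodeSequences", function(x) standardGeneric("barcodeSequences"))

#' @rdname BarcodeLibrary-class
#' @export
setGeneric("cellLineIds", function(x) standardGeneric("cellLineIds"))

#' @rdname BarcodeLibrary-class
#' @export
setGeneric("isSpikein", function(x) standardGeneric("isSpikein"))

#' @rdname BarcodeLibrary-class
#' @export
setGeneric("kAssign", function(x) standardGeneric("kAssign"))

#' @rdname BarcodeLibrary-class
#' @export
setGeneric("minPairwiseDistance",
           function(x) standardGeneric("minPairwiseDistance"))

#' @rdname PoolState-class
#' @param x a PoolState.
#' @export
setGeneric("cellNumbers", function(x) standardGeneric("cellNumbers"))
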