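#' Design a barcode library
#'
#' Draws random 26-mers subject to the design constraints used for
#' cell-line barcoding: GC content within \code{gcRange}, no homopolymer run
#' longer than \code{maxHomopolymer}, and minimum pairwise Hamming distance
#' \code{2*kAssign + 1} so that assignment within \code{kAssign}
#' substitutions is unambiguous.  Deterministic for a given seed.
#'
#' @param nLines number of (non-spike-in) cell lines.
#' @param nSpikein number of spike-in control lines appended to the library.
#' @param seed integer RNG seed.
#' @param kAssign Hamming assignment radius to guarantee.
#' @param gcRange numeric(2), allowed GC fraction.
#' @param maxHomopolymer longest allowed single-base run.
#' @param maxAttempts candidate draws before giving up.
#' @return a \linkS4class{BarcodeLibrary} of \code{nLines + nSpikein} entries;
#'   spike-in entries are last, named \code{SPK293T_<k>}.
#' @examples
#' lib <- designLibrary(20, 2, seed = 1)
#' minPairwiseDistance(lib) >= 5
#' @export
designLibrary <- function(nLines, nSpikein = 0L, seed = 1L, kAssign = 2L,
                          gcRange = c(0.40, 0.60), maxHomopolymer = 4L,
                          maxAttempts = 1000L * (nLines + nSpikein)) {
  stopifnot(nLines >= 1L, nSpikein >= 0L)
  nTotal <- nLines + nSpikein
  floorDist <- 2L * as.integer(kAssign) + 1L
  seqs <- .withSeed(seed, {
    acc <- character(0)
    accM <- NULL
    attempts <- 0L
    while (length(acc) < nTotal) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts) {
        stop(sprintf(
          "could not design %d barcodes meeting GC/homopolymer/distance constraints within %d attempts",
          nTotal, maxAttempts))
      }
      cand <- paste(sample(DNA_BASES, BARCODE_LEN, replace = TRUE),
                    collapse = "")
      gc <- (nchar(gsub("[AT]", "", cand))) / BARCODE_LEN
      if (gc < gcRange[1L] || gc > gcRange[2L]) next
      if (grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}",
                        maxHomopolymer + 1L, maxHomopolymer + 1L,
                        maxHomopolymer + 1L, maxHomopolymer + 1L), cand)) next
      if (length(acc) > 0L) {
        d <- .hammingCross(cand, acc)
        if (min(d) < floorDist) next
      }
      acc <- c(acc, cand)
    }
    acc
  })
  ids <- sprintf("BC%04d", seq_len(nTotal))
  lines <- c(sprintf("CL%04d", seq_len(nLines)),
             if (nSpikein > 0L) sprintf("SPK293T_%d", seq_len(nSpikein)))
  BarcodeLibrary(ids, seqs, lines,
                 isSpikein = c(rep(FALSE, nLines), rep(TRUE, nSpikein)),
                 kAssign = kAssign)
}

#' Designed fractions for the 5-tier dilution pool
#'
#' Encodes the equal-volume mixing semantics of the dilution-series
#' validation: barcoded plasmids at concentrations \code{tiers} (default
#' 100/10/1/0.1/0.01 ng/ul, 4 plasmids per tier) are mixed in equal volumes,
#' so a tier-\eqn{c} barcode contributes designed fraction
#' \eqn{c / (perTier \cdot \sum tiers)}.  The default design spans a
#' 10,000-fold abundance range.
#'
#' @param library a \linkS4class{BarcodeLibrary} (or character of barcode ids)
#'   with exactly \code{length(tiers) * perTier} entries.
#' @param tiers tier concentrations, largest first.
#' @param perTier barcodes per tier.
#' @return data.frame with \code{barcode_id}, \code{tier},
#'   \code{designed_fraction} (sums to 1).
#' @export
makeDilutionPool <- function(library, tiers = c(100, 10, 1, 0.1, 0.01),
                             perTier = 4L) {
  ids <- if (is(library, "BarcodeLibrary")) barcodeIds(library)
         else as.character(library)
  need <- length(tiers) * perTier
  if (length(ids) != need) {
    stop(sprintf("library has %d barcodes; the %d-tier x %d design needs exactly %d",
                 length(ids), length(tiers), perTier, need))
  }
  tier <- rep(tiers, each = perTier)
  data.frame(barcode_id = ids, tier = tier,
             designed_fraction = tier / (perTier * sum(tiers)))
}
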