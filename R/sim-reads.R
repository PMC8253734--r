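## Amplicon construction and FASTQ read emission.

#' Build the two-step PCR amplicon template
#'
#' The first PCR amplifies a 550-bp product with the universal primer pair
#' (forward \code{ACAACAAGCACCGGGATAAG}, reverse \code{AGGAACTGCTTCCTTCACGA});
#' the 26-nt barcode slot directly abuts the forward primer.  The second
#' (indexing) PCR yields the final 332-bp dual-indexed product, whose primers
#' tail onto sites nested in the first product so the forward universal
#' primer is retained internally in every read, 30 nt from the 5' end — the
#' extraction anchor therefore ends at position 50, comfortably before
#' position 150 so short-read prefixes still cover anchor + barcode.
#' Spacer and flank sequences are synthetic (drawn from \code{seed});
#' only the printed product lengths (550/332), the primer placements and the
#' 26-nt barcode slot are constrained.
#'
#' @param seed integer seed for the synthetic spacer/flank sequences.
#' @return an \linkS4class{AmpliconTemplate}.
#' @export
ampliconTemplate <- function(seed = 101L) {
  rnd <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
  .withSeed(seed, {
    ## the barcode slot directly abuts the forward primer: extraction slices
    ## the 26-mer immediately after the anchor
    spacerB <- rnd(10L)
    stuffer <- rnd(550L - 76L)        # between spacer B and the reverse site
    tail5 <- rnd(30L)                 # index/adapter tail, 5' of the anchor
    slot <- strrep("N", BARCODE_LEN)
    rcRev <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(PRIMER_REV)))
    first <- paste0(ANCHOR_FWD, slot, spacerB, stuffer, rcRev)
    secondCore <- paste0(tail5, ANCHOR_FWD, slot, spacerB)
    tail3 <- substr(stuffer, 1L, 332L - nchar(secondCore))
    second <- paste0(secondCore, tail3)
    new("AmpliconTemplate", firstProduct = first, secondProduct = second,
        barcodeStart = nchar(tail5) + 20L + 1L,
        anchorFwd = ANCHOR_FWD, primerRev = PRIMER_REV)
  })
}

## i.i.d. per-base substitution errors.  Per-read error counts are
## Binomial(L, p); positions within a read are drawn uniformly per pass
## (a repeated position across passes is possible but has probability
## ~k^2/L per multi-error read, negligible at the error rates modeled).
.applyReadErrors <- function(reads, perBaseError) {
  if (perBaseError <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads[1L])
  k <- stats::rbinom(length(reads), L, perBaseError)
  alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (pass in seq_len(max(k, 0L))) {
    idx <- which(k >= pass)
    if (length(idx) == 0L) break
    pos <- sample.int(L, length(idx), replace = TRUE)
    orig <- substr(reads[idx], pos, pos)
    pick <- sample.int(3L, length(idx), replace = TRUE)
    newb <- alt[cbind(match(orig, rownames(alt)), pick)]
    reads[idx] <- paste0(substr(reads[idx], 1L, pos - 1L), newb,
                         substr(reads[idx], pos + 1L, L))
  }
  reads
}

.randomReads <- function(n, L) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * L, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Emit sequencing reads for one sample
#'
#' Reads are drawn multinomially across barcodes with probabilities
#' proportional to the pool's cell numbers, rendered as the 332-bp indexed
#' product (or its first \code{readLength} nt), then subjected to i.i.d.
#' per-base substitution errors.  A configured fraction of anchor-less junk
#' reads (uniform random sequence) stands in for PhiX and artifacts.  Exactly
#' \code{depth} reads are written: barcode-derived + junk = depth.
#' Deterministic for a given seed.  Quality strings are constant Phred 30
#' (offset 33).
#'
#' @param pool a \linkS4class{PoolState}.
#' @param library a \linkS4class{BarcodeLibrary}; pool lines are matched to
#'   barcodes via \code{cellLineIds(library)}.
#' @param depth total reads to emit (>= 1).
#' @param path output FASTQ; gzip if the name ends in \code{.gz}.
#' @param perBaseError substitution rate in \code{[0, 0.1)}.
#' @param seed RNG seed.
#' @param readLength read length (prefix of the 332-bp product); \code{NULL}
#'   emits the full product.
#' @param junkFraction expected fraction of anchor-less reads (default 1\%).
#' @param template an \linkS4class{AmpliconTemplate}.
#' @return (invisibly) list with \code{path}, \code{depth}, \code{junk} (junk
#'   reads emitted) and \code{truth} (reads drawn per barcode).
#' @export
simulateReads <- function(pool, library, depth, path,
                          perBaseError = 0.001, seed = 1L,
                          readLength = NULL, junkFraction = 0.01,
                          template = ampliconTemplate()) {
  stopifnot(depth >= 1, perBaseError >= 0, perBaseError < 0.1,
            junkFraction >= 0, junkFraction < 1)
  cells <- cellNumbers(pool)[cellLineIds(library)]
  cells[is.na(cells)] <- 0
  if (sum(cells) <= 0) stop("empty pool: no library line has cells > 0")
  prod <- template@secondProduct
  L <- if (is.null(readLength)) nchar(prod) else as.integer(readLength)
  if (L < template@barcodeStart + BARCODE_LEN - 1L) {
    stop("readLength ", L, " does not cover the barcode slot (ends at ",
         template@barcodeStart + BARCODE_LEN - 1L, ")")
  }
  perBc <- substr(vapply(as.character(barcodeSequences(library)), function(b) {
    paste0(substr(prod, 1L, template@barcodeStart - 1L), b,
           substr(prod, template@barcodeStart + BARCODE_LEN, nchar(prod)))
  }, character(1), USE.NAMES = FALSE), 1L, L)
  out <- .withSeed(seed, {
    nJunk <- stats::rbinom(1L, depth, junkFraction)
    nReal <- depth - nJunk
    cnt <- if (nReal > 0L) {
      as.vector(stats::rmultinom(1L, nReal, cells / sum(cells)))
    } else integer(length(cells))
    reads <- c(rep(perBc, cnt), .randomReads(nJunk, L))
    reads <- reads[sample.int(length(reads))]
    reads <- .applyReadErrors(reads, perBaseError)
    list(reads = reads, junk = nJunk,
         truth = stats::setNames(cnt, barcodeIds(library)))
  })
  dss <- Biostrings::DNAStringSet(out$reads)
  names(dss) <- sprintf("read%07d", seq_along(dss))
  qual <- Biostrings::BStringSet(rep(strrep("?", L), length(dss)))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(list(path = path, depth = depth, junk = out$junk,
                 truth = out$truth))
}
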