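## Barcode extraction: anchor search in reads, Hamming assignment to the
## library, and streaming FASTQ counting.

## Vectorized anchor scan over a DNAStringSet.  Returns, per read, the
## 0-based position immediately after the best (fewest-mismatch, then
## leftmost) anchor occurrence inside the search window, and the mismatch
## count; NA where no occurrence within tolerance.
.anchorScan <- function(reads, cfg) {
  n <- length(reads)
  pos <- rep(NA_integer_, n)
  ned <- rep(NA_integer_, n)
  if (n == 0L) return(list(pos = pos, nedit = ned))
  alen <- nchar(cfg@anchorFwd)
  w <- Biostrings::width(reads)
  winStart <- cfg@searchWindow[1L] + 1L          # 1-based
  winEnd <- pmin(w, cfg@searchWindow[2L])
  scanable <- which(winEnd - winStart + 1L >= alen)
  if (length(scanable) == 0L) return(list(pos = pos, nedit = ned))
  win <- IRanges::narrow(reads[scanable], start = winStart,
                         end = winEnd[scanable])
  pat <- Biostrings::DNAString(cfg@anchorFwd)
  ## exact pass (0 mismatches is always the best achievable)
  m0 <- Biostrings::vmatchPattern(pat, win)
  nh <- S4Vectors::elementNROWS(m0)
  hit0 <- which(nh > 0L)
  if (length(hit0) > 0L) {
    ## leftmost exact hit per read, without materializing per-read lists
    allStarts <- BiocGenerics::start(BiocGenerics::unlist(m0))
    grp <- rep.int(seq_along(nh), nh)
    first <- !duplicated(grp)
    pos[scanable[grp[first]]] <- winStart - 1L + allStarts[first] - 1L + alen
    ned[scanable[hit0]] <- 0L
  }
  ## mismatch-tolerant pass on the remainder, fully vectorized: slice every
  ## candidate site, count mismatches by column comparison, keep the
  ## fewest-mismatch (then leftmost) hit per read
  if (cfg@anchorMaxMismatch > 0L) {
    rest <- setdiff(seq_along(scanable), hit0)
    if (length(rest) > 0L) {
      sub <- win[rest]
      mm <- Biostrings::vmatchPattern(pat, sub,
                                      max.mismatch = cfg@anchorMaxMismatch,
                                      with.indels = FALSE)
      nh2 <- S4Vectors::elementNROWS(mm)
      if (any(nh2 > 0L)) {
        st <- BiocGenerics::start(BiocGenerics::unlist(mm))
        grp <- rep.int(seq_along(nh2), nh2)       # index into sub per hit
        wlen <- Biostrings::width(sub)
        keep <- st >= 1L & st + alen - 1L <= wlen[grp]
        st <- st[keep]
        grp <- grp[keep]
        if (length(st) > 0L) {
          chars <- as.character(sub)[grp]
          segs <- substr(chars, st, st + alen - 1L)
          ed <- as.vector(.hammingCross(segs, cfg@anchorFwd))
          o <- order(grp, ed, st)
          best <- o[!duplicated(grp[o])]
          i <- scanable[rest[grp[best]]]
          pos[i] <- winStart - 1L + st[best] - 1L + alen
          ned[i] <- ed[best]
        }
      }
    }
  }
  list(pos = pos, nedit = ned)
}

#' Locate the barcode anchor in a read
#'
#' Searches the configured window for the forward anchor (the universal
#' forward primer) tolerating up to \code{anchorMaxMismatch} substitutions.
#' Among occurrences with the minimal mismatch count the leftmost wins.
#'
#' @param read a single DNA string.
#' @param cfg an \linkS4class{ExtractionConfig}.
#' @return the 0-based position immediately after the anchor, or \code{NA}
#'   if no occurrence within tolerance.
#' @examples
#' cfg <- ExtractionConfig()
#' findAnchor(paste0(cfg@anchorFwd, strrep("A", 26)), cfg)  # 20
#' @export
findAnchor <- function(read, cfg = ExtractionConfig()) {
  stopifnot(is.character(read), length(read) == 1L, nchar(read) > 0L)
  .anchorScan(Biostrings::DNAStringSet(read), cfg)$pos[1L]
}

## Vectorized assignment of observed 26-mers to library barcodes.
## Returns a character vector of barcode ids, "ambiguous" or "unassigned".
.assignBarcodes <- function(observed, library, kAssign) {
  libSeq <- as.character(barcodeSequences(library))
  ids <- barcodeIds(library)
  out <- rep("unassigned", length(observed))
  lenOK <- !is.na(observed) & nchar(observed) == BARCODE_LEN
  exact <- match(observed, libSeq)
  out[lenOK & !is.na(exact)] <- ids[exact[lenOK & !is.na(exact)]]
  todo <- which(lenOK & is.na(exact))
  if (length(todo) > 0L && kAssign > 0L) {
    uo <- unique(observed[todo])
    uo <- uo[!grepl("[^ACGT]", uo)]             # non-ACGT cannot match
    if (length(uo) > 0L) {
      d <- .hammingCross(uo, libSeq)
      dmin <- apply(d, 1L, min)
      nmin <- rowSums(d == dmin)
      call <- ifelse(dmin > kAssign, "unassigned",
                     ifelse(nmin > 1L, "ambiguous",
                            ids[apply(d, 1L, which.min)]))
      m <- match(observed[todo], uo)
      hitm <- !is.na(m)
      out[todo[hitm]] <- call[m[hitm]]
    }
  }
  out
}

#' Assign an observed barcode to the library
#'
#' An exact match wins immediately; otherwise the unique library entry at
#' minimal Hamming distance \code{<= kAssign}.  Two entries tied at the
#' minimum give \code{"ambiguous"}; minimum above \code{kAssign} (or a
#' wrong-length/non-ACGT observation) gives \code{"unassigned"}.
#'
#' @param observed observed barcode string(s).
#' @param library a \linkS4class{BarcodeLibrary}.
#' @param kAssign Hamming radius (default: the library's validated radius).
#' @return character vector: barcode id, \code{"ambiguous"} or
#'   \code{"unassigned"} per observation.
#' @export
assignBarcode <- function(observed, library, kAssign = NULL) {
  if (is.null(kAssign)) kAssign <- library@kAssign
  .assignBarcodes(as.character(observed), library, as.integer(kAssign))
}

## Tally one chunk of reads; returns list(counts, ambiguous, unassigned).
.countChunk <- function(reads, library, cfg) {
  scan <- .anchorScan(reads, cfg)
  if (cfg@scanRevComp) {
    rc <- Biostrings::reverseComplement(reads)
    scanRC <- .anchorScan(rc, cfg)
    better <- !is.na(scanRC$nedit) &
      (is.na(scan$nedit) | scanRC$nedit < scan$nedit)
    scan$pos[better] <- scanRC$pos[better]
    reads[better] <- rc[better]
  }
  w <- Biostrings::width(reads)
  ok <- !is.na(scan$pos) & (scan$pos + BARCODE_LEN) <= w
  obs <- rep(NA_character_, length(reads))
  if (any(ok)) {
    obs[ok] <- as.character(
      IRanges::narrow(reads[ok], start = scan$pos[ok] + 1L,
                      width = BARCODE_LEN))
  }
  call <- rep("unassigned", length(reads))
  call[ok] <- .assignBarcodes(obs[ok], library, cfg@kAssign)
  cnt <- table(factor(call[!(call %in% c("ambiguous", "unassigned"))],
                      levels = barcodeIds(library)))
  list(counts = as.integer(cnt),
       ambiguous = sum(call == "ambiguous"),
       unassigned = sum(call == "unassigned"))
}

#' Count barcodes in FASTQ files
#'
#' Streams each sample's FASTQ in chunks (constant memory in read count) and
#' runs the per-read pipeline: anchor search, 26-nt slice, mismatch-tolerant
#' assignment.  Reads whose anchor is missing, whose remaining sequence is
#' shorter than 26 nt, or whose barcode is beyond \code{kAssign} of every
#' library entry are unassigned; ties at the minimal distance are ambiguous.
#' Per sample, assigned + ambiguous + unassigned equals the records
#' processed.  Quality scores are ignored.
#'
#' @param fastq character vector of FASTQ(.gz) paths, named by sample id
#'   (unnamed: basename without extension).
#' @param library a \linkS4class{BarcodeLibrary}.
#' @param cfg an \linkS4class{ExtractionConfig}.
#' @param sampleSheet optional \linkS4class{SampleSheet}; matched rows are
#'   attached to \code{colData}.
#' @param chunkSize records per streaming chunk.
#' @return a \linkS4class{BarcodeCounts}.
#' @export
countFastq <- function(fastq, library, cfg = ExtractionConfig(),
                       sampleSheet = NULL, chunkSize = 200000L) {
  if (is.null(names(fastq))) {
    names(fastq) <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
  }
  if (anyDuplicated(names(fastq))) stop("duplicate sample ids in fastq names")
  ids <- barcodeIds(library)
  mat <- matrix(0L, nrow = length(ids), ncol = length(fastq),
                dimnames = list(ids, names(fastq)))
  amb <- una <- integer(length(fastq))
  for (s in seq_along(fastq)) {
    path <- fastq[s]
    if (!file.exists(path)) stop("FASTQ not found: ", path)
    con <- if (grepl("\\.gz$", path)) gzfile(path, open = "rt") else {
      file(path, open = "rt")
    }
    nseen <- 0L
    repeat {
      lines <- tryCatch(readLines(con, n = 4L * chunkSize),
                        error = function(e) {
                          close(con)
                          stop("cannot read FASTQ '", path, "': ",
                               conditionMessage(e), call. = FALSE)
                        })
      if (length(lines) == 0L) break
      ## structural validation of the 4-line records
      bad <- length(lines) %% 4L != 0L
      if (!bad) {
        hdr <- lines[seq(1L, length(lines), by = 4L)]
        plus <- lines[seq(3L, length(lines), by = 4L)]
        firstBad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
        bad <- length(firstBad) > 0L
      } else firstBad <- length(lines) %/% 4L + 1L
      if (bad) {
        close(con)
        stop("malformed FASTQ '", path, "' at record ",
             nseen + firstBad[1L], call. = FALSE)
      }
      chunk <- Biostrings::DNAStringSet(lines[seq(2L, length(lines),
                                                  by = 4L)])
      tal <- .countChunk(chunk, library, cfg)
      mat[, s] <- mat[, s] + tal$counts
      amb[s] <- amb[s] + tal$ambiguous
      una[s] <- una[s] + tal$unassigned
      nseen <- nseen + length(chunk)
      if (length(chunk) < chunkSize) break
    }
    close(con)
    if (nseen == 0L) {
      warning("empty FASTQ for sample '", names(fastq)[s], "': ", path)
    }
    tot <- sum(mat[, s]) + amb[s] + una[s]
    .msg("sample %s: %d reads, %d assigned (%.2f%%), %d ambiguous, %d unassigned",
         names(fastq)[s], tot, sum(mat[, s]),
         if (tot > 0) 100 * sum(mat[, s]) / tot else 0, amb[s], una[s])
  }
  BarcodeCounts(mat, library = library, sampleData = sampleSheet,
                ambiguous = amb, unassigned = una)
}
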