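# Shared fixtures and independent oracles.  Oracles re-derive results by
# brute force (sliding-window Hamming scan, exhaustive distance scan, hand
# arithmetic) and never call the code paths they check.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

# Minimal panel annotation around a library, with uniform sim parameters.
toyPanel <- function(lib, doubling = 0.8, ec50 = 1, hill = 1, residual = 0,
                     koCost = 0.1, editFrac = 0.9, cas9 = 0.9) {
  spk <- isSpikein(lib)
  PanelAnnotation(data.frame(
    cell_line_id = cellLineIds(lib), lineage = "lung",
    genotype_flags = ifelse(spk, "spikein", "none"),
    cas9_efficiency = ifelse(spk, NA_real_, cas9),
    is_spikein = spk,
    doubling_rate = doubling, ec50 = ec50, hill = hill, residual = residual,
    ko_cost = ifelse(spk, 0, koCost), edit_frac = ifelse(spk, 0, editFrac)))
}

# Minimal sample sheet with sequential dummy indexes.
toySheet <- function(df) {
  idx <- vapply(seq_len(nrow(df)), function(i) {
    paste(c("A", "C", "G", "T")[1 + (i %/% 4^(0:7)) %% 4], collapse = "")
  }, character(1))
  df$i5_index <- idx
  df$i7_index <- rev(idx)
  if (is.null(df$dose)) df$dose <- 0
  df$sample_id <- sprintf("S%02d", seq_len(nrow(df)))
  SampleSheet(df)
}

# Brute-force Hamming distance between two equal-length strings.
hammingOracle <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Hand trapezoid over log10 dose, normalized by the log10 range.
handTrapezoidAUC <- function(doses, rv) {
  x <- log10(doses)
  rv <- pmin(pmax(rv, 0), 1)
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    total <- total + (x[i + 1] - x[i]) * (rv[i] + rv[i + 1]) / 2
  }
  total / (x[length(x)] - x[1])
}

# Product-moment Pearson r and OLS fit from explicit sums.
pearsonHand <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  list(r = sxy / sqrt(sxx * syy), slope = sxy / sxx,
       intercept = mean(y) - (sxy / sxx) * mean(x))
}

# Naive per-read FASTQ counter: plain-text parsing, sliding-window anchor
# scan, exhaustive library distance scan.  Mirrors the documented per-read
# rules only (leftmost minimal-mismatch anchor; exact match wins; unique
# minimal Hamming neighbour within k; ties ambiguous).
bruteCountFastq <- function(path, lib, anchor = "ACAACAAGCACCGGGATAAG",
                            anchorMaxMM = 2L, k = 2L, window = c(0L, 150L)) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  libSeq <- as.character(barcodeSequences(lib))
  ids <- barcodeIds(lib)
  libRaw <- lapply(libSeq, charToRaw)
  anchorRaw <- charToRaw(anchor)
  alen <- length(anchorRaw)
  counts <- setNames(integer(length(ids)), ids)
  ambiguous <- 0L
  unassigned <- 0L
  for (rd in seqs) {
    L <- nchar(rd)
    lastStart <- min(L, window[2L]) - alen + 1L
    call <- "unassigned"
    if (lastStart >= window[1L] + 1L) {
      best <- NA_integer_
      bestMM <- anchorMaxMM + 1L
      for (p in seq(window[1L] + 1L, lastStart)) {
        mmc <- sum(charToRaw(substr(rd, p, p + alen - 1L)) != anchorRaw)
        if (mmc < bestMM) {
          bestMM <- mmc
          best <- p
          if (mmc == 0L) break
        }
      }
      if (!is.na(best)) {
        bcStart <- best + alen
        if (bcStart + 25L <= L) {
          obs <- charToRaw(substr(rd, bcStart, bcStart + 25L))
          d <- vapply(libRaw, function(b) sum(b != obs), integer(1))
          dmin <- min(d)
          if (dmin <= k) {
            call <- if (sum(d == dmin) > 1L) "ambiguous" else ids[which.min(d)]
          }
        }
      }
    }
    if (call == "ambiguous") ambiguous <- ambiguous + 1L
    else if (call == "unassigned") unassigned <- unassigned + 1L
    else counts[call] <- counts[call] + 1L
  }
  list(counts = counts, ambiguous = ambiguous, unassigned = unassigned)
}

# All sequences within Hamming distance <= k of x (k in {1, 2}).
perturbations <- function(x, k) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(x)
  out <- character(0)
  subs1 <- function(s) {
    res <- character(0)
    for (p in seq_len(L)) {
      for (b in setdiff(bases, substr(s, p, p))) {
        v <- s
        substr(v, p, p) <- b
        res <- c(res, v)
      }
    }
    res
  }
  d1 <- subs1(x)
  out <- d1
  if (k >= 2L) {
    for (p1 in seq_len(L - 1L)) {
      for (b1 in setdiff(bases, substr(x, p1, p1))) {
        v1 <- x
        substr(v1, p1, p1) <- b1
        for (p2 in seq(p1 + 1L, L)) {
          for (b2 in setdiff(bases, substr(x, p2, p2))) {
            v2 <- v1
            substr(v2, p2, p2) <- b2
            out <- c(out, v2)
          }
        }
      }
    }
  }
  unique(out)
}
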