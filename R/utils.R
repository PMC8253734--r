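# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom withr with_seed
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## Derive a stream-specific child seed; kept below 2^31.
.childSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset) %% 1009L
}

## Character matrix (n x width) from equal-length sequences.
.seqMatrix <- function(seqs) {
  seqs <- as.character(seqs)
  if (length(seqs) == 0L) return(matrix(character(0), nrow = 0L))
  w <- unique(nchar(seqs))
  stopifnot(length(w) == 1L)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = w, byrow = TRUE)
}

## All-pairs Hamming distances between two sets of equal-length sequences.
.hammingCross <- function(a, b) {
  am <- .seqMatrix(a)
  bm <- .seqMatrix(b)
  d <- matrix(0L, nrow = nrow(am), ncol = nrow(bm))
  for (j in seq_len(ncol(am))) {
    d <- d + outer(am[, j], bm[, j], "!=")
  }
  storage.mode(d) <- "integer"
  rownames(d) <- names(a)
  colnames(d) <- names(b)
  d
}

## Minimum pairwise Hamming distance and the closest pair, brute force.
.minPairwiseHamming <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(list(min = Inf, pair = c(NA_character_, NA_character_)))
  d <- .hammingCross(seqs, seqs)
  diag(d) <- NA_integer_
  idx <- sort(which(d == min(d, na.rm = TRUE), arr.ind = TRUE)[1L, ])
  nm <- names(seqs)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  list(min = min(d, na.rm = TRUE), pair = c(nm[idx[1L]], nm[idx[2L]]))
}

## Atomic table writer: temp file in the target directory, then rename.
## First line is a schema comment so outputs are self-describing.
.writeTableAtomic <- function(df, path, schema) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wt")
  writeLines(sprintf("# prismscreen schema v1: %s", schema), con)
  utils::write.table(df, con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  close(con)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

.readTable <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "")
  miss <- setdiff(required, colnames(df))
  if (length(miss) > 0L) {
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

.msg <- function(...) message("[prismscreen] ", sprintf(...))
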