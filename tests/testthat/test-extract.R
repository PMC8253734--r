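# Anchor search, Hamming assignment, FASTQ counting.

test_that("anchor search honors mismatch tolerance and leftmost rule", {
  cfg <- ExtractionConfig()
  anchor <- cfg@anchorFwd

  expect_identical(findAnchor(paste0(anchor, strrep("A", 26), "GGTT"), cfg),
                   20L)

  # two substitutions still found; position verified by a sliding oracle
  mut <- anchor
  substr(mut, 3, 3) <- "T"
  substr(mut, 18, 18) <- "C"
  read <- paste0("CCGGT", mut, strrep("A", 30))
  expect_identical(hammingOracle(substr(read, 6, 25), anchor), 2L)
  expect_identical(findAnchor(read, cfg), 25L)

  # beyond tolerance: not found
  mut3 <- mut
  substr(mut3, 10, 10) <- "C"
  expect_identical(hammingOracle(mut3, anchor), 3L)
  expect_true(is.na(findAnchor(paste0("CCGGT", mut3, strrep("T", 30)), cfg)))

  # a random read without the anchor
  set.seed(1)
  rnd <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
               collapse = "")
  expect_true(is.na(findAnchor(rnd, cfg)))

  # leftmost wins among equal-mismatch occurrences
  double <- paste0(anchor, anchor, strrep("T", 40))
  expect_identical(findAnchor(double, cfg), 20L)

  # anchors outside the search window are invisible
  far <- paste0(strrep("T", 200), anchor, strrep("A", 30))
  expect_true(is.na(findAnchor(far, cfg)))
  cfgWide <- ExtractionConfig(searchWindow = c(0L, 260L))
  expect_identical(findAnchor(far, cfgWide), 220L)
})

test_that("barcode assignment resolves exact, near, tied and distant cases", {
  lib <- designLibrary(30, 0, seed = 13)
  seqs <- as.character(barcodeSequences(lib))

  expect_identical(assignBarcode(seqs[4], lib), barcodeIds(lib)[4])

  # distance-1 neighbour goes to the unique closest entry (oracle-verified)
  v <- seqs[7]
  substr(v, 12, 12) <- setdiff(c("A", "C", "G", "T"), substr(v, 12, 12))[1]
  d <- vapply(seqs, hammingOracle, integer(1), a = v)
  expect_identical(unname(which(d == min(d))), 7L)
  expect_identical(assignBarcode(v, lib), barcodeIds(lib)[7])

  # constructed equidistant tie (d = 2 to both) is ambiguous
  s1 <- paste0(strrep("AC", 10L), "GGGTTT")
  s2 <- s1
  substr(s2, 1, 4) <- "GGGG"                     # distance 4 from s1
  tieLib <- BarcodeLibrary(c("T1", "T2"), c(s1, s2), c("L1", "L2"),
                           kAssign = 1L)
  obs <- s1
  substr(obs, 1, 2) <- "GG"                      # 2 from s1, 2 from s2
  expect_identical(hammingOracle(obs, s1), 2L)
  expect_identical(hammingOracle(obs, s2), 2L)
  expect_identical(assignBarcode(obs, tieLib, kAssign = 2L), "ambiguous")

  # beyond the radius, or malformed: unassigned
  far <- seqs[1]
  substr(far, 1, 3) <- c("TTT")
  d1 <- min(vapply(seqs, hammingOracle, integer(1), a = far))
  if (d1 > 2) expect_identical(assignBarcode(far, lib), "unassigned")
  expect_identical(assignBarcode(substr(seqs[1], 1, 25), lib), "unassigned")
  expect_identical(assignBarcode(sub("A", "N", seqs[1]), lib), "unassigned")
})

test_that("no misassignment under <= k errors with distance floor 2k+1", {
  lib <- designLibrary(25, 0, seed = 17, kAssign = 2L)
  target <- as.character(barcodeSequences(lib))[1]
  variants <- perturbations(target, 2L)
  expect_length(variants, 26 * 3 + choose(26, 2) * 9)
  calls <- assignBarcode(variants, lib, kAssign = 2L)
  expect_true(all(calls == barcodeIds(lib)[1]))
})

test_that("counting is conservative, logged and robust to edge inputs", {
  lib <- designLibrary(5, 0, seed = 23)
  pan <- toyPanel(lib)
  pool <- seedPool(pan)
  dir <- withr::local_tempdir()

  # clean sample: 100% assignment
  fq <- file.path(dir, "clean.fastq.gz")
  res <- simulateReads(pool, lib, depth = 2000, path = fq, perBaseError = 0,
                       junkFraction = 0, seed = 2)
  cnt <- quietly(countFastq(c(clean = fq), lib))
  expect_identical(unname(colData(cnt)$unassigned), 0L)
  expect_identical(unname(colData(cnt)$ambiguous), 0L)
  expect_equal(assay(cnt, "counts")[, 1], res$truth[rownames(cnt)],
               ignore_attr = TRUE)

  # with errors: conservation holds, nearly all anchor-bearing reads assigned
  fq2 <- file.path(dir, "err.fastq.gz")
  res2 <- simulateReads(pool, lib, depth = 10000, path = fq2,
                        perBaseError = 0.001, junkFraction = 0.01, seed = 3)
  cnt2 <- quietly(countFastq(c(err = fq2), lib))
  cd <- colData(cnt2)
  expect_equal(unname(sum(assay(cnt2, "counts")) + cd$ambiguous +
                        cd$unassigned), 10000)
  nAnchored <- 10000 - res2$junk
  expect_gte(sum(assay(cnt2, "counts")), 0.99 * nAnchored)

  # empty FASTQ: zero column plus a warning
  empty <- file.path(dir, "empty.fastq")
  file.create(empty)
  expect_warning(cnt3 <- suppressMessages(countFastq(c(none = empty), lib)),
                 "empty FASTQ")
  expect_true(all(assay(cnt3, "counts") == 0))

  # malformed FASTQ: hard error naming the file
  badfq <- file.path(dir, "bad.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), badfq)
  expect_error(quietly(countFastq(c(bad = badfq), lib)), "bad.fastq")
})

test_that("reverse-complement scanning recovers flipped reads", {
  lib <- designLibrary(4, 0, seed = 29)
  pan <- toyPanel(lib)
  pool <- seedPool(pan)
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "fwd.fastq")
  res <- simulateReads(pool, lib, depth = 400, path = fq, perBaseError = 0,
                       junkFraction = 0, seed = 4)
  # reverse-complement every read
  lines <- readLines(fq)
  ii <- seq(2, length(lines), by = 4)
  lines[ii] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(lines[ii])))
  rcfq <- file.path(dir, "rc.fastq")
  writeLines(lines, rcfq)
  plain <- quietly(countFastq(c(s = rcfq), lib))
  expect_identical(sum(assay(plain, "counts")), 0L)
  rc <- quietly(countFastq(c(s = rcfq), lib,
                           cfg = ExtractionConfig(scanRevComp = TRUE)))
  expect_equal(assay(rc, "counts")[, 1], res$truth[rownames(rc)],
               ignore_attr = TRUE)
})

test_that("streaming counting matches the naive per-read oracle exactly", {
  lib <- designLibrary(12, 0, seed = 37)
  pan <- toyPanel(lib)
  pool <- seedPool(pan)
  fq <- file.path(withr::local_tempdir(), "oracle.fastq")
  simulateReads(pool, lib, depth = 2000, path = fq, perBaseError = 0.005,
                junkFraction = 0.05, seed = 8)
  cnt <- quietly(countFastq(c(s = fq), lib, chunkSize = 512L))
  oracle <- bruteCountFastq(fq, lib)
  expect_equal(assay(cnt, "counts")[, 1], oracle$counts[rownames(cnt)],
               ignore_attr = TRUE)
  expect_identical(unname(colData(cnt)$ambiguous), oracle$ambiguous)
  expect_identical(unname(colData(cnt)$unassigned), oracle$unassigned)
})
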