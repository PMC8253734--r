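# Generative model: library design, pool growth, dilution pool, amplicon
# geometry, read emission.

test_that("designed libraries satisfy composition and distance constraints", {
  lib <- designLibrary(40, 2, seed = 3)
  expect_length(lib, 42L)
  seqs <- as.character(barcodeSequences(lib))
  gc <- vapply(seqs, function(s) nchar(gsub("[AT]", "", s)) / 26, numeric(1))
  expect_true(all(gc >= 0.40 & gc <= 0.60))
  expect_false(any(grepl("A{5}|C{5}|G{5}|T{5}", seqs)))
  # brute-force all-pairs scan, independent of the package's distance code
  dmin <- 26L
  for (i in seq_along(seqs)[-1]) {
    for (j in seq_len(i - 1L)) {
      dmin <- min(dmin, hammingOracle(seqs[i], seqs[j]))
    }
  }
  expect_gte(dmin, 5L)
  expect_identical(sum(isSpikein(lib)), 2L)
  # determinism
  lib2 <- designLibrary(40, 2, seed = 3)
  expect_identical(as.character(barcodeSequences(lib2)), seqs)
  expect_s4_class(designLibrary(1, 0, seed = 7), "BarcodeLibrary")
})

test_that("pool growth follows the stated compound and CRISPR kinetics", {
  lib <- designLibrary(3, 0, seed = 9)
  pan <- toyPanel(lib, doubling = 1, ec50 = 2, hill = 1, residual = 0,
                  koCost = 0.4, editFrac = 0.8)
  pool0 <- seedPool(PanelAnnotation(as.data.frame(pan)), cellsPerLine = 100)

  # zero dose: pure exponential growth
  g0 <- simulatePoolGrowth(pan, pool0, "compound", "DMSO", dose = 0, t = 5,
                           noise = FALSE)
  expect_equal(unname(cellNumbers(g0)), rep(100 * 2^5, 3))

  # d = EC50, h = 1, b = 0, g = 1, t = 5: N = N0 * 32 * 0.5 = 16 N0
  g1 <- simulatePoolGrowth(pan, pool0, "compound", "drugX", dose = 2, t = 5,
                           noise = FALSE)
  expect_equal(unname(cellNumbers(g1)), rep(1600, 3))

  # no fitness cost (delta = 0) with full editing equals the sgNT expectation
  panNull <- toyPanel(lib, doubling = 1, koCost = 0, editFrac = 1)
  gT <- simulatePoolGrowth(panNull, pool0, "crispr", "sgTARGET", t = 5,
                           noise = FALSE)
  gNT <- simulatePoolGrowth(panNull, pool0, "crispr", "sgNT", t = 5,
                            noise = FALSE)
  expect_equal(cellNumbers(gT), cellNumbers(gNT))

  # CRISPR mixture formula, directly evaluated
  gK <- simulatePoolGrowth(pan, pool0, "crispr", "sgTARGET", t = 5,
                           noise = FALSE)
  expected <- 100 * (0.2 * 2^5 + 0.8 * 2^(1 * 0.6 * 5))
  expect_equal(unname(cellNumbers(gK)), rep(expected, 3))

  expect_error(simulatePoolGrowth(pan, pool0, "compound", "drugX",
                                  dose = 1, t = -1), "negative")
})

test_that("viability is monotone non-increasing in dose", {
  doses <- sort(c(0, 10^seq(-3, 2, length.out = 40)))
  for (h in c(0.5, 1, 2, 4)) {
    v <- doseViability(doses, ec50 = 0.7, hill = h, residual = 0.1)
    expect_true(all(diff(v) <= 1e-12))
    expect_equal(v[1], 1)
  }
})

test_that("dilution pool fractions follow equal-volume mixing", {
  lib <- designLibrary(20, 0, seed = 21)
  pool <- makeDilutionPool(lib)
  # arithmetic oracle: tier c fraction = c / (4 * 111.11)
  expect_equal(pool$designed_fraction[1], 100 / (4 * 111.11),
               tolerance = 1e-12)
  expect_equal(pool$designed_fraction[20], 0.01 / (4 * 111.11),
               tolerance = 1e-12)
  expect_equal(sum(pool$designed_fraction), 1, tolerance = 1e-12)
  expect_equal(max(pool$designed_fraction) / min(pool$designed_fraction),
               1e4)
  expect_error(makeDilutionPool(lib[1:10]), "exactly 20")
})

test_that("amplicon template matches the printed product geometry", {
  tpl <- ampliconTemplate()
  expect_identical(nchar(tpl@firstProduct), 550L)
  expect_identical(nchar(tpl@secondProduct), 332L)
  expect_match(tpl@secondProduct, "ACAACAAGCACCGGGATAAG")
  # barcode slot is 26 nt and abuts the forward anchor
  slotPos <- regexpr("N+", tpl@secondProduct)
  expect_identical(attr(slotPos, "match.length"), 26L)
  anchorEnd <- regexpr("ACAACAAGCACCGGGATAAG", tpl@secondProduct) + 20L
  expect_identical(as.integer(slotPos), as.integer(anchorEnd))
  # anchor ends at least 30 nt before position 150 (short-read mode safe)
  expect_lte(as.integer(anchorEnd) - 1L, 120L)
  # reverse universal primer site present in the first product
  rcRev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("AGGAACTGCTTCCTTCACGA")))
  expect_match(tpl@firstProduct, rcRev)
})

test_that("read emission conserves depth, embeds barcodes and is seeded", {
  lib <- designLibrary(2, 0, seed = 31)
  cells <- setNames(c(9000, 1000), cellLineIds(lib))
  pool <- PoolState(cells)
  dir <- withr::local_tempdir()

  # error-free single line: every read carries its exact barcode
  one <- PoolState(setNames(1000, cellLineIds(lib)[1]))
  fq1 <- file.path(dir, "one.fastq")
  simulateReads(one, lib[1], depth = 200, path = fq1, perBaseError = 0,
                junkFraction = 0, seed = 5)
  reads <- readLines(fq1)[seq(2, 800, by = 4)]
  expect_length(reads, 200L)
  expect_true(all(grepl(as.character(barcodeSequences(lib))[1], reads,
                        fixed = TRUE)))

  # conservation and truth accounting at nonzero junk
  fq2 <- file.path(dir, "two.fastq")
  res <- simulateReads(pool, lib, depth = 5000, path = fq2,
                       perBaseError = 0.001, junkFraction = 0.01, seed = 6)
  expect_identical(sum(res$truth) + res$junk, 5000L)
  expect_identical(length(readLines(fq2)) %/% 4L, 5000L)

  # 9:1 mixing recovered within a binomial 99% CI
  p <- res$truth[1] / sum(res$truth)
  ci <- qnorm(c(0.005, 0.995), mean = 0.9,
              sd = sqrt(0.9 * 0.1 / sum(res$truth)))
  expect_gt(p, ci[1])
  expect_lt(p, ci[2])

  # junk volume ~ Binomial(depth, 0.01): +/- 4 sd around 1% of 2e4
  res3 <- simulateReads(pool, lib, depth = 20000,
                        path = file.path(dir, "three.fastq"),
                        perBaseError = 0, junkFraction = 0.01, seed = 7)
  expect_lt(abs(res3$junk - 200), 4 * sqrt(20000 * 0.01 * 0.99))

  # byte-identical FASTQ for identical seeds
  fqA <- file.path(dir, "a.fastq")
  fqB <- file.path(dir, "b.fastq")
  simulateReads(pool, lib, depth = 1000, path = fqA, seed = 42)
  simulateReads(pool, lib, depth = 1000, path = fqB, seed = 42)
  expect_identical(readLines(fqA), readLines(fqB))

  expect_error(simulateReads(PoolState(setNames(10, "ghost")), lib,
                             depth = 10, path = file.path(dir, "x.fastq")),
               "empty pool")
})
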