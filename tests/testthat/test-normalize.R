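# Fractions, spike-in/CTG adjustment, control anchoring.

# Counts object with an explicit sheet, built without reads.
makeCounts <- function(cnt, lib, sheetDF) {
  BarcodeCounts(cnt, library = lib, sampleData = as.data.frame(toySheet(sheetDF)))
}

test_that("fractions follow the pseudocount formula and sum to one", {
  lib <- designLibrary(3, 1, seed = 41)
  cnt <- matrix(c(10, 30, 60, 100,
                  0, 0, 100, 50), ncol = 2,
                dimnames = list(barcodeIds(lib), c("s1", "s2")))
  bc <- BarcodeCounts(cnt, library = lib)

  f0 <- assay(barcodeFractions(bc, pseudocount = 0), "fraction")
  expect_equal(unname(f0[1:3, 1]), c(10, 30, 60) / 200)

  f <- assay(barcodeFractions(bc, pseudocount = 0.5), "fraction")
  # arithmetic oracle on {0, 0, 100} with pseudocount 0.5 (plus the 4th row)
  expect_equal(unname(f[1:3, 2]), c(0.5, 0.5, 100.5) / 152)
  expect_true(all(abs(colSums(f) - 1) < 1e-12))

  lc <- assay(barcodeFractions(bc), "low_count")
  expect_identical(unname(lc[, 2]), c(TRUE, TRUE, FALSE, FALSE))

  zero <- BarcodeCounts(matrix(0, 2, 1,
                               dimnames = list(barcodeIds(lib)[1:2], "dead")),
                        library = lib[1:2])
  expect_error(barcodeFractions(zero), "dead")
})

test_that("spike-in adjustment divides by the viability-corrected reference", {
  lib <- designLibrary(3, 1, seed = 43)
  spikeId <- barcodeIds(lib)[isSpikein(lib)]
  sheet <- data.frame(arm_type = "compound",
                      agent = c("DMSO", "drugX"),
                      dose = c(0, 3), timepoint = 5, replicate = 1L,
                      is_control = c(TRUE, FALSE))
  # fractions chosen directly: f[spike] = 0.02, line 1 at 0.01
  cnt <- matrix(c(10, 790, 180, 20,
                  10, 790, 180, 20) * 100, ncol = 2,
                dimnames = list(c(barcodeIds(lib)[!isSpikein(lib)], spikeId),
                                c("S01", "S02")))
  bc <- makeCounts(cnt, lib, sheet)
  bc <- barcodeFractions(bc, pseudocount = 0)

  # unit fitness: A = f / f_spike
  ctg1 <- CTGFitness(data.frame(line_id = cellLineIds(lib)[isSpikein(lib)],
                                agent = "drugX", dose = 3, fitness = 1))
  A1 <- assay(quietly(spikeinAdjust(bc, ctg1)), "abundance")
  expect_equal(unname(A1[1, ]), c(0.5, 0.5))

  # drug kills the spike-in to 40%: r = 0.02 / 0.4 = 0.05, A = f / r
  ctg2 <- CTGFitness(data.frame(line_id = cellLineIds(lib)[isSpikein(lib)],
                                agent = "drugX", dose = 3, fitness = 0.4))
  A2 <- assay(quietly(spikeinAdjust(bc, ctg2)), "abundance")
  expect_equal(unname(A2[1, 2]), 0.01 / 0.05)   # treated sample corrected
  expect_equal(unname(A2[1, 1]), 0.5)           # control untouched (v = 1)

  # missing CTG defaults to fitness 1 with a warning
  expect_warning(spikeinAdjust(bc, NULL), "assuming fitness 1")
})

test_that("two identical spike-ins give the same reference as one", {
  lib <- designLibrary(2, 2, seed = 47)
  sheet <- data.frame(arm_type = "compound", agent = "DMSO", dose = 0,
                      timepoint = 5, replicate = 1L, is_control = TRUE)
  cnt <- matrix(c(600, 200, 100, 100), ncol = 1,
                dimnames = list(barcodeIds(lib), "S01"))
  bc <- makeCounts(cnt, lib, sheet)
  bc <- barcodeFractions(bc, pseudocount = 0)
  A <- assay(quietly(spikeinAdjust(bc)), "abundance")
  expect_equal(unname(A[1, 1]), 0.6 / 0.1)
  # spike-ins sit at their own fitness (1 here) by construction
  expect_equal(unname(A[3:4, 1]), c(1, 1))
})

test_that("control anchoring uses the stratum median and flags depletion", {
  lib <- designLibrary(2, 1, seed = 53)
  sheet <- data.frame(
    arm_type = "compound",
    agent = c("DMSO", "DMSO", "DMSO", "drugX"),
    dose = c(0, 0, 0, 3), timepoint = 5,
    replicate = c(1L, 2L, 3L, 1L),
    is_control = c(TRUE, TRUE, TRUE, FALSE))
  # counts tuned so line 1's control abundances are {0.39, 0.40, 0.41}
  # relative to a constant spike-in fraction of 0.5
  spike <- 5000
  mk <- function(a) round(c(a * spike, (1 - a) * spike, spike))
  cnt <- cbind(mk(0.39), mk(0.40), mk(0.41), mk(0.2))
  dimnames(cnt) <- list(barcodeIds(lib), sprintf("S%02d", 1:4))
  bc <- makeCounts(cnt, lib, sheet)
  bc <- barcodeFractions(bc, pseudocount = 0)
  bc <- quietly(spikeinAdjust(bc))
  rv <- assay(controlNormalize(bc), "rv")
  expect_equal(unname(rv[1, 4]), 0.2 / 0.40, tolerance = 1e-6)
  # controls sit near 1 against their own stratum median
  expect_equal(unname(rv[1, 2]), 1, tolerance = 1e-6)

  # treated equals control: RV exactly 1
  cnt2 <- cbind(mk(0.4 / 2), mk(0.4 / 2), mk(0.4 / 2), mk(0.4 / 2))
  dimnames(cnt2) <- dimnames(cnt)
  bc2 <- makeCounts(cnt2, lib, sheet)
  bc2 <- quietly(controlNormalize(spikeinAdjust(
    barcodeFractions(bc2, pseudocount = 0))))
  expect_equal(unname(assay(bc2, "rv")[1, 4]), 1)

  # missing control stratum is a hard error naming the sample
  sheetNoCtrl <- sheet
  sheetNoCtrl$is_control <- FALSE
  bc3 <- makeCounts(cnt, lib, sheetNoCtrl)
  bc3 <- quietly(spikeinAdjust(barcodeFractions(bc3, pseudocount = 0)))
  expect_error(controlNormalize(bc3), "no matched control")
})

test_that("normalization is invariant to per-sample scaling", {
  lib <- designLibrary(4, 1, seed = 59)
  sheet <- data.frame(arm_type = "compound",
                      agent = c("DMSO", "drugX"), dose = c(0, 1),
                      timepoint = 5, replicate = 1L,
                      is_control = c(TRUE, FALSE))
  cnt <- matrix(c(50, 100, 150, 200, 500,
                  40, 90, 160, 210, 510), ncol = 2,
                dimnames = list(barcodeIds(lib), c("S01", "S02")))
  scaled <- cnt %*% diag(c(3, 7))
  dimnames(scaled) <- dimnames(cnt)
  norm <- function(m) {
    bc <- makeCounts(m, lib, sheet)
    quietly(controlNormalize(spikeinAdjust(
      barcodeFractions(bc, pseudocount = 0))))
  }
  expect_equal(assay(norm(cnt), "rv"), assay(norm(scaled), "rv"))
})

test_that("spike-in correction keeps untouched lines at RV 1 and the
           noise-free pipeline reproduces planted viabilities exactly", {
  lib <- designLibrary(6, 2, seed = 61)
  ec50 <- c(0.2, 0.5, 1, 2, 5, 1000)
  pan <- PanelAnnotation(data.frame(
    cell_line_id = cellLineIds(lib), lineage = "lung",
    genotype_flags = "none",
    cas9_efficiency = ifelse(isSpikein(lib), NA, 0.9),
    is_spikein = isSpikein(lib),
    doubling_rate = c(0.6, 0.7, 0.8, 0.9, 1.0, 0.75, 0.9, 0.9),
    ec50 = c(ec50, 3, 3), hill = 1.5, residual = 0.05,
    ko_cost = 0, edit_frac = 0))
  dose <- 3
  pool0 <- seedPool(pan)
  ctrl <- simulatePoolGrowth(pan, pool0, "compound", "DMSO", 0, t = 5,
                             noise = FALSE)
  trt <- simulatePoolGrowth(pan, pool0, "compound", "drugX", dose, t = 5,
                            noise = FALSE)
  # exact expected cells as "counts": the chain is scale-free
  cnt <- cbind(S01 = cellNumbers(ctrl)[cellLineIds(lib)],
               S02 = cellNumbers(trt)[cellLineIds(lib)])
  rownames(cnt) <- barcodeIds(lib)
  sheet <- data.frame(arm_type = "compound", agent = c("DMSO", "drugX"),
                      dose = c(0, dose), timepoint = 5, replicate = 1L,
                      is_control = c(TRUE, FALSE))
  bc <- makeCounts(cnt, lib, sheet)
  # CTG table holds the spike-in's true viability under the drug
  spk <- as.data.frame(pan)[isSpikein(lib), ]
  ctg <- CTGFitness(data.frame(
    line_id = spk$cell_line_id, agent = "drugX", dose = dose,
    fitness = doseViability(dose, spk$ec50, spk$hill, spk$residual)))
  bc <- quietly(controlNormalize(spikeinAdjust(
    barcodeFractions(bc, pseudocount = 0), ctg)))
  rv <- assay(bc, "rv")[, "S02"]
  truthV <- doseViability(dose, ec50, 1.5, 0.05)
  expect_equal(unname(rv[1:6]), truthV, tolerance = 1e-6)
  # the insensitive line (ec50 = 1000) stays at RV ~ 1 even though the
  # spike-in itself was killed to ~54% - the purpose of the CTG adjustment
  expect_equal(unname(rv[6]), truthV[6], tolerance = 1e-6)
  expect_gt(truthV[6], 0.999)
})
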