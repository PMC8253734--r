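# prismscreen

Simulation, barcode counting, normalization and scoring for **pooled
barcoded cell-line screens** (PRISM-style): hundreds of cancer cell lines,
each tagged with a unique 26-bp DNA barcode, are cultured as one pool,
perturbed with compounds or CRISPR knockouts, and deconvolved by amplicon
sequencing.  The package is aimed at screen analysts and method developers
who need a fully testable, end-to-end reference implementation of such a
platform's data processing — including a generative simulator, so every
step can be validated without any proprietary screen data.

## What it computes

For line *i* with doubling rate *g*, the simulator grows pools as

- compound arm: `N(t) = N(0) * 2^(g*t) * V(d)` with
  `V(d) = b + (1 - b) / (1 + (d/EC50)^h)`;
- CRISPR arm: `N(t) = N(0) * [(1-e) * 2^(g*t) + e * 2^(g*(1-delta)*t)]`
  (editing fraction *e*, knockout fitness cost *delta*; sgNT/sgNC have
  *delta* = 0),

emits the 332-bp dual-indexed amplicon (nested in the 550-bp first-PCR
product) as FASTQ with substitution errors, then the analysis side:

- **count**: anchor on the forward universal primer (≤ 2 mismatches,
  leftmost), slice the 26-mer, assign to the unique library barcode within
  Hamming radius *k* (library min pairwise distance ≥ 2k+1 guarantees
  unambiguity);
- **normalize**: fractions (pseudocount 0.5) → divide by the spike-in
  reference corrected by the spike-in's CTG viability `v` under the same
  condition (`r = f_spike / v`) → relative viability `RV` against the
  median of matched DMSO/sgNT controls;
- **score**: dose-response `AUC` = trapezoid of clipped RV over
  `log10(dose)`, normalized by the log-dose range (1 = insensitive,
  0 = killed; dose 0 excluded as the anchor); CRISPR dependency =
  mean over targeting sgRNAs of `log2 RV`, with an sgNC DNA-damage flag;
  t test / one-way ANOVA group comparison; OLS + Pearson r;
- **qc**: Cas9 gate (strictly > 85% editing), dilution-series linearity
  (count-floor detection, log-log fit), replicate concordance.

## Worked example

The dilution-series validation: 20 barcodes in five tiers
(100/10/1/0.1/0.01 ng/µl, four barcodes per tier, equal-volume mixing — a
10,000-fold designed abundance range), sequenced at 1e6 reads with 0.1%
per-base error, counted and checked for linearity:

```r
library(prismscreen)
b <- runDemo("dilution", outdir = "demo_out", seed = 1)
#> [prismscreen] sample dilution: 1000000 reads, 990013 assigned (99.00%),
#>               0 ambiguous, 9987 unassigned
b$linearity
#> LinearityReport: 20/20 detected (>= 10 reads); slope 1.0050, r 0.9998,
#>                  dynamic range 1e+04-fold
```

All 20 barcodes clear the 10-read detection floor (the ~1% unassigned
reads are the simulated anchor-less junk standing in for PhiX), the
log-log regression of estimated on designed fractions has slope ≈ 1, and
the detected dynamic range spans the full 10,000-fold design.

Scoring primitives work standalone:

```r
aucDoseResponse(c(0.1, 0.3, 1, 3, 10), c(1, 1, 0.5, 0, 0))
#> 0.4942803
pearsonFit(c(1, 2, 3, 4), c(2, 1, 4, 3))$r
#> 0.6
```

Two richer scenarios chain the whole pipeline — `"focused_egfr"` (20-line
panel, 3 planted drug/knockout-sensitive lines, a spike-in killed at the
top doses to exercise the CTG correction) and `"full_kras"` (368 lines
split 17/61/290 by genotype with sensitivity planted only in the 17-line
group); each writes counts, abundances, AUC/dependency tables, QC and a
markdown report under `outdir`.  `inst/scripts/prism.R` exposes
`count / normalize / score / qc / demo` subcommands for shell use.

## Acceptance script

`scripts/acceptance.R` rebuilds the dilution pool from scratch (library
design → equal-volume tier mixing → 1e6 simulated reads at 0.1% error →
counting at k = 2 → detection at ≥ 10 reads) and reports the detected
dynamic range (`t1`, fold) and the number of barcodes detected (`t2`):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — S4 classes (`BarcodeLibrary`, `BarcodeCounts` extending
  `SummarizedExperiment`, …), simulator, extraction, normalization,
  scoring, QC, demo orchestration
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles
- `vignettes/pooled-barcode-screens.Rmd` — the model, conventions and
  their rationale
- `inst/scripts/prism.R` — command-line front end
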