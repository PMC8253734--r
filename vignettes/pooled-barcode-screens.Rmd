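---
title: "Pooled barcoded cell-line screens: model, normalization and scoring conventions"
author: "prismscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled barcoded cell-line screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prismscreen)
```

# The problem

Multiplexed (PRISM-style) screening pools hundreds of cancer cell lines,
each engineered to carry a unique 26-bp DNA barcode, into a single culture.
After a compound or CRISPR perturbation, the relative abundance of each
barcode — read out by amplicon sequencing — reflects the relative fitness of
the corresponding line.  One run therefore yields a drug-sensitivity or
gene-dependency profile across the whole panel.

`prismscreen` implements the computational side of such a platform:

1. a generative simulator (pool growth, two-step PCR amplicon, FASTQ reads)
   so the entire pipeline is testable without any real screen data;
2. mismatch-tolerant barcode extraction and counting;
3. spike-in-referenced, control-anchored normalization;
4. dose-response AUC and sgRNA-averaged dependency scoring, with group
   statistics;
5. QC: Cas9-efficiency gating, dilution-series linearity, replicate
   concordance.

# The generative model

## Pool growth

Each line $i$ has a doubling rate $g_i$ (doublings/day).  Pools are seeded
at about 1000 cells per line — the pooling convention for a several-hundred
line collection — and grown 5 days (compound arms) or 10 days (CRISPR
arms).

**Compound arms.** The effect of dose $d$ (µM) is an end-point viability
multiplier from a four-parameter log-logistic curve,

$$V_i(d) = b_i + \frac{1 - b_i}{1 + (d / \mathrm{EC50}_i)^{h_i}},
\qquad N_i(t) = N_i(0)\, 2^{g_i t}\, V_i(d),$$

with residual viability $b_i \in [0,1]$ and Hill coefficient $h_i > 0$.  A
multiplier rather than a growth-rate change is deliberate: with a single
end-point readout the two are indistinguishable, and the multiplier matches
the way 5-day viability assays are summarized.

**CRISPR arms.** A targeting guide edits a fraction $e_i$ of cells (the
line's editing efficiency); edited cells grow with a relative fitness cost
$\delta_i$:

$$N_i(t) = N_i(0)\left[(1 - e_i)\,2^{g_i t} + e_i\,2^{g_i (1-\delta_i) t}\right].$$

The two control guides are modeled with $\delta_i = 0$: sgNT cuts nothing,
and sgNC cuts a non-expressed intron, so neither should cost fitness — sgNC
exists precisely to flag lines where DNA damage alone is toxic.  Spike-in
lines are Cas9-dead and ignore CRISPR arms entirely, but respond to
compounds through their own dose-response curve.

Realized pools are drawn Poisson around the expectations: at ~1000 cells
per line, per-cell branching simulation adds nothing at count-level
statistics.

## Amplicon and reads

The first PCR amplifies a 550-bp product with the universal primer pair
(forward `ACAACAAGCACCGGGATAAG`, reverse `AGGAACTGCTTCCTTCACGA`); a second,
dual-indexed PCR (8-nt i5/i7, at most 96 combinations per pool) yields the
final 332-bp sequencing product.  The exact spacer sequences around the
barcode are not published; the template here uses synthetic spacers
constrained by the printed product lengths, with two deliberate choices:

* the barcode slot directly abuts the forward primer, because extraction
  slices the 26-mer immediately after the anchor;
* the anchor ends at read position 50, at least 30 nt before position 150,
  so a 150-nt short-read prefix always covers anchor + barcode (read length
  is not published; the default emits the full 332-bp product).

Reads are drawn multinomially with probabilities proportional to cell
numbers; substitution errors are i.i.d. per base (default 0.1%).  Indels
are deliberately absent: fixed-length Hamming decoding treats an indel read
as unassigned, which is the desired behavior.  A configurable fraction of
anchor-less random reads (default 1%) stands in for the PhiX spike-in and
artifacts; actual PhiX genome sequence is never emitted because PhiX
filtering happens upstream of this tool.  Exactly `depth` reads are
emitted, and identical seeds give byte-identical FASTQ.

## The dilution series

The counting validation mixes 20 barcoded plasmids in five concentration
tiers (100, 10, 1, 0.1, 0.01 ng/µl; 4 per tier) in equal volumes, so a
tier-$c$ barcode has designed fraction $c / (4 \sum_c c)$ — a 10,000-fold
designed abundance range.  `makeDilutionPool()` encodes these fractions and
`linearityCheck()` compares them with estimates.

# Extraction conventions

* **Anchor search**: the forward universal primer is searched in a window
  (default positions 0–150) tolerating up to 2 substitutions; among
  occurrences with the minimal mismatch count the leftmost wins.  Reverse
  orientation is off by default (simulated reads are oriented) and
  available via `scanRevComp`.
* **Assignment**: an exact 26-mer match wins immediately; otherwise the
  unique library entry within Hamming distance `k_assign` (default 2).
  Ties are ambiguous and tracked separately — excluded from fractions to
  avoid double-counting.  Whether the original platform counted exactly or
  mismatch-tolerantly is not published; `k_assign = 2` is this package's
  documented default, and `k_assign = 0` reproduces exact counting.
* **Library design floor**: libraries are validated to minimum pairwise
  Hamming distance $2k+1$, which makes nearest-neighbor decoding within
  radius $k$ provably unambiguous; with at most $k$ errors per barcode the
  misassignment rate is exactly zero (tested by exhaustive perturbation).
* Quality scores are ignored: Hamming tolerance already absorbs
  substitution errors and no quality filter is published.
* Reads whose anchor is found with fewer than 26 nt remaining are
  unassigned.

# Normalization

Counts become assigned-read fractions with a symmetric pseudocount of 0.5
(keeps log-ratios finite for fully depleted lines; `pseudocount = 0`
restores exact scale invariance).  Entries under 10 raw reads carry a
low-count flag.

**Spike-in reference.** Each pool contains barcoded Cas9-dead 293T spike-in
lines.  The per-sample reference is the mean over spike-ins of
$f_{\mathrm{spike}} / v$, where $v$ is the spike-in's 5-day CTG viability
under the same (agent, dose) condition; abundances are $A = f / r$.  Two
conventions are deliberate here:

* the *direction* of the correction is division by $v$: if a drug kills the
  spike-in to 40% viability, its observed fraction under-represents the
  reference, and dividing by 0.4 restores it.  This is the direction under
  which a line untouched by the drug ends at relative viability 1 rather
  than $1/v$ — the stated purpose of the adjustment.  The CTG condition key
  is (agent, dose), ignoring timepoint, matching the single 5-day CTG
  convention.
* multiple spike-ins combine by the arithmetic mean of corrected fractions,
  robust to a single dropout when flags are checked.  An arm may designate
  its own spike-in set (a `spikein_set` column), e.g. CRBN-knockout 293T
  for a CRBN-modulator screen where ordinary 293T would itself be killed.

**Control anchoring.** Control samples (DMSO for compound arms, sgNT for
CRISPR arms) are collected at every timepoint.  Relative viability is
$RV = A / \mathrm{median}_{\mathrm{ctrl}}(A)$ over the controls of the same
arm and timepoint; the median across replicates is robust to one outlier
replicate.  Controls themselves normalize to ~1 against their own stratum.

# Scoring

**AUC.** The dose-response AUC convention is the central documented choice,
since only the name "AUC" is published, not the integration rule: the
dose-0 point is the normalization anchor and is excluded; relative
viabilities are clipped to $[0,1]$ (over-proliferation capped so the index
stays within $[0,1]$; raw values are retained in outputs); the trapezoid is
taken over $x = \log_{10}(\mathrm{dose})$ and divided by
$x_{\max} - x_{\min}$.  An insensitive line scores exactly 1 and a fully
killed line exactly 0.  The identical rule applies to 10-point individual
assays and 6-dose pooled screens so the two are comparable.

**Dependency.** The per-line dependency score is the unweighted mean over
targeting sgRNAs of $\log_2 RV$ at the scoring timepoint (default: the
latest timepoint common to the requested guides, typically day 10).  The
sgNC $\log_2 RV$ is recorded, and values below $-1$ raise a DNA-damage
flag: such a line's apparent dependency may reflect cutting toxicity, not
target loss.  The plotted "gene essentiality" axis of the original platform
is not given as a formula; this package defines it as exactly this
sgRNA-averaged log2 relative viability.

**Competition assay.** The flow-cytometry competition readout is
$(\mathrm{RFP_{targeting}} / \mathrm{GFP_{NT}}) /
(\mathrm{RFP_{sgNT}} / \mathrm{GFP_{sgNT}})$, typically on day 10; 1 means
no essentiality.

**Group statistics.** Two genotype groups are compared by an unpaired
two-tailed t test, three or more by one-way ANOVA; groups are summarized as
mean ± SEM.  All-constant groups are reported explicitly (p = 1 if equal,
p = 0 with a zero-variance flag if separated) rather than erroring.
Cross-platform concordance uses OLS regression plus the product-moment
Pearson r.

# QC

* **Cas9 gate**: only lines with editing efficiency strictly above 85% pass
  — the boundary is strict because the archival rule is ">85%".
* **Detection** in the dilution series is a raw-count floor (default 10
  reads), not a fraction: detection limits are Poisson/count-governed.  No
  numeric definition of "successfully detected" is published; the count
  floor is this module's documented stand-in.
* **Replicate concordance**: pairwise Pearson r of log10 abundances within
  each treatment stratum (three biological replicates per condition is the
  platform convention).

# The demo worlds and what a green test establishes

`runDemo()` packages three scenarios:

* `focused_egfr` — 20 NSCLC lines + 2 spike-ins; three lines planted with
  EGFR-exon19del-like behavior (EC50 0.05 µM, deep curves, high knockout
  cost), the rest insensitive (EC50 set at 1000 µM, far above the dose
  range); the spike-in is planted drug-sensitive at the top doses (EC50
  4 µM), exercising the CTG adjustment; erlotinib-like 6-dose scheme
  (0, 0.1, 0.3, 1, 3, 10 µM), day 5; EGFR CRISPR arm with two guides,
  day 10; 3 replicates per condition.
* `full_kras` — 368 lines split 17 / 61 / 290 (KRAS G12C / other mutant /
  wild type) + 2 spike-ins; compound sensitivity planted only in the G12C
  group (EC50 0.1 µM); knockout cost 0.5 planted in both mutant groups,
  0.02 in wild type.
* `dilution` — the 20-barcode, 5-tier pool at 1e6 reads.

Where the protocol prints a value (doses, panel sizes, tier design, product
lengths, index capacity, Cas9 gate), the generator uses it.  Where it does
not (doubling rates 0.5–1.0/day, Hill 1–1.5, editing fraction 0.9,
residuals, per-sample depth, error rate 0.1%), defaults were chosen once at
values typical for cancer-line panels and NGS and are documented here, not
tuned.  Simulated data share the real platform's count-level statistics but
none of its biology-level confounders: no paracrine effects between pooled
lines, no culture-condition dependence, no barcode copy-number variation
(assumed one integration per cell), no index hopping, chimeras or
paired-end structure.  A green recovery test therefore establishes that the
pipeline's arithmetic inverts the generative model at realistic depths —
not that the model captures everything a real screen does.

# Numerical choices and edge cases

* Pseudocount 0.5 applied symmetrically before fractions; per-sample
  fraction sums equal 1 to 1e-12.
* An all-zero sample is a hard error naming the sample; an empty FASTQ is a
  zero column plus a warning.
* Anchor ties resolve leftmost; assignment ties are ambiguous, never
  guessed.
* AUC requires at least 2 nonzero, strictly increasing doses.
* Degenerate (zero-variance) group comparisons return flagged exact limits
  instead of NaN.
* All randomness flows through explicit integer seeds; derived stream
  seeds stay below $2^{31}$.
* Read-level test simulations run at reduced depth to keep the default
  suite fast; the acceptance tests run the stated depths (1e6).

# Limitations

PCR-cycle-explicit chimera formation, index hopping, UMI handling,
paired-end merging, alignment to a full reference, EC50 curve fitting from
pooled data (AUC only, by design), and retrieval of external dependency
portals are out of scope.  Real screen data and real cell-line identities
are not shipped; external scores for correlation enter as user-supplied
tables via `pearsonFit()`.
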