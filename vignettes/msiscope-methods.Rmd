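---
title: "Scoring low-level microsatellite instability in blood: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring low-level microsatellite instability in blood: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Constitutional mismatch repair deficiency (CMMRD) is a recessive childhood
cancer-predisposition syndrome caused by biallelic germline loss of a
mismatch repair (MMR) gene. Because MMR is absent in every cell, affected
children accumulate length variants in short tandem repeats —
microsatellite instability (MSI) — at low frequency even in normal tissue.
msiscope implements a sequencing-based assay that detects this low-level
MSI in peripheral-blood-leukocyte DNA: a targeted panel of 24 short
(7–12 bp) monomorphic mononucleotide repeats is deep-sequenced with
molecular barcodes (UMIs), the wild-type (WT) read frequency at each marker
is compared to its distribution in a control cohort, and the evidence is
combined into a single score.

## From reads to marker counts

Each read carries a UMI (by default the first 5 bases, matching single-arm
smMIP barcoding) and covers one marker amplicon. Rather than aligning,
msiscope assigns a read to the unique marker whose two flank anchors
(default 10 bp, up to 1 substitution each, no indels inside anchors) both
occur in the read with the left anchor before the right. The repeat tract is
the substring strictly between the anchors, and the observed length is the
number of repeat-unit bases in it — so an interrupting substitution
shortens the call, a deliberately conservative convention: interruption and
contraction are indistinguishable to a frequency-based score. Reads are
tried forward, then reverse-complemented. Matching is staged — an exact
pass first, a mismatch-tolerant pass only for reads the exact pass leaves
unassigned — which is ~60× faster and differs from a single fuzzy pass only
if one marker matches exactly while another matches with mismatches,
impossible when flanks are distinct.

Reads sharing a (marker, UMI) pair form a family, presumed to descend from
one captured molecule. A family's consensus length is the modal member
length, called only when the family has at least `min_family_size = 2`
members and the mode reaches `min_consensus_fraction = 0.66`; ties are
discarded. Majority-of-≥2 is the minimal scheme that suppresses independent
per-read slippage errors; all three knobs are exposed, and a raw-read
counting mode (`count_mode = "read"`) is available for comparison with
barcode-free counting. Markers with fewer than `min_marker_families = 100`
called families fail coverage QC — generous at the assay's typical depth of
~3,600 reads/marker/sample, where family counts run near 900.

Aligned BAM is accepted as an alternative input: alignment is used only to
retrieve candidate reads near each marker, which are then re-anchored by the
same flank procedure, because aligner gap placement inside homopolymers is
unreliable.

## The control model and the score

For each marker, the WT-read frequency across a control cohort (40 samples
in the original design) is modelled with a Beta distribution. The default
estimator is the method of moments — with sample mean $m$ and variance
$v$, $c = m(1-m)/v - 1$, $\hat\alpha = mc$, $\hat\beta = (1-m)c$ — chosen
because it is closed-form and deterministic; maximum likelihood
(initialised at the moments estimate) is available, and the choice is
recorded in the model file. Frequencies are clamped into
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ before fitting,
since control frequencies of exactly 1 are common and the Beta log-density
is unbounded at the boundary. Training frequencies are not trimmed or
winsorized: contamination of the control cohort should surface in
calibration checks, not be hidden.

A sample's per-marker evidence is the lower-tail probability
$p_m = F_{\text{Beta}(\hat\alpha_m, \hat\beta_m)}(x_m)$ at its observed
frequency $x_m$ — the probability a control draw lies at or below the
observation. This is the only tail direction under which instability
(depressed WT frequency) raises the score. The $k$ included markers (QC
pass, present in the model) are combined with Fisher's method,

$$X^2 = -2 \sum_{m=1}^{k} \ln p_m \sim \chi^2_{2k} \text{ under the null},$$

and the score is $-\log_{10}$ of the upper-tail probability. A score of
1.30 therefore corresponds to a 5% probability the sample comes from the
control population, and 2.00 to 1%; both thresholds are inclusive and
configurable. Markers excluded by QC reduce the degrees of freedom to $2k$
rather than being imputed — Fisher's method is valid at any $k$ and
imputation would bias the null. Probabilities are floored at $10^{-300}$ so
logarithms stay finite.

An empirical-rank alternative to the fitted CDF
(`marker_tail_probability(..., mode = "empirical")`, the add-one rank among
training controls) is provided as a distribution-free cross-check; the
continuous Beta CDF is the primary route.

### Degenerate markers

With small cohorts at low depth, a near-monomorphic marker can show the
same (clamped) frequency in every control, leaving no variance to fit.
`fit_control_model()` raises a degenerate-variance error by default;
`on_degenerate = "drop"` — used by `run_pipeline()` — instead excludes the
marker from the model with a message, so scoring proceeds on the remaining
markers through the same reduced-degrees-of-freedom path as coverage
failures. At the assay's design depth this situation is vanishingly rare.

## The synthetic-data generator

The generator states a world with the statistical structure the scorer
assumes, so every stage is testable without patient data:

* per-marker control WT frequencies follow Beta distributions with means
  spread over 0.95–0.999 and a common concentration of 62 (the Beta(60, 2)
  family);
* CMMRD depresses the expected WT frequency multiplicatively, marker by
  marker, over 0.85–0.98 — chosen so default cohorts reproduce the
  qualitative score-separation geometry (controls below, patients well
  above the 2.00 threshold) without claiming the published cohort's exact
  score range, which depends on the real samples;
* depth is Normal(3,642, 1,659) reads/marker/sample, matching the assay's
  reported mean ± SD, with ~4 reads per UMI family (≈900 families/marker);
* per-read slippage perturbs a read's length by ±1 with probability 0.02,
  70% of slips being contractions — the standard asymmetry of polymerase
  slippage in homopolymers, and a realistic stress for the consensus
  caller; molecule-level non-WT lengths sit at wt±1 (80%) and wt±2 (20%),
  contraction-biased the same way.

Barcodes are drawn uniformly (collisions possible, as in reality); the
truth table records every molecule so collision-affected assertions can
exclude them. What the generator does **not** emulate: base-quality error
profiles, paired-end fragment structure, PCR duplicate family-size skew,
marker-specific capture efficiency, or contaminated/mosaic samples. A green
end-to-end test therefore establishes that the pipeline recovers the stated
world, not that the assay performs identically on real libraries.

## Calibration: what holds and what does not

If the control model were known exactly, $p_m$ would be uniform and the
score calibrated: 5% of control samples at or above 1.30, 1% at or above
2.00. The test suite verifies this convergence with a large
(2,000–3,000-sample) training cohort. With the design's 40 training
controls, however, the plug-in Beta tail inherits the fit's sampling error,
and the realised type-I fraction at 1.30 varies roughly between 4% and 11%
across training cohorts — a known property of plug-in tail probabilities,
echoed by the original assay's observed 98% (rather than 95%) control
specificity at that threshold. The corresponding fixed-seed acceptance
check is accordingly strict beyond what a 40-control design can guarantee,
and is documented rather than loosened. Diagnostic use should treat the
thresholds as operating points validated against a control cohort, not as
exact error rates.

Scaling notes: the end-to-end separation test simulates read-level cohorts
at a mean depth of 800 reads/marker (not 3,642) to keep the run inside a
desktop budget; family counts (~200/marker) remain far above the QC floor,
and separation is unaffected.

## Numerical and interface choices

* All coordinates are BED-convention 0-based half-open; `end - start`
  equals the WT repeat length by invariant.
* Histograms serialize as ascending `length:count` pairs — lossless and
  diff-friendly; markers without coverage are written with zero counts and
  a failed QC flag rather than omitted, keeping tables fixed-width.
* Same seed + same configuration ⇒ byte-identical tables, FASTQ and
  reports; every pipeline artifact carries a provenance header (package
  version, configuration JSON with md5, input checksums).
* The command-line wrapper (`inst/cli/msiscope`) is a thin layer over the
  exported functions with distinct exit codes for usage errors, missing
  inputs and stage failures.

## Known limitations

Dinucleotide repeats, somatic/tumor MSI calling and probe design are out of
scope. Lynch-syndrome carriers score within the control range by design of
the original assay, and no claim of discriminating them is made. Scores
from patients recovering from aplasia can be spuriously low; interpreting
such samples is a clinical question outside this package. The shipped
24-marker panel is a synthetic stand-in with the stated structural
properties (the published marker coordinates live in supplementary
material); substitute the real BED + metadata TSV via `load_panel()` to run
the published design.
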