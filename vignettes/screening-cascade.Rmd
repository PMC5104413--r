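---
title: "The multi-pass RNAi screening cascade: models, thresholds and the synthetic screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multi-pass RNAi screening cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`nrf2screen` implements the statistics of a multi-pass RNAi screen for
activators of the NRF2 antioxidant response: a pooled-siRNA primary screen
read out with an antioxidant-response-element (ARE) luciferase reporter, a
single-siRNA deconvolution screen, a qPCR confirmation of endogenous
target-gene expression, and a cigarette-smoke-extract (CSE) survival assay
in primary bronchial epithelial cells. This vignette is the package's
account of the underlying models, the parameters that matter, and the
design decisions taken where the workflow left room.

## Normalization model

Every readout is normalized *within its plate*: a well's value is divided
by the mean of that plate's negative-control wells and multiplied by 100.
A 384-well screening plate carries three phenotypically neutral siRNA
pools as intra-plate quadruplicates — 12 negative-control wells — plus
quadruplicates of the KEAP1 (strong), CUL3 (weak) and PLK1 (proliferation)
control pools. Layout validation enforces exactly this architecture,
because the normalizer's precision depends on it: with 12 control wells
the control-mean noise is `cv/sqrt(12)`, about 29% of the well-level noise.

Percent-of-control normalization makes the statistic scale-free:
multiplying every raw value on a plate by any constant leaves every
normalized value unchanged (a tested invariant), so plate-to-plate
transfer, reagent-lot and reader-gain effects cancel exactly. No log
transformation, B-score or spatial detrending is applied anywhere — all
statistics operate on the percent scale the workflow reports.

Imaging channels are averaged from up to four fields per well *after*
removing fields that failed the upstream image QC (focus, background,
artifacts). QC flags are inputs, not computed: the gating lived in the
imaging software, and this package consumes its boolean verdicts. Wells
whose fields all fail are excluded, not imputed, and simply reduce the
replicate count downstream. Whether control wells should be QC-filtered
before or after forming the control mean is not fixed by the workflow; the
package excludes first, so a control mean is always a mean of usable
wells, and rejects a plate outright when no usable negative control
remains.

Replicate statistics are sample mean, sample SD (n − 1 denominator; n = 3
replicate plates is typical, and the workflow does not state the
denominator — the sample convention is standard at this n), and their
ratio, the CV. An entity observed once gets `sd = NA`, `cv = NA` rather
than zero: a single replicate carries no spread information.

## The two hit metrics and their boundaries

Pass 1 thresholds the per-pool normalized luciferase mean at
**mean + 2 SD of all test pools** — controls are excluded from the
threshold population, since the planted 3x KEAP1 quadruplicates on every
plate would otherwise inflate the SD and move the threshold. The same
rule, computed independently, applies to the **per-cell metric**

$$\text{per-cell} = 100 \times
  \frac{\text{luciferase}_{\%}}{\text{nuclei}_{\%}},$$

the ratio of two intra-plate-normalized percentages. The ratio form (as
opposed to a ratio of raw values) keeps the metric dimensionless and
plate-bias-free. The per-cell route exists because whole-well
luminescence scales with cell number: a pool that activates the reporter
but slows proliferation can sit below the raw threshold while its
per-cell activity is clearly elevated. The union of both routes goes
forward.

Boundary semantics differ deliberately between passes and follow the
workflow's own wording: pass 1 is **strict** (`>` mean + 2 SD), while the
confirmation passes use an **inclusive** threshold (`>= 130%`), the
survival gate is **inclusive** (`>= 3-fold`), and the replicate rule is
**at least 4**. The tests pin each boundary exactly, including the
degenerate pass-1 population with SD 0 where every pool sits precisely at
the threshold and none may be called.

Deconvolution (passes 2 and 3, identical logic on 384- and 96-well data)
confirms a gene when at least one of its three constituent siRNAs reaches
the 130% threshold, and counts the *support* — how many independent
siRNAs pass. Support stratifies confirmed genes into likely off-target
hits (support 1) and corroborated regulators (support 2–3). The per-cell
route applies the same 130% figure to the per-cell metric; the workflow
does not print a separate per-cell confirmation threshold, and reusing
the raw one keeps the two routes comparable. The blended
`support_count` reports the raw-route count when that route confirms,
else the per-cell count; only the per-route counts are monotone in the
threshold, which the property tests respect.

Pool-versus-best-single comparisons use a two-sided Welch t-test on
normalized replicate values, with ties for "best" broken toward the
lexicographically lower siRNA identifier for determinism. The workflow
names only a 5% level, not a test; Welch is the safer default for
three-replicate samples with no variance-equality guarantee. The survival
module, by contrast, defaults to the classical equal-variance Student
test because its protocol names that test explicitly; a flag switches
either choice.

No multiple-testing correction is applied anywhere in the cascade — the
workflow applies none, and the confirmation structure (independent
re-testing in new experiments) is its error control.

## qPCR quantification

Relative quantities come from a standard curve, not from ΔΔCt: the
protocol quantifies against a dilution series, so the package fits
`Ct = slope · log10(q) + intercept` by least squares and inverts it,
`q = 10^((Ct − intercept)/slope)`. Amplification efficiency is
`10^(−1/slope) − 1`; a perfect doubling per cycle gives slope
−1/log10(2) ≈ −3.32 and efficiency 1.0. Curves with fewer than three
distinct dilutions, or slopes at or above numerical zero (≥ −1e−9), are
rejected; non-monotone mean Cts along the dilution series warn. Cts
outside the standard range are extrapolated with a message rather than
dropped — follow-up samples routinely land past the last standard.

Expression is normalized to the RNA-polymerase-II housekeeping quantity
per replicate, then expressed as fold over the mean of the
control-siRNA samples on the same plate (the reference is configurable;
control siRNA is the default when untreated cultures also exist). A
sample is an expression hit when fold ≥ 1.30 (inclusive, mirroring the
reporter confirmation boundary) *and* a two-sided Welch t-test against
the pooled control replicates gives p < 0.05. Reporter/expression
concordance is Pearson on log2 ratios — matching how such comparisons are
plotted — with Spearman alongside as a rank-based robustness output;
correlation on log ratios is invariant to rescaling either axis.

Western-blot densitometry normalizes the band of interest to actin within
each replicate, expresses it relative to the control condition of the
same replicate, and uses a paired two-sided t-test across replicates
(n ≥ 3), pairing by replicate because blots share gel, transfer and
exposure.

## The survival assay

CSE-tolerance plates are valid only when the siKEAP1 positive control
shows at least 3-fold (inclusive) the siControl ATP level — a functional
check that transfection worked under stress. Test siRNAs run as
intra-plate duplicates; duplicates are averaged *before* any testing,
never pooled into the t-test as pseudo-replicates. Valid plates are
biological replicates; at least 4 are required before a significance
call, and the generator mirrors the bench practice of repeating
experiments until that bar is met. Each siRNA's per-plate normalized
means are compared against the reagent-only normalized means *of the same
plates*, keeping independent experiment batches independent.

One statistical property deserves note: because both sides of the t-test
are divided by the same per-plate siControl mean, they are positively
correlated, and the two-sample test is slightly conservative — with 16
siControl wells per plate the realized null rejection rate is about 0.04
at a nominal 0.05. This is a property of the published procedure, not of
the implementation; the null-calibration test uses a Monte-Carlo band
around the nominal level wide enough to accommodate it. ATP is analyzed
in relative luminescence units throughout; converting to molar
concentrations via an ATP standard would cancel out of every ratio, so
the package does not model it.

## The synthetic screen generator

The generator exists so that every stage is testable against known ground
truth without external data. It emulates the screen's geometry — 4995
gene pools randomly distributed over 19 source plates in 384-well format,
intra-plate control quadruplicates, six replicate experimental plates per
source plate (three lysed for luciferase, three imaged at four fields per
well) — and its noise profile.

Noise is multiplicative log-normal with mean 1: screen readouts are
positive and right-skewed, and multiplicative effects compose naturally
(luciferase ∝ activation × proliferation, so per-cell confounding arises
without special casing). Plate-level factors drawn from ±30% prove that
intra-plate normalization removes them. The well-level CV default, 0.0757,
is derived, not fitted: for the 3-replicate sample CV to fall below 0.10
with probability 0.80 requires a per-replicate CV of
`0.1 * sqrt(2 / qchisq(0.8, 2)) ≈ 0.0788`, and dividing out the extra
noise the 12-well control mean contributes (`sqrt(1 + 1/12)`) gives
0.0757. A full-scale run reproduces the calibration: 80.1% of luciferase
CVs fall below 10% (nuclei, which carry additional per-field jitter, sit
near 79%).

Defaults the study conditions do not pin down were chosen once, on
realism grounds, and are not tuned:

* **50 planted true activators** with folds uniform on 1.3–3x. Strong
  activation in such screens is rare and specific; at this prevalence the
  mean + 2 SD threshold lands near 126–128%, the regime the workflow
  operates in. The KEAP1-like 3x ceiling matches the strongest control.
* **Effective-siRNA counts** per activator drawn with probabilities
  0.6/0.3/0.1 for 1/2/3, matching the strong skew toward single-siRNA
  support that deconvolution screens show.
* **25 proliferation suppressors** at nuclei folds 0.5–0.8 (the 0.5 floor
  is the PLK1-like two-fold reduction).
* **Off-target rate 0.05** per non-effective single siRNA, with folds
  1.3–2x.
* **Baselines**: 2e5 RLU per well, 800 nuclei per image field (with 3.5%
  field jitter, the scale of counting noise at a few hundred objects),
  condensation fraction 0.04.
* **Survival**: 10% well noise, planted siKEAP1 protection 4x, and 20% of
  plates drawn with a sub-threshold KEAP1 response (2–2.9x) to exercise
  the validity gate; 16 siControl, 4 siKEAP1 and duplicate reagent-only
  wells per 96-well plate.
* **qPCR**: standards on the exact 100%-efficiency line over five decades,
  Gaussian Ct noise of 0.1 cycles, triplicate wells.

All randomness flows from one seed; sub-simulations derive child seeds
deterministically, so identical configurations reproduce byte-identical
tables.

What the generator deliberately does **not** emulate: spatial plate
effects (edge evaporation, gradients — the analysis applies no spatial
correction, so simulating them would only document a known blind spot),
sequence-determined off-targets (seed-complement effects are i.i.d.
draws here), cross-contamination, and the biological scatter that
decouples reporter activity from endogenous expression. The last point
matters when reading the concordance output: synthetic reporter and
expression readouts share their latent activation and differ only by
measurement noise, so their correlation (r ≈ 0.97) is far higher than
real screens achieve; the concordance *machinery* is what is being
exercised, not a realistic r. Passing tests therefore demonstrate the
statistics are implemented and calibrated correctly — not that the
generator is a faithful biological model.

## Numerical choices and degenerate inputs

* Sample SD everywhere uses the n − 1 denominator; single observations
  yield `NA`, not 0.
* Identical samples in a t-test (or two zero-variance samples with equal
  means) return `indistinguishable`/non-significant rather than erroring;
  zero-variance samples with different means are reported as
  significant with p = 0.
* Standard-curve slopes above −1e−9 are rejected as flat.
* Well addresses are case-insensitive on input, zero-padding tolerated,
  normalized to upper case without padding.
* Condensation fractions are clamped to [0, 1] at generation and
  validated on ingestion.
* Empty result tables write a header and warn, so downstream tooling
  always finds the schema.

## Problem sizes in the test suite

The acceptance properties run at the scales the analyses describe: the
full 4995-gene, 19-plate geometry for the calibration and null-tail
checks (a few seconds each, vectorized), 1000 random tables for the
brute-force oracle equivalences, and 1000 independent single-siRNA
survival batches for the null calibration. Unit tests use one-plate
screens of a few hundred genes, sized for readability rather than power.

## Limitations

The package consumes per-field nuclei counts and condensation fractions;
it does not segment images. It reads delimited text (and spreadsheets via
readxl for the supplementary-table importer); binary plate-reader vendor
formats are out of scope. Dose–response curves for CSE or compound
titrations are not modeled — the cascade's decisions never depend on one.
And the hit thresholds are the workflow's own fixed rules; the package
applies them exactly rather than offering alternative hit-scoring schemes
(RSA, redundant-siRNA probability), which would change the question being
answered.
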