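---
title: "Measuring signal transduction pathway activity from target-gene mRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring signal transduction pathway activity from target-gene mRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsig)
```

## Why infer pathway activity from target genes

Whether a signal transduction pathway (ER, AR, PI3K, Wnt, Hedgehog, ...) is
functionally driving a tumor is not readable from mutations or from the
expression of the pathway's own signaling proteins: protein levels track
mRNA poorly and activity is set by post-translational state. What an
activated pathway does do, reliably, is switch on the transcriptional
program of its transcription factor (TF). `pathsig` therefore treats the
mRNA levels of a small curated panel of the TF's *direct target genes* as
evidence about a latent binary activity state, and combines that evidence
probabilistically. Which genes qualify as high-evidence direct targets is a
literature problem and deliberately outside this package: panels are inputs
(`gene_panel()`), typically around 12 genes for qPCR assays.

## The two-layer network

For one pathway the model is a tree: TF at the root; one binary target-gene
node TG per panel gene; one observed measurement node per probe/assay,
conditionally independent given TG.

* **First layer (priors), P(TG = up | TF).** These express how tightly the
  gene's transcription follows TF activity, and come from biology rather
  than from the calibration data. Defaults:
  `p_up_given_active = 0.95`, `p_up_given_inactive = 0.05` for an induced
  gene, the pair swapped for a repressed gene, and `P(TF active) = 0.5`.
  The defaults are a declared choice — strong but non-degenerate coupling,
  and a uniform prior so that log2 odds 0 means "evidence balanced" — not a
  reconstruction of any commercial assay's undisclosed values. Repression is
  modeled here, in the biology layer, by swapping the coupling; measurements
  are never negated, so the emission layer stays purely about measurement
  behavior.
* **Second layer (emissions), P(measurement = high | TG).** Continuous
  values are dichotomized against a per-probe threshold `t` (`value >= t`
  reads high, a stated tie-break convention). Per probe the model stores
  `p_high_given_up` and `p_high_given_down`, fitted during calibration.

Scoring a sample marginalizes each gene's latent state:

$$LR_g = \frac{\sum_{s} P(e_g \mid TG=s)\,P(s \mid \mathrm{active})}
              {\sum_{s} P(e_g \mid TG=s)\,P(s \mid \mathrm{inactive})},
\qquad
L = \log_2 \frac{P(\mathrm{active})}{P(\mathrm{inactive})} + \sum_g \log_2 LR_g .$$

A probe with a missing value contributes likelihood factor 1: absent
evidence is neutral, not "low". This single choice is what makes the score
degrade gracefully under conflicting genes and low-input dropout — a gene
that is not expressed in some tissue simply stops contributing, instead of
voting "inactive". Because the likelihood ratio of each observed probe is
bounded by its emission odds, no single gene can dominate the sum: strongly
conflicting evidence from one gene is outvoted by the remainder of the
panel, which is the mechanism behind the assay's claimed robustness to
conflicting data. `brute_force_infer()` computes the same posterior by
summing the full joint over all $2^n$ TG configurations (n ≤ 16) and is the
package's internal correctness oracle; the test suite holds the two routes
to within $10^{-9}$ in $L$.

### The 0–100 score

The mapping from log2 odds to the familiar 0–100 activity score is not
published; this package pins a deterministic, model-intrinsic one:
`S = 100 (L − l_min)/(l_max − l_min)`, clamped to [0, 100], where
`l_min`/`l_max` are the extreme log2 odds over all *complete* evidence
assignments. They are computed exactly at build time by exploiting the
factorization over genes (per-gene extremes over the $2^{\#probes}$
assignments, summed, plus the prior term). Consequences: `S = 100` is
attainable, `S = 50` corresponds to `L = 0` under the symmetric default
parameterization (where `l_min = −l_max` exactly), and scores are
comparable only between samples scored by the same calibrated model.
Comparisons with published score values are therefore qualitative. A model
in which every gene is uninformative has `l_min = l_max`; its scores are
defined as 50. The prior term is included in the bounds so the mapping
remains well-behaved under non-uniform priors.

## Calibration

Ground-truth samples (disease etiology, mutation status, or controlled
stimulation/blocking experiments) carry labels active/inactive. Calibration
is deliberately *hard-assigned* and deterministic, not an EM over latent
states: the TG state of each gene in each calibration sample is deduced
from the label and the gene's direction ("up" in active-labeled samples for
induced genes, "up" in inactive-labeled samples for repressed genes). Then:

* **Thresholds** (`derive_thresholds()`): midpoint of the two
  class-conditional medians per probe. Medians resist outliers; the
  midpoint is symmetric in the classes, so direction does not move `t`.
  This estimator is unbiased when the within-state value distributions are
  (approximately) symmetric around their centers with similar spread;
  strongly asymmetric emission behavior biases the midpoint, a known
  limitation of the pinned rule.
* **Emissions** (`fit_emissions()`): Laplace-smoothed counts,
  `p_high_given_up = (n_high,up + α)/(n_up + 2α)` with `α = 1` by default.
  Smoothing keeps every probability strictly inside (0,1), hence every
  likelihood ratio finite, even with small calibration sets. At least
  `min_samples_per_class = 2` labeled samples per class are required.

`calibrate()` chains the two and records provenance (per-class counts, α,
threshold rule) inside the model; `save_model()`/`load_model()` serialize
everything as versioned JSON (`pathsig-model/1`) with probabilities stored
as decimals for auditability, refusing newer major versions outright.

### Porting a panel to RT-qPCR

Microarray-calibrated panels move to clinical RT-qPCR by re-measuring the
*same* calibration samples on the new platform and re-deriving only the
measurement layer (`port_platform()`): thresholds and emissions are
platform properties, the first-layer biology is not, so priors and gene
directions are retained. Raw Cq tables are first converted to relative log2
expression by reference-gene ΔCq normalization (`normalize_cq()`):
`expr = mean(Cq of reference genes) − Cq(target)`, so that larger always
means more transcript and one calibration code path serves both platforms.
Cq above `cq_max = 40` (the conventional no-amplification cutoff) or
missing becomes missing expression; samples without any valid reference
gene are dropped with a warning record. The transform is shift-invariant
per sample, which absorbs global efficiency shifts; per-gene amplification
efficiency is assumed to be 2.0 (no efficiency correction — a stated
limitation, as none is described for the original assay).

## Reference ranges and patient reports

Clinical interpretation needs a normal range. `reference_distribution()`
collects scores from healthy tissue (n ≥ 5) and fixes the abnormality
threshold at the 95th percentile of normal, computed by linear
interpolation between order statistics at rank `h = 1 + (n−1)q/100`
(identical to R's default quantile type 7). The percentile method matters —
different conventions shift thresholds — so one is pinned and tested. The
source material describes the same threshold once as a percentile and once
as a "95% confidence interval of normal"; this package implements the
percentile reading. Calls use a strict inequality (`score > t95` ⇒
above-threshold, potentially tumor driving and targetable; equality stays
within-normal), and only the upper tail is thresholded: loss of a
tumor-suppressive pathway is pathway-dependent in meaning and is reported
descriptively, not called. `patient_report()` assembles one call per
analyzed pathway (stable alphabetical order) with optional cancer-type
score-distribution context, serialized as versioned JSON or TSV.

For the PI3K–FOXO pair, where reported PI3K activity is by convention the
inverse of the measured FOXO transcription factor activity, a panel may
declare `inverse_of = "PI3K"`; results then carry the annotation. The score
itself is never numerically inverted — inventing such a transformation
would overstate what the convention says.

## The synthetic cohort generator

No external data sets ship with or are downloaded by this package; every
claim is exercised on synthetic cohorts with the statistical structure the
assay assumes (`simulate_cohort()`):

* per sample and gene, the latent state follows the first-layer coupling
  (up with probability 0.95 in the label-consistent class by default);
* `frac_conflicting` flips each gene's state independently per sample,
  emulating conflicting data (target genes contradicting pathway state);
* measurements are Gaussian on the log2 scale around class means 8 (up)
  vs 5 (down) with sd 1 — a 3 log2-unit effect with clear but imperfect
  within-gene separation, a realistic magnitude for a strongly regulated
  direct target on either platform;
* `degrade_low_input()` models low-input measurement as independent
  missing-at-random dropout plus extra Gaussian noise (dropout 0.2 and
  extra sd 0.5 in the robustness tests — free knobs, since no quantitative
  noise model for pre-amplified low-input material is published; the
  pre-amplification chemistry itself is not simulated);
* `simulate_cq()` converts an expression matrix into a raw Cq table
  (`Cq = target_base − expr + noise`, reference genes near their own base,
  sd 0.2 cycles) so the very same samples can be "re-measured" for
  platform-port studies; raising the reference base Cq toward 32–35.5
  emulates the diluted regime.

Seeds are mandatory everywhere and generators never touch the session RNG
state, so identical spec + seed is bit-identical output.

What a green synthetic test establishes — and what it does not: the tests
show that the inference machinery is mathematically correct (oracle
equivalence, analytic anchors, monotonicity), that calibration recovers the
parameters of data generated under the model's own assumptions, and that
the claimed qualitative behaviors (class separation, conflict tolerance,
low-input robustness, cross-platform rank stability) hold in the stated
synthetic world. They cannot establish clinical validity, the quality of
any particular target-gene panel, or behavior under real-platform artifacts
(batch effects, probe cross-hybridization, amplification bias), all of
which are outside the generator.

## Numerical and design notes

* All inference is done in linear probability space; with at most 16 genes
  and smoothed emissions, joint terms stay far above double underflow.
* `simulate()` on a fitted model draws values as
  `N(t + sd·qnorm(p_high|state), sd)`, so dichotomization probabilities
  equal the emission parameters *exactly*. Its default generates the latent
  states hard from the labels — the generative counterpart of the
  hard-assignment calibration — which is what makes emission parameters
  directly recoverable by re-calibration (the package's parameter-recovery
  test). With `latent = "stochastic"` states are drawn from the first-layer
  coupling instead; the identifiable label-conditional quantity is then the
  mixture `0.95·p_up + 0.05·p_down`, not the raw emission parameter, which
  is why "hard" is the default for recovery studies.
* Per-sample scoring failures inside a cohort (e.g. a sample with no
  overlapping probes, or total dropout) are collected in the result's
  `error` column with `NA` scores — never silent scores, never a batch
  abort. Scoring a single sample raises the error directly.
* Ties at a dichotomization threshold read "high"; values are compared with
  `>=` everywhere, including calibration counting, so calibration and
  scoring cannot disagree on a boundary value.
* Parsing of matrices and labels is strict (duplicate IDs, ragged rows and
  non-numeric cells are errors with line numbers) and locale-independent.

## Limitations

Pathways are scored independently (no crosstalk model); the emission layer
is dichotomized rather than continuous; panel curation, microarray
preprocessing, RNA-seq quantification and batch correction are out of
scope; and the 0–100 mapping, threshold rule and ΔCq convention are this
package's declared reconstructions where the original assay leaves them
unspecified.
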