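---
title: "Methods: harmonizing GPCR-G protein coupling screens into a unified map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonizing GPCR-G protein coupling screens into a unified map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(couplemap)
```

## The problem

Large-scale GPCR-G protein coupling datasets come from incompatible
worlds: BRET-based effector-translocation biosensors, chimeric-G-protein
shedding assays, and literature curation of family-level transducer
annotations. They differ in receptor coverage, G protein panels, raw
units, detection sensitivity and even in what counts as "a coupling".
`couplemap` treats this as a harmonization-and-meta-analysis problem: put
every source on one scale, define couplings by one detection rule, and
classify every receptor-G protein cell by its pattern of independent
support.

## Data model

The exchange format is a long table with one measurement per
(source, receptor, G protein): pEC50, raw Emax, basal mean and interday
basal SD, a curve status (`converged`, `unconverged_approximate`,
`no_activity`), ligand metadata and exclusion flags. The G protein panel
(`gprotein_panel()`) carries the structural metadata every module needs:
the 16 human subtypes in four families, the GoA/GoB isoform split of
GNAO1, which platform tested which subtype, and the chimeric-probe
equivalence classes of the shedding assay (one physical probe measures
Gi1/Gi2 — and stands in for the sensory transducins — one measures
GoA/GoB, one Gq/G11; `expand_probe_measurements()` duplicates the probe
value to each member, so comparisons at subtype level use identical
datapoints where the assay cannot distinguish members).

Workbook-shaped supplements are expected to be converted to this long TSV
upstream; a single schema keeps every analysis independent of any one
source's layout.

## QC rules

* **Enzymatic-unit ligands.** Ligands dosed by enzymatic activity (e.g.
  thrombin in mU/ml) produce pEC50 values on a different scale; a fixed
  offset of +10 moves them into the molar-like range. The offset is a
  configurable convention, not an estimate.
* **Endogenous-equivalent responses** of overexpressed receptors are
  excluded outright.
* **Unconverged curves** carry only approximate values. They are kept
  only when the coupling is supported elsewhere (the other quantitative
  source shows a converged curve for the pair, or the receptor's family is
  annotated) and not contradicted (the other source tested the pair and
  saw no activity). The support lookup defaults to subtype-level matching
  (after canonicalizing isoforms); family-level matching is available,
  since either reading of "supported elsewhere" is defensible.
* **Detection threshold.** A coupler requires
  `Emax > basal + k * SD(basal)` with a *strict* inequality; strictness
  only matters on exact ties and is the documented convention here. The SD
  is the per-(receptor, G protein, source) interday basal SD — never
  pooled across G proteins, because interday variability differs widely
  between them.

The chain (exclusions → unconverged resolution → pEC50 shift → threshold)
is idempotent, which the tests assert.

## Choosing the threshold

Without a physiological gold standard, the best available criterion for
`k` is cross-platform reproducibility: `optimize_sd_cutoff()` scans
k = 0–3 in steps of 0.1 and maximizes the mean coupler/noncoupler
agreement between the two quantitative sources over cells tested by both.
Agreement is the unweighted mean over units (G proteins or families) of
per-unit matching fractions — non-coupler matches count. Ties go to the
smallest k (prefer the least aggressive filter among equally reproducible
ones). The optimization level (subtype vs family) is a switch; subtype is
the default because it uses every measured cell.

## Harmonization

Raw Emax ranges differ per G protein by orders of magnitude, so Emax is
min–max normalized per (source, G protein) across receptors: the
normalized quantity is the net signal `Emax − basal` (the no-agonist
signal defines 0), and the largest coupler signal defines 1. pEC50 needs
no normalization. The combined activity value is

```
log(Emax/EC50) = log10(emax_frac) + pEC50,   emax_frac ∈ (0, 1]
```

bounded above by pEC50 and strictly increasing in both arguments. Families
aggregate by the **maximum** member value (the argmax subtype's Emax and
pEC50 carried along); mean aggregation exists only for protocol
comparison. `evaluate_protocols()` reproduces the whole comparison table —
raw vs min–max vs double-normalized Emax, raw pEC50, the combined value,
max vs mean aggregation — scored by the mean similarity ratio and by mean
per-receptor and per-G-protein squared correlations (receptors need at
least three common datapoints to contribute an r²).

Two conventions deserve explanation:

* **Similarity ratio.** The cross-source "ratio" of two positive values is
  implemented symmetrically as `min/max`, so averages stay in (0, 1]
  regardless of which source reports larger values. A directional ratio
  would straddle 1 and make averages uninterpretable; the symmetric choice
  is recorded here and in the run manifest, and is switch-free by design.
* **Zeros.** Quantitative comparisons use only *common couplers* — a
  non-coupler has no defensible value on the log scale, so zeros are never
  imputed — with one deliberate exception: the co-coupling Pearson
  analysis fills non-couplers with 0, because there the question is
  whether two G proteins share receptors at all, and masking non-couplers
  would erase exactly that signal.

## The unified map

Every tested cell gets an evidence pattern (who tested, who found
coupling, whether the family is annotated) and labels:

* *supported* — coupler in ≥2 sources, the annotation counting as one
  source; annotation-only couplings self-support (they aggregate multiple
  publications).
* *novel* — coupler in both quantitative sources, not annotated.
* *proposed* — coupler in one quantitative source, no other source ever
  tested the cell.
* *unique:source* / *missing:source* — one source couples while all other
  testing sources do not, and vice versa. "Missing" applies to
  quantitative sources: an annotation gap opposite two quantitative
  couplers is what "novel" means, not a missing annotation.

Map values are the arithmetic mean of the coupling sources'
log(Emax/EC50); when one source couples and the other does not, the
coupling source's value is used alone and the labels record the
discrepancy. Receptors with no quantitative data form a separate
family-level, annotation-only section. The receptor universes (all,
quantitative, annotation-only) are reported per analysis rather than
assumed constant, because different statistics legitimately use different
universes.

## Selectivity, co-coupling, expression

Promiscuity and coverage statistics run on the supported couplings with
annotation-only receptors contributing family-level presence;
within-family promiscuity requires full subtype coverage and therefore
uses the quantitative section only. When Golf is present in the subtype
universe, receptors tested for Gs but not Golf are excluded from the
Gs-family subtype statistics, and Golf counts only alongside a supported
Gs coupling.

Co-coupling uses per-G-protein activation vectors over receptors (mean of
the two sources' values where both couple, single-source values
otherwise). Pearson correlations are computed on zero-filled vectors with
two-tailed p-values and significance stars at 0.05/0.005/0.0005 — raw,
with no multiple-testing correction, since the stars describe individual
pairs rather than a family-wise claim. Jaccard indices and mean
activation differences use coupler-only data. The G protein tree is
average-linkage hierarchical clustering on the correlation distance
1 − r; building the tree from r (rather than from raw vectors) keeps it
consistent with the displayed matrix.

Tissue expression works on a 16-gene × 50-tissue nTPM matrix. The
first-quartile threshold uses linearly interpolated percentiles (R's
default type 7) over all matrix values; the convention is recorded because
the numeric threshold depends on it and on the atlas release. Per-gene
z-scores use the sample (n−1) SD — the common `scale()` convention, and
the one consistent with the package's own worked arithmetic; constant
genes are flagged rather than silently zeroed. The display cap is the
median of per-gene maxima. Real-atlas numbers are release-sensitive and
treated as validation output, never as test expectations; all tests run on
a bundled synthetic fixture.

## The synthetic-data generator

The generator defines the study conditions for all download-free
validation:

* **Couplome truth.** Family couplings are Bernoulli per receptor with
  prevalences (Gs 0.34, Gi/o 0.69, Gq/11 0.52, G12/13 0.19) — the family
  coverage fractions of the reference couplome — giving ≈1.74 expected
  families per receptor. A coupled family activates each member with
  probability 0.75 (matching the observed ~3/4 full-family activation),
  at least one member forced. pEC50 ~ Normal(7, 1); the true Emax fraction
  has a 15% weak tail (0.05–0.3) so near-threshold couplings exist.
* **Assays.** Each platform has per-G-protein raw signal windows (the
  BRET-like default shrinks Gs and G12 windows to emulate their small
  assay windows), detection sensitivities, basal noise with per-record
  interday jitter, multiplicative Emax noise, additive pEC50 noise, and a
  5% rate of spurious sub-threshold responses (≤1.2 SD) in true
  non-coupler cells — the weak false signals the basal-SD cut-off exists
  to remove. An optional chimera mode duplicates Gi1/Gi2, GoA/GoB and
  Gq/G11 values to emulate shared probes.
* **Annotation.** True family couplings are reported with per-family
  probabilities (default 0.8, but 0.2 for G12/13, emulating its literature
  under-representation); the strongest family is ranked primary.
* **Threshold scenario.** `threshold_scenario()` injects a known detection
  threshold: coupler signals start just above `k_true` SDs, spurious
  responses stay strictly below it, independently in the two sources, so
  the agreement scan has its maximum at `k_true`.

What the simulation does *not* model: ligand-dependent bias, receptor
classes, correlated pEC50/Emax errors, curve fitting itself (statuses are
generated, not fitted), and any mechanistic pharmacodynamics. Passing the
recovery tests therefore demonstrates that the pipeline's logic is
correct under its own assumptions, not that any particular real dataset
meets them.

## Problem sizes and numerical choices

The test suite and acceptance script use n = 300 receptors for end-to-end
recovery, n = 200 for threshold recovery, and n = 2000 only for moment
checks of the generator — sizes at which the checked properties are
stable across seeds while the whole suite runs in seconds. Determinism:
every stochastic step takes an explicit seed and the pipeline contains no
hidden randomness, so identical inputs give byte-identical output bundles.
Degenerate inputs (all-flagged exclusions, all-zero responses for a G
protein, constant expression genes, empty annotation sets, empty agreement
strata) warn or error explicitly rather than producing silent NA
propagation.

## Known limitations

* Receptor identifier reconciliation is name-based; no synonym table is
  bundled, so sources must agree on receptor naming (an alias file can be
  applied upstream).
* Workbook ingest is out of scope; supplements are converted to the
  canonical TSV before entry.
* The classification treats the annotation dataset as a single aggregate
  source; it cannot represent disagreement *within* literature.
* Family aggregation by maximum discards within-family activation
  diversity by construction; use subtype-level outputs where that matters.
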