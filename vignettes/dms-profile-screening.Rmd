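---
title: "Profile comparison and riboswitch screening with dmscreen"
author: "dmscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile comparison and riboswitch screening with dmscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmscreen)
```

## The signal model

DMS methylates the Watson–Crick–Franklin face of unpaired, solvent-exposed
A and C bases; mutational profiling converts each adduct into a mutation
during reverse transcription. After upstream alignment and mutation
counting (which this package deliberately does not do), the per-position
data are counts: `coverage` reads covering a position and `mutated` reads
carrying a non-reference call there. The reactivity signal is the mutation
fraction `f = mutated / coverage`, masked (`NA`, `null` in JSON) wherever
coverage is zero or the reference base is N.

"Mutated" counts any non-reference call — substitution *or* deletion —
because reverse transcriptases produce both at modified bases. The
substitution breakdown `sub_counts` (reads mutated to A/C/G/T) covers
substitutions only, so its position-wise sum is at most `mutated`; data
converted from tools that do not export a breakdown carry no `sub_counts`,
and the identity plot refuses to fabricate zeros for them.

Coordinates are 1-based inclusive everywhere — in section annotations, in
profiles, in the JSON dialect. Any half-open arithmetic is internal.

## The data model and its JSON dialect

A study is samples → references → sections → profiles. Each sample also
holds per-reference aligned-read counts, per-read mutation-count
histograms, and experimental variables as (value, unit) pairs so that
series like "fraction at one base versus MgCl2 concentration" are
well-defined and sortable.

The JSON dialect (schema_version "1") is defined by this package:
top-level `{schema_version, references, sections, samples, provenance}`,
position-parallel arrays, masked values as `null`, numbers at full
precision, and a fixed field ordering so that writing a study is
byte-stable. Unknown top-level keys from other exporters are preserved
under `provenance` rather than rejected. Round-tripping (`load_study
. write_study`) is the identity and is tested field-by-field, masked
positions included.

Converters for ShapeMapper2-style profile tables and for two documented
RNA-Framework-style count dialects map third-party output into this model.
They preserve counts exactly and compute fractions through the same single
code path as everything else. Files holding only normalized reactivities
are rejected with an explanation: the model is count-based, and a 2–8%-rule
style normalization cannot be undone. A user-supplied FASTA, when given,
must agree with the converted file's own sequence column — a silent
sequence mismatch would corrupt every base-colored display downstream.

## Selection and quality control

Selections (samples, references, one section, a base subset, an optional
position range, a coverage floor) only ever *mask*; they never drop
positions or alter counts, so the position axis is stable across plots and
the base filter and range filter commute. The default base subset is
`{A, C}` — the bases DMS reports on. The coverage floor is inclusive: a
position exactly at `min_coverage` is kept.

The screening QC gate requires, in *both* samples of a pair, a median
region-of-interest coverage of at least 1000 reads and at least 10 unmasked
A/C positions. The 1000× floor reflects common practice for stable MaP
fractions (at f = 0.02 the binomial standard error at 1000× is 0.0044,
about 22% relative); 10 informative positions is the minimum at which a
correlation over a profile is meaningfully interpretable. Both thresholds
are explicit parameters, and the gate is symmetric in the sample pair.
These defaults are this package's own choices; they are not calibrated to
reproduce any particular published pass count.

## Comparison statistics

`compare_profiles` computes, over positions unmasked in both inputs:
Pearson r (reported squared as R²), RMSE of the fractions, and an
ordinary-least-squares fit of sample 1 (y-axis) on sample 2 (x-axis) — the
plotting convention in which the identity line x = y is the null model of
no difference and the fitted slope is directly comparable to the identity
slope 1. Conventions worth stating:

* R² is the squared correlation, which for simple OLS coincides with the
  regression R²; the coincidence is unit-tested rather than assumed.
* RMSE is computed on raw fractions (or on normalized fractions only when
  normalization is explicitly requested); no transformation is applied.
* A constant input vector makes r undefined; it is reported as a masked
  statistic with a reason, never coerced to 0.
* `n` is exactly the number of shared unmasked positions; fewer than 2 is
  an error, not a silent NA.

Cross-sample normalization (for comparisons across chemistry conditions,
e.g. uridine versus pseudouridine transcripts) defaults to least-squares
scaling through the origin: `k = sum(x·y) / sum(y²)` over shared unmasked
A/C positions, which minimizes `sum((x − k·y)²)` — a deterministic,
single-factor scaling appropriate when the two samples differ in overall
signal magnitude but not in shape. A median-of-ratios alternative is
available for outlier-heavy profiles, and `"none"` disables scaling.
Normalized fractions above 1 are clipped, and the number of clipped
positions is reported. Scaling is off by default for technical replicates
and available per screen run for condition comparisons.

## The screen

For each reference present in both samples and passing QC, the screen
correlates the two samples' fractions over the region of interest (A/C
only), ranks references ascending by R² (ties broken lexicographically so
ranking is deterministic), and calls responders strictly below the
threshold, default R² < 0.6. The strictness matters at the boundary: a
reference at exactly the threshold is not a responder. Calling is monotone
in the threshold. References missing from one sample are reported as
`absent` rather than failed, and QC failures carry machine-readable
reasons.

Binding-site protection summarizes the per-position evidence behind a
call: `delta = with-ligand − without-ligand` at stated site positions,
`protected` meaning delta < 0.

## What the simulator emulates — and what it does not

The simulator works at the *signal* level of an amplicon experiment: every
read covers the full reference, and each read mutates independently at
each position with a per-position probability

* `p_unpaired = 0.02` at unpaired A/C (typical DMS-MaPseq reactive-base
  fractions are in the 1–5% range),
* `p_paired = 0.002` at paired A/C,
* `p_background = 0.002` at G/U,
* binding-site positions of responders multiplied by
  `protection_factor = 0.1` when the ligand is present.

Per-position counts are drawn as Binomial(depth, p) and the mutated reads
are assigned uniformly at random without replacement — exactly the joint
distribution of independent per-read coin flips, so the per-read
mutation-count histograms are genuine rather than resampled. A fixed 10%
of mutation events are deletions (no target base); substitution targets
are uniform over the three non-reference bases. Pairing truth is supplied,
not predicted: the built-in toy generator lays out alternating stems and
loops and regenerates until the region of interest has at least 6 paired
and 10 unpaired A/C positions, so simulated profiles always carry genuine
signal variance. Planted binding sites occupy 8 unpaired A/C positions by
default — the scale of a purine-aptamer ligand pocket.

Not emulated: reverse-transcription or PCR sequence errors, read-length
variation and partial coverage, alignment and demultiplexing artifacts,
co-occurring mutation correlations from alternative conformations, and
thermodynamic folding. Tests passing on simulated data therefore
demonstrate the correctness of the statistics and the screen's operating
characteristics under the stated signal model — not robustness to upstream
artifacts in real libraries.

## Library design rules

Members are laid out as primer5 | barcode | flank5 | ROI | flank3 |
primer3 at a common total length (default 170 nt). The member sequence
begins with the forward primer verbatim and ends with the reverse
complement of the reverse primer, since the reverse primer anneals to the
transcript's 3′ end. Barcodes (default 8 nt, immediately inside the 5′
primer) are drawn by greedy rejection sampling until all pairwise Hamming
distances are ≥ 4 — the strict reading of "distance greater than 3". The
Gilbert–Varshamov bound only *guarantees* 36 such words at length 8, but
greedy maximal codes run far larger (81 barcodes take a few hundred draws
of a 500,000-draw budget); the one-call study builder therefore keeps 8 nt
up to 100 members and switches to the smallest GV-guaranteed length
beyond. Flanks are i.i.d. C/U draws regenerated whenever a run of
identical bases exceeds 3 — drawing then filtering is equivalent to
shuffling a fixed pool under the same run constraint, and simpler. Flank
lengths are computed per member to equalize total length, split evenly
5′/3′.

## Numerical choices and degenerate inputs

* Pearson r divides by matching variance terms, so sample-versus-population
  division cancels; `stats::cor` is used, and tests compare against an
  independent direct-summation oracle at 10⁻¹² relative tolerance.
* Masked propagation is strict: any statistic uses only positions unmasked
  in *all* inputs.
* Zero depth yields fully masked profiles, not errors; all-zero scaling
  targets and all-masked binding sites are errors with actionable
  messages.
* Plot CSV export formats doubles with `%.17g` (whole values keep a
  decimal point), so parsing the CSV reproduces the in-memory numbers
  bit-for-bit.
* JSON numbers are written at full precision; integers stay integers.

## Problem sizes used by the test-suite

The suite exercises the screen at the study's scale: the operating
characteristics are established on 81-member libraries with 4 planted
responders at depth 5000 across 50 simulation seeds (sensitivity and
false-positive counts both checked exactly), null behavior on a 200-member
replicate pair at depth 5000, and simulator calibration on a single member
at depth 100,000 averaged over 20 replicate samples (the standard error of
that mean, 10⁻⁴, makes the 10⁻³ bias bound a 10-sigma check at every
unpaired A/C position). Routine unit tests run on a cached 12-member
library at depth 2000.

## Known limitations

* The JSON dialect is this package's own contract; other tools' exports go
  through the converters, and only the two documented RNA-Framework-style
  count dialects are recognized.
* No background-channel subtraction and no SHAPE-style reactivity
  normalization: the model is DMS-count-based end to end.
* The screen detects *any* reproducible between-condition profile change
  below the R² threshold; it does not distinguish ligand binding from
  other causes of conformational change — that judgment needs the
  protection summaries and orthogonal evidence.
* Alternative-conformation deconvolution (EM clustering of co-mutation
  patterns) is out of scope.
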