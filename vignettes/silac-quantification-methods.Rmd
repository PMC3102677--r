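---
title: "SILAC pair quantification and differential expression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SILAC pair quantification and differential expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacquant)
```

## The measurement model

A SILAC experiment grows one cell population on ¹³C₆-Arg / ¹³C₆,¹⁵N₂-Lys
medium. After mixing, digestion and LC-MS, every tryptic peptide appears
twice in the mass dimension, separated by an exact shift determined by its
labeled residues. With at most one missed cleavage a peptide carries one
or two labeled K/R, giving exactly five shift classes (R, K, RR, RK, KK).
The package defaults to the conventional printed constants
(6.0201324 Da/Arg, 8.0142036 Da/Lys); a `"physical"` mode derives the
shifts from atomic isotope mass differences (6·Δ¹³C and 6·Δ¹³C + 2·Δ¹⁵N).
The two agree within 1e-4 Da — the printed constants presumably come from
a slightly different atomic-mass table, and the package treats neither as
more correct; the default merely reproduces the conventional deltas
bit-exactly.

The quantity of interest per pair is the relative isotope abundance
`RIA = A_L / (A_L + A_H)`, in (0, 1), with 0.5 the 1:1 point. The study
design has four sample types — forward mix (resistant light : parental
heavy), reverse mix, and two self-mix controls — each in biological
triplicate and technical duplicate (24 runs). A true abundance ratio ρ
appears as RIA ρ/(1+ρ) in forward mixes, 1/(1+ρ) in reverse mixes, and
0.5 in controls.

## Pipeline stages and the parameters that matter

**Feature building** (`build_features`). Per-scan detections of one run
are clustered into persistent chromatographic features by the transitive
closure of "same charge, masses within `ppm_tol` (default 5 ppm, the
instrument accuracy reused throughout), and within `max_scan_gap`
(default 1) missing scans". The closure is computed as connected
components of the explicit pair relation, so the result is independent of
row order; tests verify it against a brute-force closure oracle. Feature
mass is the area-weighted mean; area is the trapezoidal integral of the
trace; the scan index of a detection is the rank of its RT among the
run's distinct RTs (the grid is taken from the data, not assumed).

**Pair matching** (`match_pairs`). Ordered (light, heavy) candidates with
equal charge must have a mass difference within 5 ppm (relative to the
heavy mass, where the light/heavy distinction is < 0.1 ppm) of exactly
one class delta — a difference matching two classes at once is rejected —
and must co-elute: interval overlap of at least half the shorter feature
span (the co-elution rule is a package choice; the class deltas and ppm
figure are the method's). Conflicts are resolved one-to-one by a global
greedy pass on |ppm error|, then RT-apex distance, then feature id: a
deterministic, order-independent assignment, checked against an
exhaustive oracle. Unpaired singleton features are simply not reported;
nothing downstream uses them.

**AMT database** (`attach_ids`, `build_amt`, `filter_amt`,
`merge_technical`). Identifications attach to pairs by mass (light or
heavy channel, 5 ppm) and RT (5 min), nearest-ppm first, RT breaking
ties. Entries are keyed by (sequence, charge); shared peptides go to the
highest-scoring accession. Three exclusion rules then apply: presence in
fewer than 25% of the analyzed runs (the denominator is all 24 runs of
the design — the method text does not define it, so it is configurable),
RT span above 10 min, and mean RT inside a wash (0–10 min) or
post-gradient (>120 min) window; both windows are instrument-specific and
configurable. Filtering is idempotent and each rule's drop count is
reported. Technical duplicates of one preparation merge by arithmetic
mean of RIA when they agree within 5 ppm / 5 min; disagreeing duplicates
stay separate and are counted. Whether the original method averaged RIA
or light:heavy ratio across duplicates is unstated; arithmetic RIA mean
is used (at RIA ≈ 0.5 the difference is second-order).

**Protein rollup and trimming** (`rollup_proteins`, `trim_outliers`).
Protein RIA per sample is the mean of its peptide RIAs. Outlier peptides
are removed in a single pass: a peptide whose RIA deviates from the mean
of the *other* peptides by more than twice their SD is dropped, and the
mean recomputed. Trimming needs at least 3 peptides (the leave-one-out SD
needs two others). At small n this rule is aggressive — three evenly
spaced values flag both extremes — so removal is capped at ⌊n/2⌋, keeping
the most deviant only. The single-pass reading follows the method's
wording ("were removed … was re-calculated"); iterating would remove
more.

**Normalization** (`normalize_sample`). Each sample's protein RIAs are
normalized so their mean is 0.5, under the assumption that most proteins
are unchanged. The correction is a single multiplicative factor c in
ratio space — r maps to c·ρ/(1+c·ρ), ρ = r/(1−r) — found by monotone
bisection to |mean − 0.5| ≤ 1e-9. This is equivalent to a constant shift
of log-ratios; it preserves ranks and keeps values inside (0, 1), which
an additive RIA shift would not. Normalization is applied at protein
level by default ("for a given sample" is ambiguous about the level); a
peptide-level option exists, and neither is asserted as the original
choice. Because the mean of complements is the complement of the mean,
normalizing before or after orientation flipping is equivalent for the
0.5 criterion; the package normalizes raw samples, then flips.

**Orientation** (`orient_ria`). Reverse-mix samples enter the statistics
as 1 − RIA so forward and reverse mixes form one group. Heat-map exports
keep raw orientation, so forward and reverse lanes mirror each other as
on the published display.

**Differential testing** (`anova_protein`, `control_cutoff`,
`call_significant`). Per protein, the up-to-6 oriented mixed values are
compared with the up-to-6 control values by two-group one-way ANOVA
(F = MS_between/MS_within on (1, n−2) df), subject to the inclusion rule
of at least 3 mixed and 3 control observations. All replicate values
enter individually (grouping by replicate means is the stated open
alternative). Degenerate cases are explicit: zero within-variance with
unequal means reports the smallest representable p and a flag; identical
constant groups give F = 0, p = 1. The fold screen comes from the pooled
per-protein, per-replicate oriented control RIAs: central quantiles at
the chosen confidence (99%) give RIA bounds and the corresponding fold
cutoff. The ANOVA runs on RIA values, not log-ratios, matching the
method's inputs; p-values are used raw at α = 0.01 with the fold cutoff
as the second screen (no multiple-testing correction, deliberately — the
original analysis applies BH only to enrichment p-values).

**Downstream** (`hcluster_ria`, `enrich_terms`, `bh_adjust`).
Hierarchical clustering uses Pearson-correlation distance (1 − r,
pairwise-complete; undefined correlations get distance 1) with average
linkage — the common Gene Cluster configuration, since the original names
the program but not its settings; both are configurable, and ties merge
the lowest row indices for full determinism. Enrichment is the upper-tail
hypergeometric test per term with BH correction over tested terms; the
default universe is the quantified protein set, with a whole-annotation
universe available (the original compared against the full human GO
annotation; GO-hierarchy propagation is out of scope and annotations are
treated as flat sets).

## What the generator emulates — and what it does not

`simulate_proteome()`/`simulate_experiment()` reproduce the study design
exactly: 4 sample types × 3 biological × 2 technical runs, 1:1 mixing, a
minority of truly changed proteins, Gaussian elution peaks (SD 0.1–0.3
min) sampled on a 2-s scan grid over a 120-min gradient with a 10-min
wash, m/z 400–1400, ppm-scale mass error and minute-scale RT jitter,
random missing detections and subsampled identifications. Noise has the
replicate structure of the design: biological noise perturbs ρ once per
preparation (shared by that preparation's technical duplicates),
technical noise perturbs each channel's area per run.

Defaults chosen once, as a realistic desk-scale world: 200 proteins of
60–120 residues (≈5–10 quantifiable peptides each — enough to exercise
the ≥3-peptide rules at interactive runtimes), true changes fixed at
2-fold for 10% up and 10% down, biological log-ratio SD 0.1, technical
log-area SD 0.05, 1.5 ppm mass error (Orbitrap-class), 0.5 min run-level
RT jitter, 70% per-run detection, 60% identification, 1% wash artifacts.
Real data differ in ways the generator does not model: intensity-
dependent detection, co-eluting interference and chimeric features,
charge-state envelopes, isotope-envelope deisotoping errors, nonlinear RT
drift, and shared peptides between homologous proteins. A green test
therefore establishes that the pipeline's algebra and bookkeeping are
right under the stated noise model — not that real-instrument artifacts
are handled.

## Numerical choices and degenerate inputs

Bisection for the normalization factor brackets c in [1e-12, 1e12] and
stops at |mean − 0.5| ≤ 1e-9; ranks are preserved exactly. RIA values of
exactly 0 or 1 are rejected wherever a ratio transform is applied. ppm
errors are computed relative to the heavier mass. Pair and attachment
ties break on deterministic keys (ppm, RT distance, ids), so results are
invariant to input row order. Zero-length feature spans (single-scan
features) co-elute with a partner iff they fall inside its interval.
Empty detection tables yield empty feature tables; an empty control pool,
an empty universe, and all-missing matrix rows are errors with the
offending input named.

## Known limitations

Only two-channel SILAC with the five one-missed-cleavage shift classes is
supported; labeled-residue counting follows the fragment C-terminus
convention, so peptides whose only K/R sits before a proline count as
unlabeled and are excluded from pairing rather than matched at their
physical shift. Protein inference is the highest-scoring-accession rule
only. The ANOVA is the classical equal-variance two-group test; with
n ≈ 12 observations its p-values are approximate for non-normal RIA
noise, which the null-simulation acceptance test bounds empirically.
Cross-experiment AMT reuse (tracing peptides across time points) is out
of scope.
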