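---
title: "Methods: from differential chromatin accessibility to synthetic promoters"
author: "promforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from differential chromatin accessibility to synthetic promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promforge)
```

`promforge` implements a pipeline for sensing cell state through synthetic
promoters: find transcription-factor motifs enriched in state-specific
open-chromatin peaks, keep the motifs that replicate across independent
datasets (including across species), and compile each into a tandem-array
promoter that the corresponding factors can activate. This vignette is the
package's own account of the models, parameter choices and their limits.

## Motif model and scanning

A motif is a position probability matrix (PWM): independent per-position
base probabilities, strictly positive after a pseudocount. JASPAR files
carry counts and are normalized as `(count + pseudocount) / (colsum + 4 *
pseudocount)` with a default pseudocount of 1 per base — the conventional
regularizer; it is configurable because no single value is canonical.
Homer-format files carry probabilities already, so they are renormalized
without the count pseudocount (a 1e-6 floor is applied only to exact
zeros, to keep log-odds finite).

Scanning uses log-odds scores in bits, `log2(p / background)`, summed over
the window. The background defaults to uniform base frequencies; an
empirical mononucleotide background estimated from the user's background
peaks is available (`background_freqs = "empirical"` in
`motif_enrichment()`). Scores are discretized to integers at a scale of
1000 (0.001-bit resolution) and the *exact* distribution of the window
score under the background model is obtained by convolving the per-column
score distributions. A hit threshold for tail probability α is then the
smallest score t with P(S ≥ t) ≤ α. The default α = 1e-4 per window per
strand is a stringency comparable to common known-motif scanners; it is
deliberately a *per-window* false-positive rate, so the expected number of
background hits in a 200-bp peak scanned on both strands is about 0.04.
Discreteness means the achieved tail can sit well below α for
sharply-peaked PWMs; `threshold_for_pvalue()` reports the achieved value.
When α is below the probability of even the maximum score, the maximum
score is returned with a warning flag. Windows containing N score −∞ and
are therefore never hits — a conservative, deterministic rule.

Both strands are scanned by default (TF binding is strand-agnostic);
minus-strand hits are reported at forward-strand offsets. Peak-level
statistics use ZOOPS (zero-or-one occurrence per sequence): a peak either
contains a hit or it does not. A total-occurrence mode
(`peak_hit_counts()`) exists but does not feed the enrichment test.

## Differential peaks and enrichment

With a two-condition count matrix, `select_differential_peaks()` scales
each sample to the mean library size, forms condition means with a +0.5
stabilizer, and calls a peak state-specific when `log2 fold change >
log2(2)` and the BH q-value of a pooled two-proportion chi-square test
(with continuity correction) is below 0.05. The defaults — fold change
> 2, FDR < 0.05 — are the conventional thresholds for this kind of
analysis. Scaling to the *mean library size* rather than to a fixed
per-million unit keeps the stabilizer on the scale of raw counts for
typical libraries; with equal library sizes normalized counts equal raw
counts. The pooled two-proportion test was chosen over a replicate-aware
negative-binomial model deliberately: it is transparent, exactly testable,
and adequate for pooled-count designs; it will be anti-conservative in the
presence of strong biological replicate dispersion, which is a documented
limitation, not a target use case.

Motif enrichment forms, for each motif, the 2×2 table of peaks with and
without a hit in target vs background peaks and reports the one-sided
Fisher exact p (the hypergeometric tail), fold enrichment
`(n_t/N_t)/(n_b/N_b)` with a 0.5 Haldane correction to both hit counts
when the background count is zero, and BH q-values across the library.
Results are ordered by p, ties broken by motif id so output is
reproducible. The background peak set is the user's choice; when the
pipeline runs on simulated studies it is the matched background set. No
GC-matching or resampling of backgrounds is attempted.

A calibration note: the one-sided Fisher exact test is *conservative* on
discrete tables. At the package's default stringency a 200-peak set
typically yields single-digit hit counts per side, where the attainable
p-values are coarse; in a null simulation (no planting, identical
background models on both sides) the fraction of motifs reaching p < 0.05
is therefore well *below* 0.05 — around 0.003 at these problem sizes —
rather than equal to it. The test never exceeds its nominal level (this is
asserted as a property test); users should expect conservative, not
calibrated, p-values at small hit counts, which is the standard behavior
of Fisher's test.

## Cross-dataset intersection

`intersect_enriched()` keeps motifs significant (p < 0.05 by default) in
*every* dataset. Across homogeneous libraries, case-insensitive id
matching suffices (`by_id`, the default). Across heterogeneous libraries
(e.g. mouse JASPAR vs human Homer collections) `by_similarity` aligns
PWMs at every ungapped offset with at least 4 overlapping columns, in
both orientations, scoring the mean column-wise Pearson correlation of
probability columns; matches require similarity ≥ 0.80, a conventional
PWM-correlation cutoff. Matching is greedy best-first and one-to-one —
deterministic and adequate at motif-library scale, though not an optimal
bipartite assignment; for near-duplicate motif families the greedy choice
can differ from the optimum, which we accept for reproducibility. A flat
probability column has zero variance, so its correlation contribution is
defined as 0.

## Promoter design

For a selected motif the design is: r copies of the strict consensus site
(per-column argmax, ties broken A<C<G<T), 3-bp spacers between copies, and
a minimal core promoter downstream, on the forward strand 5'→3'. The
repeat count targets ~120 bp of total binding sites: `r =
max(1, round(120 / site_length))`, half-up. Both constants (120 bp, 3 bp)
are the package defaults and are configurable in `design_config()`.

Spacers are not arbitrary: a candidate spacer (all 64 triplets, tried in
lexicographic order) is accepted only if the assembled array contains
exactly r hits of the intended motif and no hit of any other library
motif at the screening thresholds — junction-spanning windows are real
sequence and can otherwise create spurious binding sites. If no uniform
spacer passes, junctions are filled left to right; if nothing passes, the
minimal-violation spacer is used and a warning is attached to the design.
This screening is a hardening rule of this package's own design, beyond
the bare "3-bp spacer" convention. Note that a motif whose consensus is
its own reverse complement (e.g. an E-box) hits both strands at every
site, so such designs always carry a warning — an inherent property of
palindromic sites, not a defect.

The consensus-site realization is itself a declared choice: PWMs describe
ensembles, and the single most probable word is the natural repeated unit
for a tandem array. A configuration hook (`spacer_candidates`, and
supplying literal sites via a custom `Pwm`) allows experimentally curated
site sequences instead. The default core promoter is a placeholder
carrying a commonly used ~60-bp minimal CMV fragment; anyone synthesizing
constructs should supply their validated core sequence via
`design_config(core_promoter_seq = ...)`.

`validate_design()` re-scans the finished construct (including the core)
with every library motif: hits of the design's own motif on its site
spans are `intended_hits` (r for a clean design); everything else is
`unintended_hits`. GenBank output annotates every site, spacer and core
span with 1-based inclusive coordinates; internally all coordinates are
0-based half-open (the BED convention) and the +1 conversion happens only
at serialization.

## The simulator: what it emulates and what it does not

`simulate_study()` builds K datasets of target/background peak sets with
i.i.d. mononucleotide background sequence (order-0 Markov), planting one
PWM-sampled instance per selected peak at a uniform offset and strand.
Defaults — 3 datasets, 200 peaks per side, 200-bp peaks, planting
probability 0.6 in target vs 0.05 in background — represent a desk-scale
version of a multi-model cross-species comparison with a strong,
recoverable signal. Per-dataset seeds are derived as `seed + dataset
index` so individual datasets are reproducible in isolation. Optional
count matrices give target peaks a specified fold change (default 4) over
Poisson noise, embedded among nine state-invariant filler peaks per
target peak: differential peaks must be an atlas minority or library-size
normalization absorbs the fold change (composition bias), exactly as in
real data.

What the simulator does not model: dinucleotide or higher-order sequence
composition, GC heterogeneity between peak sets, Tn5 insertion bias,
fragment-length structure, replicate overdispersion beyond Poisson, and
motif co-occurrence. Passing the planted-truth tests therefore
demonstrates correctness of the statistical machinery under the stated
model, not robustness to every bias of real ATAC-seq; on real data the
background peak choice and GC composition matter and are the user's
responsibility.

## Numerical and scale choices

Test-suite and acceptance problem sizes (200 peaks/side, 200-bp peaks, 50
null motifs × 20 replicates, widths ≤ 8 for exact enumeration) were chosen
so every oracle comparison is exact or statistically decisive while the
whole suite stays interactive. Discretization at scale 1000 bounds the
exact-distribution support (a resource guard suggests a coarser scale if
exceeded) and keeps rounding error (≤ 0.0005 bits per column) far below
any decision boundary used here. Determinism is end-to-end: identical
inputs and seeds give byte-identical reports, and the run manifest records
version, configuration and input checksums.
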