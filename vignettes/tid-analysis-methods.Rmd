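---
title: "Detecting and modeling transcription-induced domains in bacterial Hi-C maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modeling transcription-induced domains in bacterial Hi-C maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidmapper)
```

## The problem

At sub-kilobase resolution, bacterial Hi-C contact maps resolve a level of
chromosome folding below the classical 30–300 kb self-interacting domains
(CIDs): short (1–20 kb) stretches of dense contacts hugging the main
diagonal, coinciding with actively transcribed genes and operons. These
*transcription-induced domains* (TIDs, or "bundled domains") vanish when
transcription initiation is blocked with rifampicin and can be recreated at
will by a single highly expressed T7-polymerase unit. `tidmapper`
implements the computational side of that analysis as a reusable toolkit:
matrix preparation, three domain/border callers at their respective scales,
gene-anchored pileups, a generative contact model driven by RNA-polymerase
occupancy, and a synthetic-data generator so that every stage can be
exercised and validated without sequencing data.

## Contact-map model and preparation

A `ContactMap` is a symmetric `N × N` matrix of contacts between fixed-width
genomic bins (0.5–5 kb in this kind of analysis) with a bin size, genome
length, a circularity flag (bacterial chromosomes wrap; all distances and
windows here wrap with them), and a mask of invalid bins.

* **White lines.** Bins whose coverage (row sum) falls below
  `median − 3·MAD` (MAD unscaled) are masked everywhere. With MAD = 0 the
  rule degenerates to "strictly below the median"; the package warns, and a
  constant coverage track yields an empty mask.
* **ICE balancing.** Symmetric iterative correction divides each entry by
  the square root of the product of its row biases until the coefficient of
  variation of the unmasked row sums drops below `tol` (default `1e-6`,
  `max_iter` 1000). Balancing is idempotent up to a global scale factor.
* **Comparisons.** Maps are compared after downsampling to a common total
  (multivariate-hypergeometric thinning, exact total, seeded) via
  elementwise `log2((a + pc)/(b + pc))`.
* **Distance decay.** `p(s)` is the mean balanced contact over unmasked
  pairs at each circular separation `s = min(|i−j|, N−|i−j|)`; separations
  with no valid pair are filled by linear interpolation.

## Bundle (TID) calling by diagonal kernel convolution

The caller matches a fixed template against the diagonal. With 0-based
indices `i, j ∈ [0, n)` (`n = 5` by default):

$$M_{i,j} = \frac{1}{\sqrt 2}\,
  \exp\!\left(-\frac12\left[\frac{|i-j| + |n-1-i-j|}{2(n-1)}\right]^2\right)$$

The per-bin score is the kernel-weighted sum of the `n × n` window centered
on `(i, i)`. Two numerical choices matter here:

* **Masked cells inside windows are imputed with the expected contact at
  that separation** (from the map's own `p(s)`), rather than dropped and
  rescaled. Rescaling by the observed kernel mass inflates the score
  variance next to every white line — in transcription-off simulations all
  of the top spurious peaks sat 1–2 bins from a masked bin. Imputation
  keeps the noise level flat across mask edges. Bins whose own row is
  masked stay undefined.
* **Second-envelope background removal.** The first envelope anchors at
  local minima of the score, where "local" means minima over a ±2-bin
  neighborhood (the kernel half-width), and the second envelope anchors at
  the minima *of that anchor sequence* — minima of minima — interpolated
  linearly (wrapping) back to every bin. The corrected track is
  `score − E2`. Iterating on the extrema sequence rather than on the
  interpolated curve is what lets the background pass *underneath* long
  elevated plateaus: with ±1 curve-based minima, any domain wider than
  about 8 bins acquires internal anchors, the background climbs onto the
  plateau, and the domain is split at its deepest interior dip.

Peaks of the corrected track are then extended and merged:

* A **peak** is a strict-left local maximum (plateaus take the leftmost
  bin) whose corrected value exceeds the calling threshold.
* The region is **extended** in both directions while the corrected value
  stays at or above `max(peak/3, threshold)`. The one-third rule alone sets
  the extent of strong bundles; the threshold floor stops extensions of
  modest peaks from drifting through background noise, which otherwise
  widens every call by 2–3 bins and fuses clusters of nearby transcribed
  units into one region. Extensions never cross more than 2 consecutive
  masked bins.
* Overlapping extensions **merge** (the merged peak is the maximum);
  domains shorter than `min_size_bins` (default 2) are dropped.

**The peak threshold.** `call_bundles()` defaults to the median of the
corrected track, which treats peak calling as a pure ranking problem. That
is not usable as a detection rule on noisy maps: on *any* track roughly
half of all noise local maxima exceed the median, so a map with no
transcription at all still produces dozens of calls. `detect_bundles()`
therefore thresholds at `median + z·MAD` of the corrected track (scaled
MAD, `z = 5` by default). The corrected track outside bundles is a noise
floor whose robust scale the MAD measures directly; five robust standard
deviations across ~10³ bins keeps the family-wise false-call rate near
zero, which is what transcription-off controls require, while the weakest
planted single-gene domains in the validation scenarios sit 6–20 robust
SDs above the floor. `z = 0` reproduces the plain median rule.

## Border callers

**Directionality index (DI).** For each bin the vectors of
correlation-matrix values to its `w` left and `w` right neighbors are
compared with a paired t-test on `d = R − L` (sample SD):
`t = mean(d)/(sd(d)/√w)`. `|t| ≥ 2` (P ≈ 0.05) is significant; a border is
the first bin of a significant positive run that follows a significant
negative run with at most `max_gap_bins` (default 2) non-significant bins
between them. The correlation matrix is computed on the balanced map
without distance detrending (a `detrend` flag exists), and raw-contact rows
can be used instead via `use_correlation = FALSE`. DI suits 2–5 kb maps and
large domains; at 1 kb it becomes noisy, which motivates the second caller.

**Multi-window relative insulation.** For window `w`, upstream block
`U = [i−w, i)` and downstream block `D = [i, i+w)`:

$$RI_w(i) = \frac{A + B - C}{A + B + C}$$

with `A`, `B` the within-block contact sums (diagonal excluded) and `C` the
between-block sum. `RI` is bounded in `[−1, 1]`, scale-free (invariant
under uniform scaling of the map), and equals 1 at a junction with no
cross contacts. Tracks for windows 10–30 kb (defaults 10, 15, 20, 25,
30 kb at 1-kb bins) are averaged, the second envelope is removed, and
borders are local maxima at least `mean + z·sd` above the track mean
(`z = 1` by default — the threshold is a package default, not a literature
value; it is exposed and the monotonicity of calls in `z` is tested).

Border sets are compared by greedy nearest matching within a bin tolerance,
each border used at most once; interval sets are compared by unioned-kb
overlap.

## Gene-anchored pileups

Active genes are the top `fraction` by RPKM (ties broken by genomic
order); *first transcribed* genes additionally have no other active gene
in the 3 kb upstream of their start codon (strand-aware, wrapping).
Windows centered on the anchors are flipped 180° for reverse-strand genes
so all genes point the same way, and averaged per cell over the windows in
which that cell is unmasked. The window width is a parameter (default
50 kb; 100 kb is equally supported — the two scales both appear in this
literature and neither is canonical here).

The observed pileup is normalized by a pileup of control windows drawn
uniformly within ±100 kb of each anchor (one per anchor, seeded). The
ratio is computed on **raw counts**: per-bin visibility biases largely
cancel between numerator and denominator, whereas balancing actively
flattens the signal of interest — a bin inside a broad enriched block has
an elevated row sum, so ICE scales its row down and a ~3× block enrichment
survives only as ~1.5× in the balanced map.

For comparison with transcription, the pileup's adjacent-bin diagonal
profile (`matrix[k, k+1]`) is correlated (Pearson) with the averaged,
strand-reoriented RNA-seq track resampled to the same inter-bin positions.
This profile is the windowed analogue of the genome-wide short-range
signal; the profile choice is a package default since no single functional
is canonical.

## The polymerase-occupancy contact model

A ChIP occupancy track is normalized so its maximum is `ε ∈ (0, 1]`, the
single model parameter: `C_i` is the proportion of contacts at bin `i`
mediated by polymerases, `1 − C_i` the proportion mediated by everything
else. Two hypotheses give the expected contact between bins `i` and `j` at
separation `s`:

* **Variant 1** (polymerase–polymerase preference):
  `p(s) · (C_i C_j + (1 − C_i)(1 − C_j))`
* **Variant 2** (consecutive polymerases; intervening polymerases act on
  the pair): `p(s) · (m · C_i C_j + (1 − C_i)(1 − C_j))` with
  `m = Σ C_k` over bins strictly between `i` and `j` (taken along the
  shorter arc on circular genomes; `m = 0` for adjacent pairs).

The `m` factor is implemented *as printed* in its source, where it
multiplies — and hence amplifies with intervening occupancy — the
polymerase term, even though the verbal description of the mechanism is
insulation; `insulation_form = "reciprocal"` substitutes `1/(1 + m)` for
users who want the literal insulation reading. The model map is normalized
to a doubly stochastic matrix (symmetric Sinkhorn scaling; every row and
column sums to 1) so entries are contact probabilities.

**Fitting ε.** A grid search (default 0.01–1.00 in steps of 0.01)
maximizes the Spearman rank correlation between model and observed maps
over unmasked upper-triangle pairs within a maximum separation (default
200 kb; the modeled signal is local). Two details determine whether the
fit can actually recover a known ε:

* *What is normalized.* The separable factor `(1 − C_i)(1 − C_j)` is a
  row/column scaling, and doubly-stochastic normalization removes exactly
  such scalings — from the model *and*, via ICE, from the observed map. A
  balanced-vs-normalized comparison therefore sees only the non-separable
  `m` structure, which at a realistic 2×10⁶-contact depth is far below the
  rank noise. `fit_epsilon()` hence has a `normalize` mode: given a raw
  count map it ranks raw counts against the unnormalized model expectation
  (keeping the full occupancy signal; this recovers planted ε to ±0.02 at
  that depth), and given a balanced map it normalizes both sides — the
  right comparison when only a balanced map exists, with the caveat that ε
  is then only weakly identified unless the map is deep.
* *The argmax.* The correlation curve has a flat, slightly noisy top, so
  the raw grid argmax jitters by a few grid steps. `best_epsilon` is the
  grid value nearest the vertex of a tricube-weighted quadratic fit to the
  curve within ±5 grid points of its maximum (boundary maxima are never
  refined). `best_spearman` is the curve's maximum.

`compare_variants()` runs both variants on the same inputs and returns both
fits for model selection.

## 1D track utilities

Block binning (mean or sum, partial trailing block aggregated over its
actual length), z-transformation (sample SD; population-SD flag), the
short-range Hi-C signal (`map[i, i+1]`, wrapping), circular Gaussian blur
(σ given in bp and converted by the bin size; kernel truncated at 4σ and
renormalized so total signal is conserved; the reference use is GapR ChIP
at σ = 2500 bp), and Spearman correlation between tracks over common
unmasked bins (average ranks on ties).

## The synthetic-data generator

`make_scenario()` fixes a seeded study condition; `simulate_map()` realizes
it. The generator emulates the statistical structure the analysis assumes —
it is the package's test bed, not a biophysical simulation.

* **Genome.** 1 Mb circular, 1-kb bins by default.
* **Genes.** 100 non-overlapping TUs, lengths log-uniform on 1–20 kb
  (the documented TID size range; log-uniform favours short genes as real
  annotations do and keeps the layout feasible at ~63% occupancy), placed
  with broken-stick random gaps; log-normal expression
  (`meanlog 3, sdlog 1.5`, RPKM-like); the top 10% by expression are
  *active*. `rifampicin = TRUE` zeroes all native expression.
* **Occupancy.** Proportional to expression within each TU, plus an
  optional T7 unit: an exponentially decaying track (decay length = ⅓ of
  the 110-kb track length) from its promoter, amplitude twice the
  strongest native gene; the whole track is scaled so `max = ε_true`
  (default 0.15).
* **Expected map.** `p(s) = (s+1)^{-1}` (shifted power law; any positive
  decreasing decay is accepted) times the variant-2 weight of the
  occupancy track, times a plaid factor `1 + κ·a_i·a_j·[s ≤ 25 kb]`
  (`a` = active-bin indicator, κ default 2.5 so that an active TU's
  diagonal block sits ≈3× above background after the mild variant-2
  depletion — the enrichment regime the callers are specified for), and,
  when large domains are configured, a within-domain factor
  `1 + κ_dom·[same domain]`.
* **Counts.** The expectation is scaled to 2×10⁶ total contacts, the upper
  triangle is Poisson-sampled and mirrored, and 10 random bins are zeroed
  and masked as white lines.
* **Truth tables.** Planted TID intervals (active TUs, with back-to-back
  TUs separated by <2 bins recorded as one domain — no caller could
  separate them), domain boundaries, the occupancy track and `ε_true`.

What the generator does *not* emulate: reproducible per-bin visibility
biases (GC, mappability), the plaid's dependence on transcription timing,
loop extrusion, long-range compartment structure, replication asymmetry,
and read-level artifacts. Passing the validation suite therefore
demonstrates that the algorithms recover the structures they target under
realistic Poisson sampling noise and masking — not that any particular
biological map will show those structures.

## Validation experiments and problem sizes

The test suite validates each stage against either an independent oracle
(direct formula evaluation, textbook paired t-test, brute-force
convolution and weight double-loops) or a seeded simulation truth:

* Bundle caller: 20 planted TIDs (1–20 kb) on a 1 Mb / 1-kb map at 2×10⁶
  contacts; recall ≥ 0.9, precision ≥ 0.8 at ≥50% reciprocal overlap.
  Transcription-off maps (with and without a T7 unit): no calls outside
  the T7 track.
* Border callers: 8 planted domains (≥50 kb); DI at 5-kb bins (100-kb
  window) and insulation at 1-kb bins both reach border F1 ≥ 0.8 at ±2
  bins.
* Model fit: 20 simulations with ε* ∈ {0.10, 0.15, 0.30} at 2×10⁶
  contacts; ε recovered within ±0.02, and variant 2 outscores variant 1 on
  variant-2-generated data in ≥18/20 runs. The recovery experiment feeds
  the generator's decay law (estimating `p(s)` from the same map folds the
  average polymerase depletion into `p` and double-counts it) and
  correlates within 120 kb, the T7 track scale.
* Pileups: 500 random anchors on a transcription-off map reproduce the
  `p(s)` Toeplitz window within 5% per diagonal; the TSS pileup ratio
  shows ≥1.5× enrichment in the first downstream near-diagonal cells with
  distal background within [0.9, 1.1].

These sizes (1000-bin genomes, 10²–10³-pair oracles, 20-run recovery
loops) keep the full suite in the tens of minutes on a single core while
leaving each check's statistical margin wide.

## Known limitations

* The bundle caller's resolution floor is the kernel width: a 1–2-bin
  domain is reported as ≈4 bins.
* Very long enriched plateaus (≳35 bins) can still split at a deep
  interior dip despite the extrema-sequence envelope.
* ε is weakly identified from balanced maps at moderate depth (see the
  model section); the package states this rather than hiding it, and uses
  raw maps when it can.
* The DI caller's run-joining (`max_gap_bins`) and the insulation z-cutoff
  are defaults without a literature anchor; both are exposed.
* `cool` input is not supported; dense and triplet TSV (plus bedgraph/BED
  for tracks and genes) are the interchange formats.
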