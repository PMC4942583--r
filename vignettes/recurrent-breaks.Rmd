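---
title: "Detecting recurrent copy-number breaks: model, defaults and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recurrent copy-number breaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(breakrec)
```

## The model

A cohort of tumour copy-number profiles is a samples × probes matrix of log2
ratios aligned to a genome-ordered marker map. Driver aberrations recur at
the same loci across samples; passengers do not. Rather than testing for
recurrently amplified intervals, this package tests for recurrent *breaks* —
transitions from neutral to gain or gain to neutral — in the cohort
aggregate. Gains and losses are split first (`split_gains_losses()`, keeping
`max(x, 0)` and `max(-x, 0)` respectively) and processed identically; every
statement below about gains applies to mirrored losses.

The per-probe sum over samples is the aggregate profile. At a boundary $b$
(between the probes with genome order $b-1$ and $b$) and a scale pair
$w = (w_L, w_R)$ in probes, the break-recurrence score is the difference
between the mean aggregate in the $w_R$ probes right of the boundary and the
mean in the $w_L$ probes left of it. Many co-located neutral-to-gain breaks
push this difference up; the score is deliberately *not* variance
standardised — it is the jump height a piecewise-constant fit would take, and
the permutation null absorbs the variance.

**Null model.** Each sample's profile is rotated by an independent uniform
offset along the concatenated genome (`cyclic_shift()`). Break positions
become independent across samples while all within-sample structure
(chromothripsis-like clustering, event widths, value marginals) is retained.
The observed cohort is, for passenger breaks, exchangeable with this
ensemble up to two edge effects discussed under Limitations.

**Significance.** For a scale pair and threshold $t \ge 0$, the Euler
characteristic of the score track is the number of maximal stretches with
score $\ge t$ plus the number with score $\le -t$, counted within
chromosomes (`euler_characteristic()`). Its expectation under the null,
$E[\chi_t]$, estimated by `estimate_euler_curves()`, is the significance of
an observed score $t$: it is the expected number of places in the whole
genome where the null reaches what was observed, so small values are
significant, and it directly bounds counts of false-positive calls rather
than per-probe error.

**Segmentation and calling.** `segment_genome()` starts with one segment per
probe and repeatedly merges the adjacent pair whose boundary is least
significant (largest $E[\chi]$ evaluated at the boundary's jump and the two
segment widths), rescoring only the two neighbouring boundaries after each
merge, until every remaining boundary has $E[\chi] \le E$. A lazy-deletion
priority queue keeps this $O(P \log P)$. Segments bordered by a positive
jump on the left and a negative jump on the right are called
(`call_local_maxima()`). Since a called region consumes a positive and a
negative excursion, $E/2$ is the nominal bound on the expected number of
false-positive calls, and `adaptive_threshold()` adapts $E$ to a requested
region-level FDR: starting from $E = 2 \cdot \mathrm{fdr}$, set
$E \leftarrow n \cdot 2 \cdot \mathrm{fdr}$ for $n$ called regions until $n$
is stable (with FDR 0.25 and a stable count of 100 the iteration settles at
$E = 50$). Because driver breaks sit inside the permutation null and make it
conservative, `refine_null()` deletes sample-level breakpoints falling in
called break windows (replacing the flanking runs by their length-weighted
mean) and the pipeline re-estimates the curves, up to
`max_null_refinements` times or until the region count converges.

## Parameters that matter

* `fdr` (default 0.25): target region-level false discovery rate; the only
  scientific tuning parameter.
* `n_perm` (default 100; 50 in the desk-scale studies): cyclic-shift
  permutations per curve estimation. Tail values of $E[\chi]$ near the
  decision region carry Poisson noise of order `1/n_perm`, smoothed by the
  isotonic and tail fits.
* `scale_grid`: geometric, `1, 2, 4, ...` capped at P/4 and at half the
  longest chromosome; curves are estimated for every unordered pair. Scales
  are probe counts, so physical resolution follows probe spacing.
* `threshold_grid`: `0` plus 24 geometrically spaced values reaching 5%
  above the largest observed |score| over the equal-scale tracks. Geometric
  spacing matters: observed jumps span orders of magnitude once selection
  drives loci to high copy number, and a linear grid would waste almost all
  its resolution on the largest jump.
* `max_region_width` (default 10 Mbp) and `require_gene_overlap` (default
  on when genes are supplied): the reporting filters; very broad or
  gene-less regions are uninformative for driver hunting.
* `refine_margin` (default 0 probes): half-width of the deletion window
  around a called break during null refinement. With the default, only
  sample breakpoints falling in the boundary's own inter-probe interval are
  deleted; on realistic probe grids sample breakpoints rarely coincide with
  it, so refinement is typically inert unless a margin of the order of the
  aberration width (hundreds of probes) is chosen. The conservative default
  was kept because the appropriate window is data-dependent.

## The simulator

`simulate_cohort()` evolves each sample from a diploid clone through
`rounds = 20` rounds; each round spawns `descendants = 100` clones, each
acquiring `n_aberrations = 10` random aberrations, and promotes the clone
with the highest proliferation score — the sum over driver genes of a normal
coefficient (sd `coeff_sd = 1`) times the length-weighted mean copy-number
fold change $2^{\text{log2 ratio}}$ over the gene body (a diploid genome
scores the coefficient sum; a fully +1-covered gene doubles its term).
Positive coefficients behave as oncogenes, negative as tumour suppressors.
With `descendants = 1` there is no selection and the model degenerates to
passenger-only accumulation.

Aberration widths follow a parametric stand-in for empirical tumour event
sizes: focal events with log-uniform widths between 10 kb and 10 Mb
(probability 0.9) mixed with broad events whose width is a uniform 25–50%
fraction of the chromosome, all placed uniformly; magnitudes are exponential
with mean 0.35 in |log2 ratio| and a fair amplification/deletion coin. Broad
events are intentionally *not* pinned to fixed arm boundaries: with fixed
arms, every tenth passenger event would break at exactly the same
mid-chromosome base pair, so even selection-free cohorts would carry a
genuinely recurrent break — passenger breaks would no longer be exchangeable
and no permutation scheme could control them. The price is that the
simulator does not reproduce the centromere-anchored arm events of real
karyotypes; real-data users should expect recurrent centromeric breaks to be
called and to require annotation-based post-filtering.

The default study genome is 3 chromosomes × 100 Mb at 3 kb probe spacing
(100,002 probes), a desk-scale stand-in for a human-sized genome
(`genome_model_human()` exists for realistic coordinates). Benchmarks
(`benchmark()`) draw a fresh gene set (300 genes, lengths log-uniform
5–500 kb), pick 20 drivers, simulate cohorts, run the full pipeline and
score driver recovery with `compute_metrics()`. Unbounded accumulation (no
copy-number cap) plus linear selection on exponential fold changes produces
winner-take-all dynamics: the largest-coefficient oncogenes are amplified
round after round and reach very large fold changes, while weak drivers stay
near passenger level. This matches the qualitative "few strong recurrent
loci plus broad noise" structure of real cohorts but makes recovery of *all*
planted drivers impossible at small cohort sizes — recall figures from this
simulator are conservative.

## Numerical choices

* Curve cleanup: per scale pair, the Monte-Carlo means are made
  non-increasing in $t$ by antitonic isotonic regression; `significance()`
  interpolates log values linearly in $t$ within the grid (so grid lookups
  reproduce the tabulated values) and, beyond the last threshold with a
  positive tabulated mean, extrapolates with the fitted Gaussian-style tail
  $\log E[\chi] = a - b t^2$ ($b > 0$, least squares on the upper half of
  the positive grid points), spliced continuously. Across scales the
  evaluation interpolates bilinearly in $(\log w_L, \log w_R)$ over the
  symmetrised grid; out-of-grid scales are clamped to the grid range
  (segments wider than the largest scale are routine and their clamped
  significance errs conservative, since wider null windows fluctuate less).
* Ties during merging resolve to the leftmost boundary; with that rule the
  segmentation is fully deterministic, as is everything else given `seed`
  (both directions derive their permutation offsets from the same seed,
  which is what makes the gains calls on a matrix and the losses calls on
  its negation mirror exactly).
* Degenerate inputs: chromosomes shorter than a window contribute no track;
  single-probe chromosomes return one boundary-less segment; an all-zero
  direction yields one segment per chromosome and no calls; `E = Inf`
  accepts the per-probe segmentation unchanged, since every boundary is then
  already "significant" under the merge-termination rule.
* Region coordinates run from the first base of the segment's first probe
  to the base before the first probe after the segment (half-open);
  chromosome-terminal segments end one base past their last probe. Terminal
  segments count as local maxima when their single internal jump points
  uphill into them — telomeric amplifications are real calls.
* SEG files are 1-based inclusive on disk; everything internal and BED is
  0-based half-open.

## Problem sizes used by the tests

The acceptance suite runs the calibration and benchmark studies at the
package's default desk scale: 500 passenger-only cohorts of 20 samples for
the false-positive calibration, three 100-sample driver cohorts for the
measured FDR, 200 simulated samples for the selection check, and oracle
comparisons (brute-force Euler counting, an $O(P^2)$ reference clusterer,
exhaustive offset enumeration) at up to a few hundred probes.

## Known limitations

* **The nominal $E/2$ bound is exceeded at aggressive thresholds.** The
  bound reasons at a fixed scale pair, but the agglomerative segmentation
  evaluates boundaries at adaptively grown segment widths, effectively
  searching several octaves of scale; each fixed scale contributes its own
  expected sub-threshold excursions. In the package's 500-replicate
  passenger calibration (test suite and acceptance script), the mean number
  of regions called at the fixed initial threshold $E = 0.5$ exceeds the
  nominal 0.25 severalfold. The effect is independent of the permutation
  count and of the aberration mixture, and each reported significance is
  individually honest (they match direct re-permutation at the called
  boundary's exact scale); it is the scale-space multiplicity that the
  single-scale bound does not cover. In the full pipeline the practical
  consequence is small: the spurious null calls are arm-scale broad and are
  removed by the 10 Mbp width filter, and the measured FDR on driver
  cohorts at a 25% target stays well below it — but the intermediate
  per-threshold guarantee should be read as approximate, not exact.
* Whole-genome rotation can wrap an event across a chromosome boundary,
  splitting it in the null ensemble while observed events never straddle
  chromosomes; at desk scale (3 chromosomes, broad events up to half a
  chromosome) this makes the null slightly optimistic at the largest
  scales. Rotating within chromosomes would remove the effect but weaken
  the "single offset per profile" exchange argument.
* Curve estimation is data-driven; two runs with different seeds differ
  within Monte-Carlo error, and calls with significance near the final
  threshold can flip between seeds at small `n_perm`.
* The simulator emulates recurrence structure, not measurement: no probe
  noise, no purity/ploidy distortion, no whole-genome doubling, no
  subclonality. Passing tests say the method behaves as designed under the
  model's assumptions, not that those assumptions hold for any given
  platform.
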