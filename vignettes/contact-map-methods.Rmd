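---
title: "Methods: differential contact-map analysis of yeast Hi-C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential contact-map analysis of yeast Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rablhic)
```

This vignette documents the statistical machinery of `rablhic`: the models
and procedures, the parameters that matter and their defaults, what the
synthetic generator does and does not emulate, and the numerical choices
made where conventions differ between tools.

## Coordinate frame and data model

All coordinates are 0-based, half-open `[start, end)`, matching BED and
BEDPE. A genome is a `GenomeModel` (ordered chromosomes with lengths and
point-centromere midpoints); a `BinTable` tiles each chromosome with
fixed-width bins, the last bin truncated at the chromosome end; a
`ContactMatrix` stores the upper triangle (`i <= j`) of a symmetric map
over the single genome-wide bin index space, so intra- and
inter-chromosomal queries use one structure. Internally bin indices are
1-based (R convention); triplet files may be 0- or 1-based, controlled by
`index_base` (default 1, the HiC-Pro convention — pipelines differ and the
files themselves do not say, so the reader takes a flag).

A point centromere (~120 bp in *S. cerevisiae*) is assigned to exactly one
bin by its midpoint; a midpoint sitting on a bin boundary belongs to the bin
starting there, the deterministic consequence of the half-open convention.

## Depth equalisation

Comparing maps of unequal sequencing depth confounds every count-based
statistic, so libraries are first sampled down to the depth of the
shallowest one. `downsample_counts()` draws `target` read pairs without
replacement from the binned counts — a multivariate hypergeometric draw,
implemented by sampling positions in the cumulative count vector. At the
matrix level this is exactly equivalent to subsampling valid pairs before
binning, which keeps the toolkit alignment-free. The draw is seeded and the
seed is recorded by the CLI's provenance file.

## ICE balancing

`ice_balance()` implements iterative correction with multiplicative per-bin
biases: at each step the bias-corrected marginals `m_i` are computed and
`b_i <- b_i * m_i / mean(m)` until the coefficient of variation (CV) of the
unmasked marginals drops below `tol`. Defaults: `tol = 1e-5`,
`max_iter = 200`, `low_coverage_fraction = 0.02` (the 2% lowest-coverage
bins, plus any empty bin, are masked before iterating), diagonal included
in marginals. These are common ICE practice; all are exposed as arguments
because the convergence rule and masking fraction are rarely reported by
studies and plainly affect sparse yeast matrices. On noisy maps the CV
tolerance of `1e-5` may not be reached within 200 iterations; the result is
still returned, flagged, with a warning — the remaining marginal spread is
then typically below `1e-4` and immaterial for the downstream statistics.
Balanced values are `M_ij / (b_i b_j)`, rescaled so stored balanced entries
have mean 1; the rescale makes the output invariant to global rescaling of
the input.

## Distance decay, CP ratio, SVL

`contact_probability()` reports the mean contact value per distance
stratum over all intra-chromosomal bin pairs — absent cells count as zero,
the divisor is the total number of pairs at that distance, and the diagonal
is excluded. Default strata are single bins up to 50 kb and 1.12-fold
log-spaced boundaries beyond, a compromise between resolution where yeast
maps are information-rich and variance control at long range; `strata =
"bin"` gives the raw per-bin curve used for exponent fitting. The log2 CP
ratio curve drops (and counts) strata where either curve is zero.

Because each condition is depth-normalised, a fold change planted in one
distance band shifts the whole ratio curve slightly: the curve is flat at
two levels whose *contrast* is the planted fold. The tests assert exactly
that contrast.

The SVL ratio per chromosome is the summed contact value at distances
`0 < d < L` over the sum at `d >= L`, `L` = 100 kb by default; a distance
of exactly `L` counts as long (an arbitrary but fixed and documented
tie-break). Chromosomes shorter than `L` get a missing ratio with a
warning; a chromosome with no long-range mass reports `Inf` with an
`all_short` flag rather than silently dropping.

CP and SVL accept raw downsampled or ICE-balanced matrices; which a study
used is often unstated, so both work and the choice is the caller's. The
package's own acceptance pipeline runs them on raw downsampled counts,
where the generator plants no per-bin bias and balancing is a no-op in
expectation.

## Wilcoxon rank-sum testing

`wilcoxon_rank_sum()` is a thin wrapper over `stats::wilcox.test` that
selects the exact enumeration when `n_x + n_y <= 12` with no ties and the
tie- and continuity-corrected normal approximation otherwise, and records
which method was used. The exact branch is verified in the tests against an
independent `combn()` enumeration of all labelings.

## CEN–CEN pile-ups

For every unordered pair of centromere-bearing chromosomes the
inter-chromosomal block centred on the two centromere bins and spanning
±`flank` (default 50 kb at 1-kb bins — centromeres are small enough that
1 kb is the natural resolution) is extracted, symmetrised by averaging with
its transpose, and averaged cell-wise across the 120 pairs. Unordered pairs
with transpose-symmetrisation make the estimate orientation-free; averaging
240 ordered blocks would weight identically. Cells extending past a
chromosome end are missing *for that pair* and the cell-wise mean divides
by the per-cell count of contributing pairs — silent zero-padding would
bias edges for centromeres closer than `flank` to a telomere (none in
sacCer3 at 50 kb, but true for other flanks and genomes).

Quantification takes the central `side x side` window (default 5, n = 25
values) and compares conditions by `mean(control) / mean(depleted)` with a
one-sided rank-sum test; the direction of the fold is explicit in the
result, because "reduced 1.6-fold" is ambiguous without it.

## O/E transformation and loop detection

The expected value at distance `s` is the per-chromosome mean contact at
`s` (absent cells zero); O/E is observed over expected, and per-distance
O/E means are 1 by construction — an identity the tests assert. O/E has no
meaning across chromosomes, so inter entries are dropped.

`detect_loops()` scores every pixel in a distance band by the Pearson
correlation between an odd square kernel and the local `log2(O/E + 1)`
patch. The log tames the multiplicative noise of ratio values and `+1`
keeps observed zeros finite; since Pearson correlation is invariant to
shift and scale of the patch, a patch exactly equal to the kernel (plus any
offset) still scores 1. The default kernel is a 7 × 7 Gaussian bump
(sigma = 1 bin) minus its mean — a generic dot detector, deliberately not a
reproduction of any trained kernel bank, and pluggable: matching the kernel
sigma to the expected loop footprint in *bins* matters, e.g. a 9 × 9,
sigma = 2 kernel for ~2-kb-wide loops at 1-kb bins, but sigma = 1 for the
same loops at 2-kb bins. Candidates need `score >= score_min` (default
0.4) and centre O/E above `min_center_oe` (default 1 — a loop must at least
be enriched); greedy non-maximum suppression then removes calls within
Chebyshev distance `nms_radius` (default 3 bins) of a stronger call.
Detection is fully deterministic: stable ordering by score, then
coordinates. At `score_min = 0.5` the null correlation distribution over
~50-80-cell patches puts single-pixel false positives below ~1 per 10^5
candidates after suppression; the package's validation runs use that
operating point, at which planted-loop precision and recall both exceed
0.9 at realistic depth.

`quantify_loops()` scores each anchor as the mean balanced value in a
`(2r+1)^2` box and classifies the depleted/control fold at 1.5: `up`,
`down` (below the reciprocal), or `marginal`. Swapping conditions maps
folds to reciprocals and swaps the classes exactly. `score_region()`
applies the same scores to every bin pair of an interval, with quartile
groups cut at the 25/50/75 percentiles of the treated condition's scores
(boundary values to the lower group, for determinism; the condition used
is switchable) and arc classes at >2- and >1.5-fold, a zero control score
with positive treated score counting as >2-fold.

## Reproducibility statistics

`scc()` smooths both maps with a `(2h+1)^2` mean filter clipped to the
chromosome block (absent cells zero, divisor the in-range cell count),
pools intra-chromosomal cell pairs genome-wide per distance stratum up to
`D`, and combines per-stratum Pearson correlations `r_s` with weights
`N_s * sd1_s * sd2_s`; constant strata carry zero weight. Defaults `h = 5`
bins and `D = 100` kb are typical for high-resolution maps; genome-wide
pooling (rather than per-chromosome averaging) keeps the statistic stable
on the small yeast chromosomes and is switch-free by design — the
per-stratum table is returned for anyone wanting a different combination.
`scc(A, A)` is exactly 1, and the statistic is symmetric and scale
invariant. `pearson_matrices()` correlates the union of nonzero cells
(absent cells zero), intra plus inter.

## The synthetic generator

`simulate_pair()` draws independent Poisson counts per upper-triangle cell
from a multiplicative rate model:

* intra: `c_intra * ((s + s0)/binsize)^-alpha`, times a peri-centromeric
  Gaussian (amplitude `peri_amp`, width `peri_sigma`), times planted loop
  bumps `1 + (strength - 1) * exp(-(dx^2 + dy^2)/(2 sigma_loop^2))`;
* inter: `c_inter * (1 + (kappa - 1) * g_i * g_j)` with
  `g = exp(-d_cen^2 / (2 sigma_cen^2))`, so the exact CEN–CEN centre sits at
  `kappa` times the background.

Rates are scaled per condition so the expected total equals `depth`; the
depleted condition differs only through configured folds (`kappa_fold` on
the clustering amplitude, per-loop folds applied as a flat window around
the anchors, optional decay-band folds). Inter-chromosomal counts are drawn
by Poisson superposition — a uniform background process plus a
CEN-proximity-weighted enrichment process — which gives exact per-cell
Poisson rates without enumerating the ~67 million inter cells.

Defaults of the study-scale configuration (`saccer3_config()`) were fixed
once, by a power calculation on the Poisson information available at depth
5 × 10^6 per condition, before any recovery was run: `alpha = 1.5`,
`s0 = 5` kb (yeast CP curves flatten below ~10 kb), `c_intra = 1`,
`c_inter = 7e-5` (about a third of the mass inter-chromosomal, the
Rabl-typical regime), `kappa = 4` with `sigma_cen = 10` kb, 20 loops with
anchor separations 5–14 kb (the short-range cohesin-loop regime; at these
separations an anchor box carries several hundred counts, enough to
classify a 1.6-fold change against a 1.5-fold threshold with ~90% per-loop
power), `strength = 3`, `sigma_loop = 2` kb, `kappa_fold = 0.625` (4 →
2.5, which implies a ~1.6-fold central-window reduction — the headline
effect size the pile-up quantification should recover), `loop_fold = 1.6`
applied as a flat ±6-kb window so a box mean is an unbiased fold estimate.
The per-condition depth renormalisation perturbs planted folds by under
0.5%.

What the generator emulates: power-law decay, flat inter background,
multiplicative centromere clustering, planted dot loops,
condition-specific folds, Poisson counting noise at configurable depth.
What it does not: per-bin coverage biases (so ICE is exercised by its own
oracle and invariance tests, not by the recovery pipeline), overdispersion
beyond Poisson, cell-cycle mixtures, telomere tethering, rDNA
sequestration, and real CAR positioning. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to every artefact of real libraries.

## Validation tiers and problem sizes

The test suite checks, in increasing order of integration: exact constants
(bundled sacCer3 table, window cell counts); oracle equivalence (ICE vs a
hand-iterated 2 × 2 oracle at 1e-10, exact Wilcoxon vs full enumeration,
mean-filter impulse response); analytic identities (self-ratio maps zero,
self-SCC 1, O/E stratum means 1, constant pile-ups, SVL scale invariance);
and planted-parameter recovery on the 16-chromosome configuration at depth
5 × 10^6 — the decay exponent within 0.1, the clustering amplitude within
5% on noiseless expected matrices, the central-window fold within 0.05 in
log2 (averaged over 24 simulated pairs, sized so the seed-to-seed standard
error ~0.027 sits well inside the band), loop precision/recall ≥ 0.9, and
≥ 90% of planted 1.6-fold gains classified up. Null configurations must
keep the mean log2 ratio within ±0.02 and the rank-sum type-I error at or
below 10% at nominal 5%. Determinism is asserted at bit level for
simulation and loop calling. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities from scratch with
twelve pairs, which keeps a full run around two minutes on one core.

## Known limitations

* ICE convergence at `tol = 1e-5` is slow on very sparse maps; the warning
  is informative, not fatal.
* Loop detection quality depends on matching the kernel width to the loop
  footprint in bins; the default 7 × 7 sigma-1 kernel is a reasonable
  generic choice at 1–2-kb bins but is not trained on data.
* `pearson_matrices()` over the union of nonzero cells is negatively biased
  for very sparse, weakly overlapping maps (absent-in-one cells are zeros);
  SCC is the better-behaved reproducibility statistic and the one to
  prefer.
* The quantile grouping of `score_region()` does not reproduce any
  particular study's unstated interaction filter; `min_score` exposes the
  knob.
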