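---
title: "Crosswise association testing of genomic region sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crosswise association testing of genomic region sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosswiser)
```

## The model

A *region set* is a list of genomic intervals on a reference genome, stored
here as a tibble with columns `chrom`, `start`, `end` in 0-based half-open
(BED) coordinates — the convention is used everywhere internally, so BED I/O
is lossless and touching intervals never count as overlapping. Strand is
ignored throughout: the statistics below are strand-free.

Given a query set $A$ (with $n$ regions) and a target set $B$, the
permutation test draws `n_perm` randomized replicates $A^{(1)}, \dots,
A^{(P)}$ of $A$ under a chosen null model, evaluates an association
statistic $s(A^{(k)}, B)$ for each, and summarizes

$$ZS = \frac{s(A, B) - \widehat\mu}{\widehat\sigma}, \qquad
  nZS = \frac{ZS}{\sqrt{n}},$$

where $\widehat\mu, \widehat\sigma$ are the empirical mean and standard
deviation of the null sample. The $\sqrt{n}$ normalization matters because
for counting statistics both the observed value and the null spread scale
with $n$ in a way that leaves $ZS \propto \sqrt{n}$ for a fixed strength of
association; dividing it out makes cells of different sizes comparable and
stabilizes results computed on subsamples of large sets (verified as a
simulation property in the test suite: across subsample sizes 25–100 the raw
ZS grows monotonically while the coefficient of variation of nZS across
sizes is smaller than that of ZS).

The test is one-sided with automatic direction: "greater" when the observed
value is at least the null mean, "less" otherwise. The p-value carries a +1
pseudocount, $p = (1 + \#\{s^{(k)} \ge s_{obs}\})/(P + 1)$ (mirrored for
"less"), so it is never zero and its floor is $1/(P+1)$. When the null
sample is degenerate ($\widehat\sigma = 0$, e.g. a constant custom statistic
or an identity randomization) ZS and nZS are reported as `NA` rather than
$\pm\infty$; the p-value is still computed from counts, and matrix assembly
renders such cells as 0 with an unset significance mask.

For distance-like statistics (smaller = more associated) the reported nZS
sign is flipped so that positive always means "more associated than
expected"; the raw ZS keeps its natural sign.

## The crosswise design

`crosswise_permtest()` runs the all-against-all design: each RS1 element is
randomized **once** — its `n_perm` replicates are generated before any
evaluation — and every replicate is evaluated against all RS2 elements.
Randomization is the expensive step, so this amortization makes a
$k_1 \times k_2$ matrix cost roughly $k_1$ pairwise tests instead of
$k_1 k_2$. P-values are adjusted jointly across all cells with
Benjamini–Hochberg by default (`adjust_method` accepts any
`stats::p.adjust` method); whether adjustment should span the whole matrix
or each RS1 row is a genuinely open choice, so both are offered
(`adjust_scope = "global"` is the default — in a discovery screen every cell
is a hypothesis, and global control is the conservative reading).

Seed discipline: a master seed is expanded into one child seed per RS1
element (`child_seed(master, i)`), and the per-element stream generates the
optional subsample followed by all replicates. Evaluations consume no
randomness, so the result is invariant to the order of RS2, and any single
cell can be reproduced exactly by `permutation_test(..., seed =
child_seed(master, i))`. Subsampling (uniform, or score-based via
`filter_top_regions()`, which keeps the upper quartile by score and then
samples) happens once per RS1 element *before* randomization, never per
permutation — the subsampled set is the unit that is permuted, and its count
is the $n$ in $nZS$.

## Null models

Three randomization strategies are built in; custom ones can be registered
(`register_randomization()`) and are validated against the contract (same
region count, on-genome) at first use.

* `resample_regions` — draw $n$ distinct members of a *universe* set without
  replacement, uniformly. The right null when a natural candidate pool
  exists (e.g. the merged peaks of all experiments under comparison). Under
  this null the count-once overlap statistic has the hypergeometric mean
  $nK/|U|$, $K$ being the number of universe members hitting the target —
  asserted empirically in the tests.
* `resample_genome` — partition every chromosome into consecutive
  non-overlapping tiles of width `round(mean(width))` (the final partial
  tile is discarded; on the demo genome at width 100 this gives
  36,000 tiles) and sample $n$ tiles without replacement. The tiling rule is
  not dictated by the statistic itself; this implementation follows the
  simplest deterministic reading and is isolated in one function so it can
  be swapped.
* `randomize_regions` — re-place every region with its width preserved.
  The target chromosome is drawn with probability proportional to its count
  of valid start positions ($\mathrm{len} - w + 1$), which makes placement
  uniform over the genome rather than uniform over chromosomes;
  `per_chromosome = TRUE` keeps each region on its own chromosome and
  `non_overlapping = TRUE` rejection-samples (cap 1000 attempts per region)
  until placements are disjoint.

Circular/rotational randomization and mask-aware placement are not
implemented; the contract-checked registry is the extension point.

Two evaluation statistics are built in — `num_overlaps` (count-once, the
default; also available as total pairs via `num_overlaps_pairs`) and
`mean_distance` — and custom ones register with a direction flag. Nearest
distances are defined within a chromosome; a query region on a chromosome
with no target regions yields `NA` and is excluded from `mean_distance`
with a warning.

## Local Z-score profiles

`multi_local_zscore()` re-evaluates the observed statistic after translating
the focal set by every multiple of `step` within $\pm$`window` (defaults
2000 bp and 50 bp, with `n_perm = 2000`), against the *fixed* null of the
unshifted test. Re-randomizing per shift would add independent Monte-Carlo
noise at every grid point and mask the positional signal; with a fixed null
the profile moves only because the observed value moves, and the Z-score at
shift 0 is bit-identical to the standard test under the same seed (asserted
in the tests). Boundary policy: shifted regions are clipped to their
chromosome and dropped when pushed off entirely; the dropped count is
recorded per shift and a warning is raised when it exceeds 5% of the set.
The $n$ in nZS stays the focal set's original count at every shift so
profile values remain comparable across shifts.

Profile shapes separate three association geometries: a sharp peak at 0
(position-exact, e.g. two transcription-factor peak sets), a flat profile
(regional, e.g. narrow peaks inside broad chromatin domains — synthetically,
a target of 10×-wider regions containing the focal regions gives a max/min
profile ratio below 1.25), and off-centre maxima with a dip at 0 (flanking,
realized by the demo's `regD` construction).

## Matrix assembly, clustering, projection

`make_matrix()` arranges nZS (or ZS) cells into the RS1 × RS2 matrix; with
`zero_nonsig = TRUE` every cell whose BH-adjusted p exceeds `alpha`
(default 0.05) is displayed as exactly 0, so the heatmap's palette midpoint
encodes "no supported association". `cluster_matrix()` fits all seven
standard `hclust` linkages on the Euclidean distances between row vectors
and keeps the one with the highest cophenetic correlation — a deterministic
rendering of "the most efficient method"; rows and columns are clustered
independently because a crosswise matrix need not be symmetric, and the
distance metric (Euclidean) is itself a design choice the interface lets
you sidestep by passing `method` explicitly. Constant matrices keep their
input order with a warning. `correlation_matrix()` replaces values by
Pearson correlations between row profiles (unit diagonal; zero-variance
rows zeroed with a warning).

`dim_red()` projects row profiles with PCA (`stats::prcomp`), t-SNE
(`Rtsne`, exact mode, perplexity auto-reduced below $(rows-1)/3$ with a
warning) or UMAP (`uwot`, single-threaded for reproducibility under the
seed). Cluster labels are **never** taken from the 2-D coordinates: they
come from cutting the row dendrogram of the matrix itself into `n_clusters`
groups, by default the $k \in 2..\min(10, rows-1)$ with the highest mean
silhouette width — so labels are identical across projection methods by
construction.

## The synthetic demonstration dataset

`build_demo_dataset()` is first-class, tested code, and its defaults *are*
the study conditions the rest of the validation rests on:

* a genome of 4 chromosomes of 0.1, 0.5, 1 and 2 Mb;
* three independent base sets `regA`, `regB`, `regC` of 100 regions with
  widths drawn from Normal(100, 50) bp, rounded and floored at 1 bp (the
  distribution family is a package choice; only mean ± SD are prescribed,
  and at these parameters the 1 bp floor shifts the realized mean by under
  half a base pair);
* `regAB`, sharing 50 verbatim regions with each parent;
* `regD`, one region per `regA` region on a uniformly chosen side at a gap
  drawn uniformly from 1–300 bp, never overlapping (nor directly touching)
  any `regA` region — the uniform gap and random side are package choices
  within the stated 300 bp bound;
* similarity ladders sharing 90%–10% (base sets) and 80%–20% (`regAB`,
  `regD`) of intervals verbatim — "similarity" is the exact fraction of
  identical intervals, not coordinate jitter, so it is verifiable by
  interval equality; the non-shared remainder is drawn freshly without an
  overlap constraint (collisions at this density are vanishingly rare);
* three negative-control sets rejected against the union of
  `regA`/`regB`/`regC`/`regAB` (three controls keep a full control block in
  the matrix while staying desk-scale).

What the generator does *not* emulate: clustering of regions along
chromosomes, GC/mappability structure, heavy-tailed width distributions,
or covariate-matched null pools. Passing tests therefore demonstrate the
correctness and calibration of the machinery, not robustness to the
confounders of real chromatin data — for those, choosing an appropriate
universe (or an externally matched control set) remains the analyst's task.

## Numerical choices and calibration

* Canonical region order (genome chromosome order, start, end) is the
  tie-break everywhere, including the upper-quartile cut of
  `filter_top_regions()` (quartile size `ceiling(n/4)`).
* The permutation p-value is discrete. For sparse sets — such as the demo's
  100 × ~100 bp regions on 3.6 Mb, where two independent sets overlap in
  0–3 regions — the attainable rejection level at nominal $\alpha = 0.05$
  is about 0.03, so the test is conservative, never anti-conservative. The
  type-I calibration test accounts for this by comparing the realized
  rejection fraction against the exact attainable level computed from each
  cell's own null sample, alongside the bound at the nominal level.
* Problem sizes in the test suite follow the demo conditions: 1000
  permutations for crosswise runs (2000 for the crosswise-vs-pairwise and
  local-profile checks, matching the local defaults), 20 sets for type-I
  calibration, 5 seed replicates for the power and stabilization
  properties. Monte-Carlo comparisons use 3-standard-error bands.
* `n_perm` below 1000 triggers a warning (classed
  `crosswiser_low_nperm`); below 100 it is an error.

## Known limitations

Masks (excluded genome regions) are not subtracted from the sampling space;
the universe mechanism of `resample_regions` is the supported way to
restrict the null. Distances never span chromosomes. The crosswise design
reuses one randomization pass per RS1 row, so cells within a row are
positively dependent — irrelevant for per-cell inference and for BH (which
tolerates this dependence), but row-wise summaries of counts of significant
cells inherit it. Runtime scales linearly in `n_perm`, RS1 size and RS2
size; subsampling large sets (the nZS makes the results comparable) is the
intended lever.
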