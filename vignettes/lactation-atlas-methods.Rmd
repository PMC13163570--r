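---
title: "Methods: atlas screening, reference-gene stability, and lactation trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: atlas screening, reference-gene stability, and lactation trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactatlas)
```

This vignette documents the statistical procedures implemented in
`lactatlas`, the parameters that matter, the design of the synthetic-data
generators, and the package's known limitations. The package addresses
the screening questions of a multi-tissue transcriptomic atlas in dairy
livestock: stable (housekeeping) genes, tissue-specific and marker
genes, qPCR reference-gene ranking, lactation-stage expression trends,
and milk-trait correlations.

## Housekeeping-gene screening

A gene qualifies as a candidate housekeeping gene (HKG) when its mean
TPM across tissues exceeds 1. For each candidate, `compute_cv()`
calculates the coefficient of variation

$$\mathrm{CV}_g = \frac{s_g}{\bar{x}_g}$$

of its *replicate-averaged tissue means* — not raw samples — so
replicate noise does not masquerade as between-tissue variability. The
standard deviation uses the sample (n − 1) form; a population-SD option
exists because the choice is a convention, not a result: the CV ranking
is nearly unchanged either way.

`classify_variability()` cuts the CV distribution at its quartiles
(type-7, linear interpolation — R's default and the one a spreadsheet
or NumPy reproduces): CV ≤ Q1 is low variability, CV ≥ Q3 high, the
rest medium. Expression bins follow mean TPM: low (1, 10], medium
(10, 50], high > 50. Core HKGs are low-variability *and* mean TPM > 50;
`select_core_hkgs()` re-screens at TPM > 70 and > 100, and these sets
are nested by construction, which the tests assert. When Q1 = Q3 (all
CVs equal) a boundary gene satisfies both group inequalities; we assign
low before high so the degenerate case is deterministic and
conservative for stability calls.

`rank_top_stable()` orders core genes by ascending CV, breaking ties by
descending mean TPM and then gene id, so rankings are reproducible to
the last position.

## Smooth quantile normalization

`qsmooth_normalize()` implements group-aware smooth quantile
normalization. Writing $q_k^{(j)}$ for sample $j$'s $k$-th order
statistic, the reference quantile $\bar{q}_k$ is the mean over all
samples and the group quantile $\hat{q}_k^{(g)}$ the mean within sample
$j$'s group. The normalized $k$-th value of a sample in group $g$ is

$$w_k\,\bar{q}_k + (1 - w_k)\,\hat{q}_k^{(g)},$$

where $w_k$ is the within-group share of the total variance at rank
$k$ ($w_k = 1 - \mathrm{SSB}_k/\mathrm{SST}_k$, set to 1 when
$\mathrm{SST}_k = 0$), smoothed by a running median over a window of
5% of the number of quantiles (forced odd). Ranks where the groups
genuinely differ keep their group-specific quantiles; ranks that behave
identically across groups are normalized globally. With one group,
$w_k \equiv 1$ and the procedure is exact quantile normalization (the
tests verify agreement with an independent implementation to 1e-8).

Two numerical choices matter. First, the blended per-group quantile
vector is **sorted** before values are mapped back to each sample's
original order: with a rank-varying weight the blend of two
non-decreasing quantile curves is not itself guaranteed non-decreasing,
and without sorting, tiny within-sample rank inversions can occur. A
quantile function must be monotone, and sorting restores that with the
same multiset of values. Second, tied input values within a sample
receive the mean of their assigned normalized values, so ties stay
tied.

## Tissue-specific, marker, and stage-specific genes

After normalization and replicate averaging, `call_tsgs()` applies the
fold-ratio rule: gene $g$ is specific to tissue $t$ when
$\mu_{g,t} \ge k \cdot \max_{t' \ne t} \mu_{g,t'}$, default $k = 3$.
Genes below 1 TPM in every tissue are excluded first. When all other
tissues have mean 0 the ratio is $+\infty$; the call is then made only
if the target tissue reaches the 1-TPM floor, which keeps exclusive
marker genes inside the TSG universe without admitting noise-level
calls. With $k > 1$ a gene can be specific to at most one tissue
(two tissues cannot each be $k$-fold above the other).

`call_markers()` implements exclusivity: expressed (mean ≥ 1 TPM, the
package-wide detection convention) in exactly one tissue. Exclusivity
implies the fold rule only when off-tissue expression is negligible; a
gene at 1.3 TPM in one tissue and 0.5 in another is a marker but only
2.6-fold enriched, so markers are not formally a subset of TSG calls —
the planted markers in the simulator, whose off-tissue means are near
zero, always are.

`call_stage_specific()` reuses the identical fold rule with lactation
stages (early, peak, mid, late) in place of tissues. The underlying
screen for stage-specific genes is not otherwise standardized in the
field; transferring the tissue rule is an explicit, configurable choice
rather than a reconstruction of any particular study's unpublished
procedure. `fold_sensitivity()` repeats the screen at stricter folds
(default 3/4/5) and reports retention fractions; nesting of the call
sets is analytically forced and asserted in tests.

## Reference-gene stability from Cq tables

All algorithms consume a gene × sample table of quantification cycles
(Cq). Relative quantities use the standard transform
$Q_{gs} = E^{\,\min_{s'} Cq_{gs'} - Cq_{gs}}$ with amplification
efficiency $E = 2$ by default (perfect doubling). The efficiency is a
configuration knob because measured efficiencies are rarely available;
rankings are invariant to it in the ungrouped analyses since it only
rescales log quantities.

**geNorm.** The pairwise variation of genes $j,k$ is
$V_{jk} = \mathrm{SD}_s\!\left(\log_2 Q_{js}/Q_{ks}\right)$ and the
stability measure $M_j$ is the mean of $V_{jk}$ over $k \ne j$; lower
is more stable. Stepwise exclusion repeatedly removes the highest-M
gene (recomputing M each round); the final two genes cannot be
separated by M and share stepwise rank 1, per the original convention.
The rank vector fed to the aggregate, however, is by full-panel M with
ties broken by gene id, so it is a proper permutation. The
normalization-factor pairwise variations V(k/k+1) are reported to guide
how many reference genes to combine.

**NormFinder.** On log₂ quantities the additive model
$x_{gs} = \alpha_g + \beta_s + \varepsilon_{gs}$,
$\varepsilon_{gs} \sim N(0, \sigma_g^2)$, is removed by two-way
centering. The naive residual variance of gene $i$ is biased — the
estimated sample effects mix every gene's noise into every gene's
residuals, with expectation
$(1 - 2/G)\,\sigma_i^2 + \sum_j \sigma_j^2 / G^2$ for $G$ genes — so
the reported stability is the square root of the jointly solved,
bias-corrected variance estimate, floored at zero. The grouped variant
(off by default; the ungrouped analysis is the package default) scores
each gene by the mean over groups of its absolute gene-by-group
deviation plus the standard error of its within-group residual,
capturing the intergroup-variation term of the published model in a
simplified form.

**BestKeeper.** Works directly on raw Cq: per-gene dispersion (sample
SD by default; the original tool's mean absolute deviation is an
option), percent CV, and the Pearson correlation of each gene with the
BestKeeper index (per-sample geometric mean of all genes' Cq). Ranking
is by ascending dispersion, following the convention that lower SD
means a better reference.

**Comparative delta-Ct and the aggregate.** The delta-Ct method scores
each gene by the mean SD of its pairwise Cq differences; at $E = 2$
this coincides numerically with full-panel geNorm M (a cross-check the
tests exploit). `reffinder()` aggregates the four rank vectors by their
geometric mean, with final ties broken by the best single-algorithm
rank and then gene id. The conventional description of this aggregate
as a "geometric mean of Cq values" in parts of the literature is
imprecise; the operative definition — and the one implemented — is the
geometric mean of *ranks*.

## Fuzzy c-means trend clustering

`standardize_stage_profiles()` z-scores each gene's stage trajectory
(constant rows carry no trend and are dropped with a warning), so
clustering groups genes by shape, not level. `fuzzy_cmeans()` minimizes

$$J = \sum_{i=1}^{n} \sum_{c=1}^{C} u_{ic}^{\,m} \lVert z_i - v_c \rVert^2$$

by standard alternating optimization with fuzzifier $m = 2$ and
$C = 6$ clusters as conventional defaults for expression-trend work
(both configurable; no internal cluster-number selection rule is
imposed). Memberships are initialized uniformly at random from the
given seed, making runs bit-for-bit reproducible; the caller's RNG
stream is left untouched. Convergence is declared when the largest
membership change falls below `tol` (1e-6). A gene sitting exactly on a
centroid receives membership split equally among its zero-distance
centroids. The objective trace is recorded and is non-increasing on
every run — an invariant the test suite asserts rather than assumes.
With $C = 1$ the memberships are identically 1 and the centroid is the
column mean.

`match_trait_trend()` correlates each centroid with the z-scored trait
trajectory (e.g. milk yield at the stage-representative days) and
selects the argmax, ties to the lower cluster index; hard cluster sizes
(maximal membership, ties likewise to the lower index) accompany the
match. Matching is invariant to cluster relabeling.

## Lactation traits

`stage_representatives()` summarizes each trait at the
stage-representative days in milk — early 7, peak 85, mid 145, late
285 — averaging across animals, with a nearest-day fallback within ±5
days (daily recording schedules slip; a five-day window stays well
inside a lactation stage). `trait_correlations()` computes Spearman
correlations across all records among milk yield, protein %, fat % and
lactose %, with two-sided p-values from the t-approximation on n − 2
degrees of freedom (the behaviour of the standard correlation-matrix
utilities; ranks are tie-corrected averages). Missing values are
dropped pairwise; zero-variance columns yield a missing coefficient
with a warning rather than an error.

`pairwise_stage_tests()` compares a trait's stage-representative
observations between every stage pair with a two-sided Wilcoxon
rank-sum test (a Welch t-test is available), adjusting across the six
pairs by Benjamini–Hochberg. Rank-sum with BH is a deliberate default
for small-n, non-normal composition data, not a reconstruction of any
particular study's unreported test. Stars follow the usual scheme
(\*, \*\*, \*\*\* at 0.05/0.01/0.001, ns otherwise).

## The synthetic-data generators

The simulators provide planted ground truth at the scale of a real
atlas study — a 20-tissue atlas with 2–4 replicates per tissue, a
6-gene × 5-sample qPCR panel, and six animals sampled intensively in
early lactation then every 10 days — so recovery of each screening
stage is measurable. All generators are deterministic given `seed`.

**Atlas (`simulate_atlas`).** Background genes draw a log-normal
abundance (meanlog 1.2, sdlog 1.2 — median ≈ 3 TPM with a long right
tail, as TPM distributions look after the detection filter) and a
per-gene between-tissue log-SD uniform on 0.25–0.7, i.e. tissue CVs
roughly 0.25–0.8. That range is chosen so the planted classes remain
the dominant source of screening calls: background genes only rarely
(~1%) satisfy the 3-fold rule or sit in the low-CV/high-TPM corner by
chance, keeping the screens discriminative without making them
trivial. Planted HKGs combine abundance 60–300 TPM with tissue CV
0.03–0.08, well below the background range; planted TSGs put one
tissue 8-fold (with a random extra margin) above the rest; planted
markers are 5–50 TPM in one tissue and < 0.2 elsewhere. Replicate
noise is multiplicative log-normal (sdlog 0.15, typical for bulk
RNA-seq biological replicates). The three planted classes are
disjoint. What the generator does **not** emulate: count-level
sampling noise, correlated gene modules, batch effects between data
sources, and compositional coupling of TPMs — so passing recovery
tests demonstrate the screening logic, not robustness to those
real-data complications.

**qPCR panel (`simulate_cq`).** Cq = gene baseline (uniform 18–30) +
shared per-sample offset + Gaussian noise with gene-specific SD
(default 0.05–1.0 cycles, spanning excellent to poor candidates). The
sample-offset SD defaults to 0.2 cycles, the residual loading
variation expected when cDNA inputs are concentration-normalized
before plating; because these offsets enter every gene's raw-Cq SD
identically, BestKeeper's ability to rank genes by their own noise
depends on offsets staying modest, whereas geNorm and NormFinder
cancel them exactly.

**Lactation (`simulate_lactation`).** Milk yield follows a Wood-type
gamma curve on a time axis compressed threefold between days 35 and
115, producing the rise–plateau–decline shape of buffalo lactation
(plateau ≈ 9–11 kg/day with the default peak of 10, declining to
≈ 5 kg by day 285), with animal-level scale (log-SD 0.08) and
day-level noise (log-SD 0.05). Composition couples to the
standardized yield trajectory with strength `dilution_strength`:
protein −0.55·d·z + N(0, 0.18), fat −0.45·d·z + N(0, 0.30), lactose
+0.35·d·z + N(0, 0.12) percentage points around buffalo-typical means
(4.6 / 7.5 / 5.0%). At d = 0 all couplings vanish and trait–yield
correlations are null; at d = 0.9 the dilution-effect sign pattern
(yield–protein and yield–fat negative, yield–lactose positive,
protein–lactose negative) emerges, as the acceptance checks measure.
The companion mammary stage matrix plants four trend clusters over the
four stages — yield-shaped, rising, falling, and inverse-yield — plus
stage-specific genes (one stage 30–100 TPM, others 1–4 TPM).
Stage-specific truth lives here rather than in the tissue atlas: with
2–4 replicates per tissue the atlas cannot also carry a 4-stage
mammary design.

## Problem sizes and determinism

The test suite and acceptance script run at deliberately chosen sizes:
the full 5000-gene, 20-tissue atlas for housekeeping recovery; 100
random 300 × 8 profiles for the brute-force TSG/marker equivalence; 100
seeded qPCR panels for stability-ranking recovery; 100 seeds for trend
and dilution properties. These sizes give stable percentages while
keeping a full run in minutes on one core. Every stochastic step takes
an explicit seed, restores the caller's RNG state, and reproduces its
output exactly on reruns.

## Known limitations

- With five samples per qPCR panel, any variance-scale stability
  estimate rests on roughly four degrees of freedom. Separating a
  0.05-cycle gene from a 0.2-cycle gene is then intrinsically
  unreliable, and NormFinder — which scores genes on the variance
  scale — misses the top-2 recovery bar that geNorm, BestKeeper and
  the RefFinder aggregate clear in the packaged experiments. This is a
  property of the design size, not of the implementation: four
  alternative estimators of the same model quantity (naive residual
  SD, bias-corrected, precision-weighted, pairwise least squares)
  perform indistinguishably. With more samples the separation
  improves rapidly.
- The geNorm stepwise ranking reports the final pair tied at rank 1;
  consumers needing a strict ordering should use the full-panel M
  ranks.
- qsmooth weights are estimated per rank from few samples; with very
  small groups the running-median smoothing is doing most of the
  stabilization work.
- The simulators are generative conveniences, not fitted models of any
  real dataset; absolute counts (e.g. how many TSGs an atlas yields)
  depend directly on generator settings and should not be read as
  biological estimates.
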