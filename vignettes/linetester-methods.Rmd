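---
title: "Line-by-tester analysis with linetester: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-by-tester analysis with linetester}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linetester)
```

## The problem

Hybrid maize breeding programs evaluate large sets of candidate inbred
lines by crossing each to a small panel of standard testers and growing the
resulting testcrosses in replicated, multi-season trials — often under
contrasting growing conditions such as managed drought stress versus
rain-fed culture.  From such a trial the breeder wants to know:

* how much of the variation among testcrosses is transmitted additively
  from the parents (general combining ability, GCA) versus arising from
  specific parent combinations (specific combining ability, SCA);
* how heritable each trait is, in the broad and narrow sense;
* how much hybrids out-perform their parents (heterosis) and the
  commercial checks (economic heterosis);
* which inbreds belong to the same heterotic group, so future crosses are
  made between groups rather than within them; and
* which secondary traits predict grain yield well enough to support
  indirect selection.

`linetester` implements this workflow end to end for the classical
line-by-tester mating design, together with a seeded trial simulator whose
known genetic architecture lets every stage be verified against ground
truth.

## Observation model

A plot observation of line $i$ crossed to tester $j$ in season $k$,
replicate $r$, block $b$ is modelled as

$$y_{ijkrb} = \mu + E_k + R(E)_{kr} + B(RE)_{krb}
  + g_i + t_j + s_{ij} + (gE)_{ik} + (tE)_{jk} + (sE)_{ijk}
  + \varepsilon_{ijkrb},$$

with $g_i$, $t_j$ the line and tester GCA effects, $s_{ij}$ the SCA effect
of the cross, the $\cdot E$ terms their season interactions, and
$\varepsilon$ the plot error.  `fit_linetester_anova()` computes the
balanced factorial sums of squares on cell means and partitions the
genotype line exactly into GCA(line) + GCA(tester) + SCA (and the
genotype-by-season line analogously).  Balance is enforced, not
approximated: the simulator always emits balanced designs, and unbalanced
field data are rejected with the offending cells named.

When plots carry incomplete-block labels (the reference design is an
alpha-lattice with 14-entry blocks), a `BLOCK(E:REP)` row — sequential
sums of squares after season and replicate — absorbs block-to-block
variation and the residual is obtained by subtraction.  For the reference
design (36 lines x 5 testers, 2 seasons, 2 replicates, 14 blocks per
replicate) this reproduces the familiar degrees-of-freedom column 1 / 2 /
52 / 179 (= 35 + 4 + 140) / 179 / 306.  Blocks in a lattice are not
orthogonal to genotypes, so the block row is a variance-absorption device,
not an estimable effect of interest; the genotype partition itself is
computed unadjusted on cell means.

F tests use the residual mean square for every source by default, which
matches how significance is conventionally reported for this design; a
`denominator = "interaction"` option tests each genetic main effect
against its own season interaction instead.  Significance codes are
`*`/`**`/`***` at 0.05/0.01/0.001.

## Adjusted means (BLUEs)

`compute_blues()` fits, per trait and growing condition, the fixed-effects
model *genotype + season + replicate(season) + block(replicate)* by least
squares with sum-to-zero contrasts on the nuisance factors, and reports
each genotype's adjusted mean (intercept + genotype effect) with its
standard error.  This is deliberately a fixed-effects analysis, not a
mixed model: it is fully reproducible, reduces exactly to raw genotype
means on balanced block-free data, and is what "BLUEs from the ANOVA
model" means operationally in this literature.  Singular designs fall back
to raw means with a warning; missing plot values are dropped for that
trait only, never imputed.  Checks are included in the genotype factor by
default (the alternative is available by filtering `roles`).

## Variance components, gene action and heritability

`estimate_components()` converts mean squares to variance components by
the method of moments, treating lines, testers and their interactions as
random and seasons as fixed:

$$\hat\sigma^2_{SCA} = \frac{MS_{SCA} - MS_e}{re},\qquad
  \hat\sigma^2_{GCA,L} = \frac{MS_L - MS_{SCA}}{ret},\qquad
  \hat\sigma^2_{GCA,T} = \frac{MS_T - MS_{SCA}}{rel},$$

with analogous divisors for the season interactions.  Negative estimates
are truncated to zero and flagged.  Note that the main-effect divisors
subtract $MS_{SCA}$, not the corresponding interaction mean square; they
are therefore unbiased when the genotype-by-season components are
negligible, and acquire a bias of $\sigma^2_{GCA\cdot E}/e$ otherwise.
The parameter-recovery simulations consequently use configurations with
the season-interaction variances at zero — that is a property of the
estimator being verified, not of the simulator.

With fully homozygous parents treated as a random non-inbred gametic
sample ($F = 0$, the package default; $F$ is exposed in
`derive_A_D()`):

$$\hat\sigma^2_A = 2(\hat\sigma^2_{GCA,L} + \hat\sigma^2_{GCA,T}),\qquad
  \hat\sigma^2_D = 4\,\hat\sigma^2_{SCA},$$

and on the entry-mean basis

$$\hat\sigma^2_E = \frac{\max(MS_{G\times E} - MS_e, 0)}{r}
  + \frac{MS_e}{re},\qquad
  H^2 = \frac{\sigma^2_A + \sigma^2_D}{\sigma^2_A + \sigma^2_D +
  \sigma^2_E},\qquad
  h^2 = \frac{\sigma^2_A}{\sigma^2_A + \sigma^2_D + \sigma^2_E}.$$

`heritability()` accepts the three components directly, so heritabilities
can be recomputed from any published component table without committing to
a particular additive-variance aggregation.  Both statistics are scale
invariant and satisfy $h^2 \le H^2$ by construction.

`gca_sca_contribution()` reports the mean-square-based GCA share
$100(MS_L + MS_T)/(MS_L + MS_T + MS_{SCA})$, the df-weighted
sum-of-squares analogue, and Baker's predictability ratio
$2(\sigma^2_{GCA,L}+\sigma^2_{GCA,T}) /
(2(\sigma^2_{GCA,L}+\sigma^2_{GCA,T})+\sigma^2_{SCA})$.  The two
percentage variants can differ a great deal (for grain yield under drought
in the reference trial: ~87% versus ~47%), because the SCA line carries
140 of the 179 genotype degrees of freedom; both are emitted and the
choice is left explicit.

## Heterosis

On adjusted means, with $P_1, P_2$ the parents' per-se values and $F_1$
the testcross:

$$MP = \tfrac{1}{2}(P_1 + P_2),\quad
  MPH = 100\,\frac{F_1 - MP}{MP},\quad
  BPH = 100\,\frac{F_1 - BP}{BP},\quad
  EH = 100\,\frac{F_1 - BCC}{BCC},$$

where $BCC$ is the best commercial check.  The better parent $BP$ is by
default the numerically larger parent regardless of the trait's selection
direction — the convention under which published tables report positive
better-parent heterosis for lower-better score traits — with a
direction-aware option.  Study-level summaries are means of the
per-hybrid percentages (not percentages of means); hybrids whose
denominator is exactly zero are excluded and counted.  A parent with zero
yield under drought is a real occurrence, which is why the zero-denominator
path is first-class rather than an error.

## Heterotic grouping (HGCAMT)

Parents are grouped from the GCA effects of the traits whose genotype mean
squares are significant under the given condition: the retained effect
columns are Z-scored (sample SD, $n-1$ — the choice matters little at
$n = 41$ parents but is fixed and documented), Euclidean distances are
taken between parents, and the tree is built with Ward.D2 (criterion on
squared distances, heights reported unsquared, so two singletons at
distance $d$ merge at height $d$).  Lines and testers are standardized
jointly before pooling.  The cluster count is chosen by majority vote of
three internal indices — mean silhouette width, the Calinski–Harabasz
pseudo-F, and the within-SS elbow — with ties broken toward fewer groups
and an explicit override for imposing a known count.

Two condition-specific trees are compared on their shared leaves by (i)
the Pearson correlation of the two cophenetic-distance matrices, (ii) the
number of leaves occupying the same position under a canonical leaf order
(smaller subtree first at every node, ties by smallest leaf index — fixed
so the metric is deterministic), and (iii) an entanglement score in
$[0,1]$: the mean absolute rank displacement of shared leaves between the
two orders, normalized by its maximum.  No untangling optimization is
applied; the score describes the canonical orders as they are.

## Correlation analyses

`midparent_hybrid_correlations()` computes the full rectangular Pearson
matrix between mid-parent trait values and hybrid trait means across
hybrids (pairwise-complete; two-sided t tests), whose diagonal holds the
same-trait parent-offspring correlations.  `f1_heterosis_correlations()`
gives the pairwise matrix among $F_1$ value, $BP$, $MP$, $MPH$, $BPH$ and
the hybrid's SCA effect.  Stars follow the two-level legend (0.05, 0.001)
these tables conventionally use.

## The simulator

`simulate_trial()` is the generative mirror of the observation model.
Design defaults reproduce the reference study: 36 lines x 5 testers (180
testcrosses) plus 6 checks, 2 replicates, 2 seasons per condition, blocks
of 14 entries re-randomized per replicate, and a parallel per-se trial of
the 41 parents grown in the same seasons (season effects are shared
between the two trials; replicate, block and plot errors are not).
Per-trait means and variances are calibrated to the reference trial's
estimates under each condition — e.g. grain yield: testcross means
2139/5568 kg/ha (drought/rain-fed), inbred means 577/2026, line GCA
variance 110198/222428, tester 18194/216692, SCA 54808/386696, plot error
823215/1095274 (kg/ha)².  Drought is therefore emulated as
condition-specific means and variances whose defaults imply roughly the
observed stress signature: a ~61% yield loss, a lengthened
anthesis-silking interval, and inflated plant/ear-aspect scores.

Choices worth knowing about:

* **One genetic score per parent/cross.**  A standard-normal score is
  drawn once and scaled by the per-condition SD, so genetic values are
  perfectly correlated across growing conditions.  This makes the
  drought-penalty oracle exact, at the cost of not emulating
  genotype-by-condition re-ranking — conclusions about cross-condition
  rank changes should not be drawn from simulated data.
* **GCA effects are re-centered to exact zero sums** (harmless: sample
  variances are unchanged).  **SCA effects are iid with only the grand
  mean removed.**  Exact row/column centering would delete SCA from every
  parent's marginal mean and bias the EMS estimators by
  $-\sigma^2_{SCA}/t$ and $-\sigma^2_{SCA}/l$; the iid draw matches the
  estimators' sampling model, so per-parent truth sums are zero only in
  expectation.
* **Inbred per-se values are $\mu_{parent} + 2g$** (pure additivity at the
  parent level).  Setting the parent mean equal to the hybrid mean thus
  gives zero expected mid-parent heterosis — the additive null used in
  tests — while the calibrated (much lower) inbred means produce the large
  positive heterosis typical of maize.
* **Ordinal scores** are simulated on a latent continuous scale and
  discretized last (clip to $[1,9]$, round to 0.1); ears-per-plant is
  clipped at 0.  Continuous traits are left Gaussian, so a weak inbred can
  show a (near-)zero drought yield, as happens in real trials.
* **Determinism:** one RNG stream per `simulate_trial()` call, seeded from
  the configuration; identical configuration and seed give byte-identical
  output.

`make_clustered_gca()` plants heterotic groups for testing the grouping
stage: group centroids form a regular simplex with pairwise distance
`separation` (in within-group SD units), rotated by a seeded random
orthonormal basis so the signal spreads over all trait columns.  The
rotation matters: axis-aligned centroids would be compressed by the
subsequent Z-scoring (a single informative column is divided by its own
inflated SD), defeating recovery at separations that are comfortably
recoverable when spread.  At separation 6 with three groups of twelve,
Ward.D2 at $k = 3$ recovers the labels with mean adjusted Rand ~0.95 over
seeds; at separation 0 recovery is at chance by construction.

## Numerical conventions and edge cases

* Zero-variance configurations collapse to exact constants; constant data
  give zero sums of squares and `NA` F ratios (not errors).
* Negative variance components are truncated to zero *after* estimation
  and flagged; `derive_A_D()` refuses negative inputs rather than
  silently re-truncating.
* Percentages with zero denominators are `NA` (heterosis) or the genotype
  is excluded with a warning (stress penalty, zero non-stress mean).
* Zero-SD trait columns cannot be Z-scored and are dropped with a warning.
* Ward.D2 merge heights are checked monotone; cutting at $k$ then $k+1$
  yields nested partitions.
* Effect-table zero sums hold to $10^{-9}$ relative tolerance.

## Problem sizes used in the test-suite simulations

Property-style checks run on deliberately small designs (2–3 lines and
testers for the brute-force ANOVA oracle; up to 7 leaves for the
exhaustive Ward oracle) where exhaustive recomputation is cheap, and on
the full 36 x 5 reference geometry where calibration matters
(parameter-recovery runs use 200 seeded replicates of the full design;
the acceptance script uses 600 for a tighter Monte-Carlo SE on the
4-df tester component).  These sizes were chosen so each oracle is
exact or its Monte-Carlo error is small relative to the tolerance being
asserted.

## Known limitations

* Fixed-effects BLUEs only; no REML/mixed-model shrinkage, no spatial
  row-column adjustment.
* Balanced testcross data are required for the ANOVA; the half-diallel
  among testers that sometimes pads such trials is out of scope.
* The EMS main-effect divisors inherit the published convention of
  subtracting $MS_{SCA}$; under strong genotype-by-season variance they
  are accordingly biased (see above).
* The simulator's cross-condition genetic correlation of 1 and Gaussian
  errors mean that passing recovery tests demonstrates correctness of the
  estimators under the stated model, not robustness to real-data features
  such as outliers, spatial trend, or genotype-by-condition crossover.
* Heritability standard errors are not computed.
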