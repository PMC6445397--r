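---
title: "Intra-individual delta methylation: model, pipeline, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intra-individual delta methylation: model, pipeline, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdelta)
```

## The analysis problem

methdelta analyses paired-timepoint reduced representation bisulfite
sequencing (RRBS) experiments in which every individual is sampled twice —
once before and once after an exposure — so that each individual can serve
as its own control. The motivating design is a rodent early-life-adversity
study: buccal-swab DNA methylomes collected at postnatal day 2 (P2, before
the manipulation) and P10 (after a week of limited bedding and nesting,
LBN, or of control rearing), in 19 individuals spread over two technical
cohorts.

The central analytical idea is that absolute methylation levels carry a
strong developmental (age) signature but also large inter-individual
variation, which can swamp the comparatively subtle imprint of an
experience. Taking the intra-individual change

$$\delta_{ri} = \log_2\!\frac{m_{r,i,\mathrm{P10}} + \varepsilon}
{m_{r,i,\mathrm{P2}} + \varepsilon}$$

for region $r$ and individual $i$ (with $m$ a methylation percentage and
$\varepsilon$ a small pseudocount) cancels whatever is stable within an
individual, so that between-individual comparisons of $\delta$ expose the
experience effect instead.

## Pipeline stages and their statistics

**Per-CpG methylation level.** Always recomputed as
$100 \cdot m/(m+u)$ from methylated ($m$) and unmethylated ($u$) read
counts; the percentage column of input coverage files is ignored so the
definition has a single source.

**Coverage filter.** Sites with fewer than `min_coverage` (default 10)
total reads are removed per sample before testing. The boundary is
inclusive ($\ge 10$), the convention of the standard RRBS
differential-methylation tools; it is configurable for users who prefer a
strict reading of "more than 10 reads".

**Per-individual DMS test.** For each individual, every CpG covered in
both its samples is tested with a two-sided Fisher exact test on the
$2\times 2$ table of methylated/unmethylated counts at P2 vs P10. The
two-sided p-value is the classical one — the sum of hypergeometric point
probabilities not exceeding that of the observed table, with a relative
tie tolerance of $10^{-12}$. Benjamini–Hochberg adjustment is applied
*within* each individual (the test family is that individual's CpGs, not
the pooled set), and a site is a differential methylation site (DMS) when
$q < 0.05$. No minimum-effect-size gate is applied by default
(`min_diff = 0`); an optional gate exists because some tools default to a
25-point difference filter, but we do not silently add an unstated filter.

**Sharing filter and DMR coalescing.** A DMS is retained when at least
`min_individuals` (default 2) distinct individuals of *either* the control
or the LBN group share it at the exact (chromosome, position). The
alternative reading — at least two individuals in *each* group — is
available as `rule = "both"`. Retained sites within 100 bp of each other
are merged by single-linkage chaining (inclusive at exactly 100 bp,
never across chromosomes) into differentially methylated regions (DMRs).
Sharing is evaluated per site *before* merging. Region methylation is
count-weighted (pooled reads across the region's covered CpGs), which
follows from defining the level as a ratio of summed read counts;
mean-of-percent is available as a sensitivity option.

**Matrices, imputation, batch correction.** The DMR × sample percent
matrix drops regions missing in more than 20% of samples and imputes the
remainder with the region's mean — data at realistic coverage have
essentially complete coverage on DMRs, so this policy is the package's
own and is deliberately mild. Cohort (batch) effects are removed per region by
aligning each cohort's mean to the region's grand mean, which preserves
within-cohort differences exactly (up to float rounding) — the linear
batch-removal model used by standard expression tools, operating on the
percent scale. The absolute-level analysis is batch-corrected before PCA;
the $\delta$ matrix is computed from *uncorrected* percentages because a
cohort offset shared by an individual's two samples cancels in the ratio
(a flag can batch-correct $\delta$ too, for robustness checks).

**Decomposition and selection.** PCA treats samples as observations and
regions as variables, centering but not scaling (the analysis operates on
levels, and scaling would inflate low-variance regions). The
decomposition is an exact SVD; at these problem sizes an incremental
solver would agree but is neither deterministic nor as easily
oracle-checked. Component signs are fixed by making each component's
largest-magnitude loading positive. Which component separates which
contrast is data-dependent, so the pipeline scores *every* component with
a folded two-class AUC (0.5 = no separation) for age and for experience
and flags the argmax among the leading components rather than hard-coding
an index. Regions driving the experience-separating $\delta$ component
are selected by signed loading against $\pm 2.5\times 10^{-2}$ (boundary
inclusive). The threshold is the published default; no automatic knee
detection is attempted because "guided by the slope of the weight
distribution" is not an algorithm. k-means (k = 10, k-means++ seeding,
best of 10 restarts, labels renumbered by cluster size) is available for
the heat-map-style row grouping.

**Gene association and enrichment.** Regions are annotated by their
midpoint against the nearest TSS (strand-oriented distance, ties broken
lexicographically): promoter-TSS within $-1000..+100$ bp of the TSS, TTS
within $-100..+1000$ bp of the TTS, otherwise exon or intron when the
midpoint falls in the gene body, else intergenic — the Homer-style
defaults, since the original tooling's parameters are not stated.
TSS-anchored categories are kept within 20 kb of the TSS; gene-body hits
are kept at any distance. Enrichment against user-supplied GMT gene sets
uses the upper-tail hypergeometric test with BH adjustment at
$\alpha = 0.05$; no gene-ontology content is bundled because such lists
are database-version-dependent.

## The simulator

`generate_experiment()` emulates the study design: 19 individuals
(cohort 1: 6 control + 5 LBN; cohort 2: 4 control + 4 LBN), two samples
each, on one synthetic chromosome whose CpG spacing is exponential with
mean 300 bp (minimum 2 bp). Methylation of CpG $j$ in individual $i$
follows

$$\mathrm{logit}\, p = \mu_j + u_{ij} + \alpha_j\,[\mathrm{P10}] +
\beta_j\,[\mathrm{P10}\wedge\mathrm{LBN}] + \gamma_j\,[\mathrm{cohort\,2}]$$

with coverage $c \sim 1 + \mathrm{Poisson}(29)$ and methylated counts
beta-binomial with intra-class correlation $\rho = 0.05$. Defaults:
$\mu_j \sim N(0, 1.5^2)$ (baseline centred at 50% methylation — a neutral
choice where only the spread is prescribed), $u_{ij} \sim N(0, 0.8^2)$,
5% of CpGs carry an age effect $|\alpha_j| = 1.5$, a disjoint 2% carry an
experience effect $|\beta_j| = 1.2$ (random signs), and
$\gamma_j \sim N(0, 0.3^2)$. Effects act only at P10 because both samples
exist before the manipulation. The per-(individual, CpG) effect $u_{ij}$
is *shared between the two ages* — this is the mechanism that makes
absolute levels noisy between individuals while $\delta$ cancels it
by construction. Everything is reproducible from a single seed, and a
truth table labels every CpG null/age/experience for recovery scoring.

What the simulator does *not* emulate: genomic CpG clustering into
islands, bimodal baseline methylation, correlated effects across
neighbouring CpGs, read-level errors or conversion failure, and sex
chromosomes. Passing recovery tests therefore demonstrate that the
pipeline's statistics behave as designed under the assumed generative
model, not that the biological effect sizes of any particular dataset
are recoverable.

## What the synthetic experiment shows — including a surprise

At the default configuration the pipeline calls roughly 2,100–2,300 DMRs
from 20,000 CpGs. About a third of them contain age-effect CpGs and ~8%
contain experience-effect CpGs; the remainder are sites where
beta-binomial overdispersion made the Fisher test anti-conservative in
two or more individuals — a realistic property of count-based DMS calling
that the sharing filter dampens but does not remove.

Three behaviours are measured (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`):

* a leading absolute-level component separates P2 from P10 essentially
  perfectly (age AUC 1.0) — the developmental signature dominates;
* a leading $\delta$ component separates control from LBN individuals
  (experience AUC 1.0 at the defaults), and selecting its top-loading
  regions at $\pm 2.5\times 10^{-2}$ enriches experience-effect regions
  roughly three-fold over their base rate among DMRs;
* with the experience effect switched off, the leading $\delta$
  components sit at chance-level separation and selection precision
  equals the (zero) base rate.

One designed-for behaviour does **not** hold at the default effect
sizes: absolute-level components are *not* blind to experience. The
expectation was that inter-individual variance ($\sigma_u = 0.8$) would
mask the experience effect in absolute levels, capping every leading
component's experience AUC below 0.75. Instead a leading absolute
component reaches AUC $\approx 1$. The reason is instructive: PCA is free
to build a direction that mixes the coherent experience pattern (carried
by the P10 samples of LBN individuals) with the LBN individuals' own
random-effect patterns $u_i$. Because $u_i$ is shared between an
individual's two ages, even the P2 samples of LBN individuals project
positively on such a direction ($u_i \cdot u_i > 0$), and the whole LBN
group separates. The corresponding acceptance check is therefore
expected to fail at the default configuration, and is retained unchanged
as a documented negative result: with an experience effect strong enough
to be this detectable in $\delta$ space (AUC 1.0 with large margin), a
linear decomposition of absolute levels can exploit the within-individual
covariance and recover it too. The qualitative contrast the pipeline is
built around — $\delta$ isolates experience far more cleanly and
interpretably than absolute levels — survives; the stronger claim that
absolute levels contain *no* linearly recoverable experience signal holds
only for weaker or sparser effects (e.g. smaller `frac_exp` or
`exp_effect_logit`, or larger `indiv_sd`), which users can explore by
varying the generator's parameters.

## Numerical and degenerate-case policies

* $\delta$ pseudocount $\varepsilon$ = 1 percentage point, added to both
  numerator and denominator: preserves $\delta = 0$ at equality, bounds
  the statistic, and is reported in the run manifest.
* Fisher two-sided tie comparison at relative $10^{-12}$; batch-mean
  equality asserted at $10^{-9}$; PCA contracts at $10^{-8}$.
* Zero coverage is an error in `methylation_percent` (callers filter
  first); a region uncovered in a sample is missing, then dropped or
  imputed by `build_matrix`.
* All-constant features give zero-variance components with explained
  variance ratio 0 rather than an error.
* Merging at exactly the 100-bp gap merges; loading selection at exactly
  the threshold selects; the coverage filter at exactly 10 reads keeps.
* k-means with $k$ equal to the number of features returns singleton
  clusters directly (the Hartigan–Wong solver requires $k < n$).
* Strand handling: call tables are assumed strand-collapsed; an optional
  reader flag merges +/− records at adjacent positions, off by default.

## Problem sizes

The test suite and the acceptance script run the full design at 20,000
CpGs (a real RRBS CpG table scaled down by roughly 25×), which yields
thousands of DMRs and takes a few seconds per simulated experiment;
multi-seed stochastic checks use 10 seeds. Unit and oracle tests run at
tiny, exhaustively checkable sizes (all 2×2 tables with total ≤ 60; all
hypergeometric instances with universe ≤ 40; matrices ≤ 20×20).

## Known limitations

* The DMS test is Fisher's exact test without overdispersion correction;
  with beta-binomial counts it is anti-conservative per individual, and
  cross-individual sharing is what restores specificity. Regions called
  from a single noisy individual pair are not interpretable.
* The $\delta$ statistic is undefined at 0% without the pseudocount; for
  very low methylation levels $\delta$ is dominated by $\varepsilon$.
* Gene association uses the region midpoint only; regions straddling a
  boundary are classified by their midpoint's category.
* The enrichment universe defaults to all genes in the supplied GTF;
  results depend on that choice as in any hypergeometric analysis.
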