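---
title: "Estimating three-way (aaa) epistasis in doubled-haploid populations"
author: "tripleQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating three-way (aaa) epistasis in doubled-haploid populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripleQTL)
```

## The model

Consider $n$ fully homozygous lines -- doubled haploids (DH) or
recombinant inbreds -- scored at $q$ biallelic markers, each coded
$m_{il} \in \{-1, +1\}$ by parental origin, and phenotyped with
replicates. Writing $y$ for the vector of per-line trait means, the
interaction model over a selected subset of $p$ markers is

$$y = \mathbf{1}\mu + X\beta + Z\gamma + W\delta + e,$$

where $X$ holds the additive marker columns, $Z$ all pairwise elementwise
products of those columns (additive $\times$ additive epistasis, the
$aa$ terms), and $W$ all three-way products (additive $\times$ additive
$\times$ additive, the $aaa$ terms). Because markers are $\pm 1$, every
product column is again $\pm 1$, products are symmetric in their factors,
and a marker multiplied by itself is the intercept -- hence only sorted,
distinct pairs and triples appear, $\binom{k}{2}$ and $\binom{k}{3}$ of
them for $k$ interaction markers.

With $G = [\mathbf{1}\; X\; Z\; W]$ of full column rank, the package fits
the model twice:

* **unweighted** (OLS): $\hat\alpha_u = (G'G)^{-1}G'y$;
* **weighted** (WLS): $\hat\alpha_w = (G'V^{-1}G)^{-1}G'V^{-1}y$ with
  $V = \mathrm{diag}(w_{ii})$, $w_{ii}$ the estimated replicate variance
  of line $i$.

The total three-way effect per trait is the sum of the fitted triple
coefficients ($aaa_{gu}$, $aaa_{gw}$), by default restricted to triples
significant at $p < 0.001$, matching how significant threes are counted
in practice. A phenotype-only estimate of the same quantity is

$$\widehat{aaa}_p = \tfrac12\,(L_{\max} + L_{\min}) - \bar L,$$

half the sum of the extreme line means minus the grand mean, which needs
no genotyping at all.

### Assumptions worth stating

* The population is fully homozygous; there are no dominance terms and no
  heterozygote class. Residuals are uncorrelated across lines.
* Weights are *relative*: the coefficient covariance is rescaled by the
  weighted residual mean square, so only the ratios of the $w_{ii}$
  matter. With all $w_{ii}$ equal, the weighted fit reproduces OLS
  exactly (this identity is tested to $10^{-10}$).
* Interaction terms are built only over loci with significant additive
  effects. This hierarchy is what keeps $\binom{q}{3}$ tractable, but it
  also means purely epistatic triples with no additive signal are
  invisible by construction.

## Marker selection

Selection runs unweighted throughout (weights enter only at final
estimation) in three stages, all driven by stepwise AIC
($n\log(\mathrm{RSS}/n) + 2k$, constants dropped, bidirectional, ties
broken toward the lowest column index so runs are reproducible):

1. **within each linkage group** over that group's additive columns,
   followed by a significance filter at $\alpha = 0.001$ Bonferroni-
   corrected by the number of candidates in the group;
2. **pooled**: survivors of all groups compete again, with the same
   filter (denominator: pooled candidate count);
3. **interaction stage**: all pairs and triples over the surviving
   additive markers enter one stepwise pool while the additive terms are
   protected from removal; retained triples must additionally reach
   $p < 0.001$ in the final fit.

Two design choices deserve comment.

*The significance filter is a backward elimination*, not a simultaneous
discard: the single least significant term is dropped and the model
refitted until every survivor passes. The one-shot alternative is unsafe
on dense maps -- stepwise AIC routinely overfits clusters of collinear
neighbours, which inflate each other's standard errors, and a
simultaneous discard then removes the true marker together with the junk.
In our reference simulations this single change moves exact-marker
recovery of a planted triple from about 0.67 to 0.99.

*Pairs and triples compete in one pool* because the model is a single
joint regression; a `hierarchical = TRUE` switch restricts triples to
marker sets whose three pairs were themselves retained, as a sensitivity
analysis.

The Bonferroni denominator is the number of candidates tested in the
current stage, logged per stage in `selection_log.tsv`. Aliased design
columns (singular-value tolerance $10^{-8}$) are dropped greedily in term
order before fitting, so the earliest representative of each dependency
survives; `checkFullRank()` reports what was aliased to what.

## The phenotypic test and the effective-factor count

`testAaaP()` tests $\widehat{aaa}_p$ as a single-df contrast over line
means, with coefficients $\tfrac12 - \tfrac1n$ on the extreme lines and
$-\tfrac1n$ elsewhere, contrast sum of squares
$\widehat{aaa}_p^2 / \sum_i c_i^2/r_i$, against the pooled within-line
replicate mean square on $\sum_i (r_i - 1)$ df. Because the extreme
lines are located *from the data* while the denominator treats the
contrast as fixed, the statistic is substantially less variable than an
$F(1,\cdot)$ under a Gaussian null: the test is **valid but
conservative** (simulated null rejection at nominal 0.05 is essentially
0). Treat its p values as upper bounds, not as calibrated tail areas;
the package's null-simulation test asserts exactly this one-sided
property.

`effectiveFactors()` estimates the number of segregating loci as
$(L_{\max}-L_{\min})^2 / (4 V_g)$, with $V_g$ the variance of line means
minus `errorVariance/nReps`, floored at zero. The divisor 4 is the DH
calibration: $k$ unlinked equal-effect loci give $V_g = k a^2$ and range
$2ka$ among homozygous lines, so the estimator returns $k$ exactly in
the noiseless limit (verified by simulation); the classical divisor 8
belongs to F2 populations, where the per-locus variance is halved, and
would systematically return $k/2$ here. As with all range-based
estimators, unequal effects and linkage bias it downward.

## Imputation of missing genotypes

Missing marker scores are replaced by their conditional expectation given
the nearest non-missing flanking markers of the same line and linkage
group, under the two-state Markov chain that describes a DH gamete along
a chromosome: with flank states $a, b$ and recombination fractions $r_1,
r_2$ (Haldane by default, $r = (1-e^{-2d/100})/2$; Kosambi selectable),

$$P(x = s \mid a, b) \propto P(a \to s; r_1)\, P(s \to b; r_2), \qquad
E[x \mid a, b] = \frac{p_+ - p_-}{p_+ + p_-}.$$

One-flank entries use $a(1 - 2r_1)$; entries with no informative flank,
and markers absent from the map, get 0 -- the unconditional expectation.
Imputed values are left as real-valued dosages in $[-1, 1]$, which
preserves expectations in the downstream regression; `round = TRUE`
restores hard calls by sign (ties to $+1$) for workflows that need them.
Whether published analyses rounded before regressing is generally not
stated, which is why both behaviours exist.

## What the simulator emulates -- and what it does not

`simulateGenotypes()` draws DH genomes marker by marker along each
linkage group (first marker fair $\pm1$, later markers flipping with the
Haldane fraction of the gap; groups independent).
`simulatePhenotypes()` adds genetic values (mean + additive + pair +
triple effects) and replicate noise whose per-line SD is either constant
or log-normal across lines; the log-normal law is what creates the
between-line variance heterogeneity that inverse-variance weighting
exploits.

The frozen reference conditions (`defaultScenario()`) are sized on a real
wheat DH study: 126 lines, 5 linkage groups of 40 markers spanning
200 cM each, 3 replicates. The genetic architecture puts three strong
additive QTLs (effect 8) at roughly 10, 97 and 190 cM of one group with
a single triple interaction of effect $\delta = 5$ among them. Placing
the triple within one linkage group mirrors the empirical observation
that about half of detected QTL triples fall in a single group, and it
matters statistically: exact-marker localization is limited by the
*unmodelled genetic variance* at selection time, not by replicate noise.
QTLs on three different groups leave $2a^2 + \delta^2$ of foreign
variance in every within-group residual and cap exact recovery near
0.25 regardless of noise; same-group placement lets stage 1 fit all
three loci jointly and recovery reaches 0.99. The three scenarios
differ only in noise: constant SD 0.5 ("recovery"), log-normal with
median 3 and log-SD 1.1, i.e. an upper/lower quartile ratio of about
4.4 ("heteroscedastic"), and no genetic signal at constant SD 2
("null").

Passing tests under these conditions show the estimators work when the
generative model *is* the fitted model on a modest, clean map. They do
not speak to: genotyping error; segregation distortion; thousands of
markers per group (the real motivating datasets are an order of magnitude
denser); multi-trait correlation; or genotype-by-environment structure.

## Numerical and degenerate-input choices

* Fits go through QR (`lm.wfit`); the design must be full rank after
  `dropAliased()`, otherwise fitting errors with a pointer to
  `checkFullRank()`.
* Stepwise RSS values are floored at $10^{-12}\sum y_i^2$ so saturated
  models compare equal instead of chasing floating-point noise.
* A zero-variance response selects nothing; selection with no surviving
  marker is a valid empty result (traits genuinely without QTLs exist),
  and $k < 3$ survivors simply yield zero triples.
* Per-line variances for single-replicate lines take the median of the
  available line variances; with no replicated line at all, weights fall
  back to 1 with a warning and WLS degenerates to OLS by design.
* Ties for the extreme line in $\widehat{aaa}_p$ take the first line in
  input order; the estimate itself is unaffected.

## Weighting: what improves and what does not

Under strong heteroscedasticity the weighted estimator of a planted
triple effect is markedly better than OLS: across the reference
heteroscedastic scenario the weighted squared error is smaller in about
80% of replicates and its MSE roughly an order of magnitude lower, and
the weighted model's overall $R^2$ is higher. One related quantity moves
the *other* way, and users should know it: the **per-triple percent
variance explained, computed in the weighted metric** (increment in
weighted RSS over weighted TSS), tends to be *smaller* than its
unweighted counterpart in this regime. Inverse-variance weights under a
heavy-tailed SD law concentrate the effective sample on a handful of
precise lines, which erodes the triple column's unique contribution even
while the coefficient estimate itself improves. A higher weighted model
$R^2$ therefore does not imply a higher weighted per-triple share.

## Worked example

```{r example, eval = FALSE}
sc <- defaultScenario("recovery")
g  <- simulateGenotypes(sc$nLines, sc$map, seed = 61)
ph <- simulatePhenotypes(g, sc$arch, seed = 62)

sel <- selectMarkers(unname(lineMeans(ph)), g, sc$map)
des <- dropAliased(buildDesign(g, sel@additive))
fu  <- fitUnweighted(unname(lineMeans(ph)), des)
fw  <- fitWeighted(unname(lineMeans(ph)), des, unname(lineVariances(ph)))
totalAaa(fw)

## or, end to end with result tables on disk:
runPipeline(g, sc$map, ph, "results/")
```

Problem sizes throughout the test suite and the acceptance script -- 200
Monte-Carlo replicates for recovery and weighting comparisons, 500 null
replicates for false-positive control, 10,000 random flank
configurations for the imputation oracle -- were chosen as the package's
reference experiment sizes; all summaries are recomputable from the
per-replicate tables that `monteCarloCompare()` returns.

## Known limitations

* Exact-marker recovery degrades with cross-group QTL triples (see
  above); recovery figures are specific to the stated architecture.
* The phenotypic F test is conservative, not calibrated.
* The effective-factor count assumes equal-effect, unlinked, purely
  additive loci; it is a rough index, not an estimate with standard
  errors.
* Weights estimated from very few replicates (2 df here) are noisy;
  weighting still wins in the simulated regime, but with a single
  replicate it silently reduces to OLS.
* No dominance, no genotype-by-environment terms, no kinship adjustment,
  and no permutation-based genome-wide thresholds.
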