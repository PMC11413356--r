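---
title: "Omnigenic two-sample MR: model, estimator and design choices"
author: "omnimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Omnigenic two-sample MR: model, estimator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omnimr)
```

## The problem

Classical two-sample Mendelian randomization estimates the causal effect of
an exposure on an outcome from GWAS summary statistics, using
genome-wide-significant SNPs as instruments and assuming they affect the
outcome only through the exposure. For highly polygenic traits both
assumptions strain: discarding sub-significant SNPs throws away most of the
heritability, and horizontal pleiotropy (direct SNP effects on the outcome)
is pervasive. The omnigenic approach implemented here keeps *all* SNPs as
instruments and absorbs pleiotropy into an explicit variance component, so
the causal effect is identified from the pattern of covariation between the
two sets of z-scores rather than from a handful of hits.

## Structural model

With standardized genotypes and unit-variance phenotypes in two disjoint
cohorts of sizes $n_x$ and $n_y$,

$$x = \mu_x 1 + G_x\beta + \varepsilon_x, \qquad
  y = \mu_y 1 + G_y(\beta\alpha + \gamma) + \varepsilon_y,$$

where $\beta_j \sim N(0,\sigma^2_\beta/p)$ are the per-SNP effects on the
exposure, $\gamma_j \sim N(0,\sigma^2_\gamma/p)$ the direct (pleiotropic)
effects on the outcome, and $\alpha$ the scalar causal effect. Phenotypes
are centered before the per-SNP marginal regressions, so the intercepts
never reach the summary statistics. Residual variances are
$1-\sigma^2_\beta$ and $1-\alpha^2\sigma^2_\beta-\sigma^2_\gamma$, which
makes both phenotypes unit-variance — the scale on which z-score algebra is
exact and on which all three parameters are interpretable as variance
fractions.

Marginalizing over $\beta,\gamma$ and the residuals, the z-scores of an LD
block with correlation matrix $R$ are jointly normal:

$$\operatorname{Cov}\!\begin{pmatrix} z_x \\ z_y \end{pmatrix} =
 \begin{pmatrix} aR^2 + R & cR^2 \\ cR^2 & bR^2 + R \end{pmatrix},
 \quad a = \tfrac{n_x\sigma^2_\beta}{p},\;
 b = \tfrac{n_y(\alpha^2\sigma^2_\beta + \sigma^2_\gamma)}{p},\;
 c = \tfrac{\sqrt{n_xn_y}\,\alpha\sigma^2_\beta}{p}.$$

$\sigma^2_\gamma$ enters only the outcome margin while $\alpha$ also drives
the cross-covariance: that asymmetry is what separates causation from
pleiotropy. There is no sample-overlap term; the pipeline assumes disjoint
cohorts throughout and does not model overlap.

## Composite likelihood and its evaluation

The genome is partitioned into LD blocks (default 50 contiguous SNPs,
never straddling a chromosome, or externally supplied boundaries). The
objective is the weighted sum of block log-densities. Equal weights are the
default because they make the composite likelihood equal the exact joint
likelihood whenever blocks are truly independent — which is also what makes
the dense-likelihood oracle test exact; $w_b = 1/m_b$ is available as an
option.

Because $R$ and $R^2$ share eigenvectors, rotating each block's data into
the eigenbasis of $R$ factorizes the $2m$-dimensional density into $m$
independent bivariate normals with covariance
$\bigl[\begin{smallmatrix} ad^2+d & cd^2 \\ cd^2 & bd^2+d
\end{smallmatrix}\bigr]$ per eigenvalue $d$. One eigendecomposition per
block is paid once; every likelihood evaluation afterwards is $O(p)$, in a
small C++ kernel. This is what makes delete-one-block jackknifing (hundreds
of re-fits) and replicate-level calibration studies affordable on one CPU.

Maximization is Nelder–Mead over $(\alpha, \log\sigma^2_\beta,
\log\sigma^2_\gamma)$ — the log scale enforces positivity without
constraints; a variance that collapses to the boundary is flagged, not
silently clipped. Starting values come from a method-of-moments initializer
that ignores LD ($\sigma^2_{\beta,0} = p(\overline{z_x^2}-1)/n_x$, etc.),
which doubles as an independent cross-check estimator on LD-free data. The
search restarts from each solution until a restart moves neither the
parameters (1e-6) nor the objective (1e-8); a fit that fails this after
500 iterations per run is returned with `converged = FALSE` and a warning.

Standard errors use the delete-one-block jackknife,
$se^2 = \frac{B-1}{B}\sum_b (\hat\alpha_{(-b)}-\bar\alpha)^2$, rather than
observed information: composite likelihoods misstate curvature-based
variances, while the jackknife is assumption-light and directly testable by
simulation. Jackknife re-fits warm-start at the full-data optimum with a
single restart; the optimum moves by $O(1/B)$ per deletion, so this loses
nothing measurable.

All p-values run through `pnorm`/`qnorm` with `log.p = TRUE`. Published MR
tables report magnitudes like $10^{-32}$; naive `2*pnorm(-|z|)` arithmetic
survives that, but not the $10^{-300}$ scale reachable on strong traits,
so the log-space path is used everywhere and `log10_p` is carried alongside
`p_value`.

## LD estimation and shrinkage

Block correlation matrices are estimated from the reference panel's
dosages and shrunk toward the identity, $R \leftarrow (1-\lambda)R +
\lambda I$ with $\lambda = \max(0.05, m/n_{\mathrm{ref}})$. The shrinkage
identity bounds the smallest eigenvalue below by $\lambda$, so every block
is positive definite even when block size approaches the panel size — the
regime where raw sample correlation matrices are singular. The floor 0.05
is deliberately mild: LD enters both margins and the cross term through the
same $R^2$, so proportional misestimation largely cancels in $\hat\alpha$
(the estimate is a ratio of cross- to marginal-signal), which the recovery
tests confirm.

## The synthetic-data generator

The generator exists so that every stage is testable without multi-gigabyte
downloads. It emulates: block-structured LD (latent AR(1) Gaussian
threshold haplotypes, correlation `rho` within blocks, independence
across), allele frequencies uniform on `maf_range`, shared polygenic
effects $\beta$ across both cohorts, pleiotropic effects $\gamma$, disjoint
cohorts, and marginal-regression summary statistics. Default conditions —
p = 20 000 SNPs in 400 blocks, $\rho = 0.5$, $n_x = 50\,000$,
$n_y = 30\,000$, $\alpha = 0.2$, $\sigma^2_\beta = 0.3$,
$\sigma^2_\gamma = 0.05$, panel of 503 (the size of a continental
1000-Genomes panel) — are the conditions used by the package's own
simulation studies. The exposure heritability default 0.3 is our choice of
a realistic value for a heritable complex trait, surfaced in the config,
not a claim about any particular dataset.

Two samplers share one law. The individual-level sampler draws genotypes,
builds phenotypes, and runs the marginal regressions — the oracle path,
intended for cohorts up to a few thousand. The summary-level sampler draws
block z-scores directly from
$z_x = \sqrt{n_x}R\beta + e$, $e \sim N(0, R)$, which is what makes
replicate studies cheap. The summary sampler uses the *panel-estimated,
shrunk* $R$ — the same matrices the estimator will use — so generative and
fitted covariances are consistent by construction; the individual-level
sampler, whose genotypes follow the true AR(1) process, provides the
independent check that the two agree within Monte-Carlo error.

What the generator does **not** emulate: realistic human LD maps and MAF
spectra, case/control liability-scale traits, sample overlap, population
stratification, and per-SNP sample-size heterogeneity beyond what the
median-collapse handles. Passing tests therefore demonstrate internal
correctness of the estimator under its stated model, not robustness to
those real-data features.

## Harmonization rules

Alignment to the panel resolves allele orientation: identical pairs keep
sign; swapped pairs negate the effect and mirror the frequency;
strand-complement pairs are complemented first; anything else is dropped as
a mismatch. Palindromic SNPs (A/T, C/G) cannot be disambiguated by strand,
so they are oriented by frequency agreement and dropped entirely when the
panel frequency lies in [0.4, 0.6] — the band where frequency cannot
arbitrate either. The MAF floor (default 0.01) exists because LD estimated
from a small panel is unstable for rare alleles. The filters are
non-interacting set predicates, so the retained set is order-invariant;
every removal is counted in a QC log whose entries reconcile exactly with
the retained count. Per-SNP sample sizes are collapsed to medians because
the covariance algebra uses scalar $n_x, n_y$.

## The two-round cascade

Round 1 tests one exposure against K mediators at the Bonferroni threshold
$\alpha/K$; survivors become exposures in round 2 against M outcomes at
$\alpha/(Mk)$ with $k$ the survivor count, computed dynamically. With
K = 42, and k = 7 survivors against M = 15 outcomes, these instantiate to
0.00119 and 0.000477 — the layered scheme used in published two-round
designs. A nominal tier ($p < \alpha$ but above Bonferroni) is flagged
separately and never promoted. Failed fits become rows with an error
status; they are never dropped. Round-1 p-values are two-sided throughout
(the choice consistent with every published CI this package reconstructs).

## Mixture-grid replication

The replication estimator deliberately uses a different identification
strategy: genome-wide-significant instruments, greedily clumped to pairwise
panel $r^2 < 0.1$, and for each candidate effect $\theta$ on a grid
(default $[-1, 1]$ step 0.005, wide enough to bracket standardized effects
up to $|\alpha| \approx 0.5$) the residuals $t_j = \beta_{y,j} - \theta
\beta_{x,j}$ with known variance $s_j^2 = se_{y,j}^2 + \theta^2 se_{x,j}^2$
are fitted with a two-component mixture $\pi_0 N(0, s_j^2) + (1-\pi_0)
N(0, s_j^2+\tau^2)$ by EM. The $\pi_0$ M-step is closed-form; the $\tau^2$
M-step maximizes the expected complete log-likelihood exactly by
one-dimensional search, so every iteration increases the observed
likelihood. $\hat\theta$ is the grid point maximizing $\pi_0$ — exact ties
break toward the smallest $|\theta|$, the conservative direction. The
two-component residual form is an approximation to richer bivariate
mixture estimators in the literature: it reproduces the
$\theta$-versus-probability-mass profile those methods report, which is
the quantity this pipeline consumes, and makes no claim of
bit-compatibility with any of them.

Sharpness of the $\pi_0$ profile is governed by instrument strength: the
identification width is of order $se/\mathrm{sd}(\beta_x)$, so localizing
$\theta$ to one grid step (0.005) requires instruments with per-SNP
standard errors a few per mille of the effect spread. The package's
validity checks use 50 such strong instruments; with weaker instruments the
profile is flatter and the peak correspondingly less precise, which is a
property of the method, not of the implementation.

Degenerate inputs are handled explicitly: residuals that are all equal
drive $\pi_0$ to 1 at once (EM's per-iteration gain vanishes as the two
components coincide, so it would otherwise stall at an interior value), and
$\tau^2$ has a floor of 1e-6 to keep the non-null component proper.

## Numerical and design choices, in brief

* 95% intervals use `qnorm(0.975)` (1.959964...), never the rounded 1.96;
  rounding happens only at serialization.
* `wald_interval` reconstructs the SE implied by a published
  (estimate, p) pair in log space; round-tripping se → p → se is exact to
  1e-10 even at $|z| = 60$.
* Results tables serialize floats at 6 significant digits and p-values in
  scientific notation, so $10^{-32}$-scale values survive a round-trip.
* Duplicate SNP ids keep the largest-n record; indels are rejected
  (palindrome logic is defined for single bases).
* Coordinates are 1-based (VCF convention); the join key is `snp_id` with
  a `chr:pos:sortedalleles` fallback.
* The simulation defaults and all problem sizes in tests (20 000-SNP
  recovery, 200-replicate null calibration at 5 000 SNPs) were chosen as
  the smallest sizes at which the genome-wide asymptotics visibly hold.

## Known limitations

The estimator assumes disjoint cohorts (no overlap covariance term is
implemented), unidirectional causation (no reverse-MR mode), a scalar
causal effect and Gaussian effect-size distributions. "Pleiotropy
proportion" is reported as $\hat\sigma^2_\gamma$, the fraction of outcome
variance attributable to direct SNP effects; phrases like "0.1% of SNPs
showing pleiotropy" in the applied literature are ambiguous between a
SNP-count fraction and this variance fraction, and this package commits to
the variance reading. LD blocks are fixed windows rather than
recombination-map-derived; block misspecification is partially absorbed by
the jackknife but not modeled.
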