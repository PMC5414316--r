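---
title: "Efficient leave-one-out cross-validation for genomic BLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficient leave-one-out cross-validation for genomic BLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gblupcv)
```

## The problem

Genomic prediction trains a whole-genome regression on phenotyped,
genotyped individuals and predicts the genetic merit of others. With small
training sets, leave-one-out cross-validation (LOOCV) is the natural way to
measure predictive ability, because every record but one is kept for
training. Done naively, LOOCV refits the model $n$ times. This package
implements the closed-form shortcuts that deliver all $n$ leave-one-out
residuals from a *single* fit, for ridge-type genomic BLUP in either of its
two equivalent parameterisations.

## Models

Phenotypes are assumed pre-corrected for every fixed effect except an
overall mean $\mu$:
$$ y = \mathbf{1}\mu + X\beta + e, $$
with $X$ the $n \times p$ matrix of allele dosages (0/1/2),
$\beta_k \sim (0, \sigma^2_\beta)$ iid marker effects and
$e_i \sim (0, \sigma^2_e)$ iid residuals. Writing
$X^* = [\mathbf{1}\; X]$, $\lambda = \sigma^2_e/\sigma^2_\beta$ and
$D = \mathrm{diag}(0, 1, \dots, 1)$, the **marker effect model** (MEM)
solves
$$ (X^{*\prime}X^* + D\lambda)\,\hat\beta^* = X^{*\prime}y $$
(a system of order $p + 1$). The **breeding value model** (BVM, i.e.
GBLUP) re-parameterises through $u = X\beta$ with
$\mathrm{var}(u) = XX'\sigma^2_\beta$, and solves
$$ (Z^{*\prime}Z^* + G\lambda)\,\hat u^* = Z^{*\prime}y, \qquad
   Z^* = [\mathbf{1}\; I],\;
   G = \begin{bmatrix} 0 & 0' \\ 0 & (XX')^{-1} \end{bmatrix} $$
(order $n + 1$; requires $XX'$ nonsingular, the typical case when
$n < p$). The two models predict identical linear functions, so
`gblup(model = "auto")` simply picks the smaller system: MEM when
$n \ge p$, BVM otherwise.

## The three LOOCV shortcuts

**MEM strategy.** The matrix-inversion lemma applied to the downdated
normal equations collapses the left-out residual to
$$ \hat e_j = \frac{y_j - x_j^{*\prime}\hat\beta^*}{1 - H_{jj}}, \qquad
   H = X^*(X^{*\prime}X^* + D\lambda)^{-1}X^{*\prime}, $$
i.e. the full-data residual inflated by one minus the leverage. Only the
full-data solution and the diagonal of $H$ are needed; the rank-one
downdate is never formed explicitly.

**BVM strategy I.** Identical algebra through the other parameterisation:
$\hat e_j = (y_j - z_j^{*\prime}\hat u^*)/(1 - C_{jj})$ with
$C = Z^*(Z^{*\prime}Z^* + G\lambda)^{-1}Z^{*\prime}$. Model equivalence
makes $C_{jj} = H_{jj}$ and the residuals identical to the MEM route.

**BVM strategy II.** Treat the mean as a random effect with a large
variance $\sigma^2_L$ (the *random-mean device*), so that
$E(y) = 0$ and $\mathrm{var}(y) = V^* = X^*\Sigma X^{*\prime} +
I\sigma^2_e$ with $\Sigma = \mathrm{diag}(\sigma^2_L,
\sigma^2_\beta I)$. Augment $V^*$ with a leading phenotype border,
$$ Q = \begin{bmatrix} y'y & y' \\ y & V^* \end{bmatrix}, $$
and invert once. For each individual, the $2\times 2$ block of $Q^{-1}$ on
indices $(1, 1+j)$ — the permutation that would bring individual $j$ next
to the border is realised purely as index selection — yields
$$ \hat e_j = \frac{-q^{(1+j),1}}
   {q^{1,1}q^{(1+j),(1+j)} - q^{1,(1+j)}q^{(1+j),1}}, $$
and the same $2\times 2$ inverse gives the **prediction error variance**
$\mathrm{PEV}_j = \mathrm{var}(y_j - \hat y_j)$ as its (2,2) element, hence
the **reliability** $1 - \mathrm{PEV}_j / V^*_{jj}$. PEV is algebraically
the Schur complement $V^*_{jj} - V^*_{j,-j}V^{*-1}_{-j,-j}V^*_{-j,j}$ and
therefore depends only on the covariance structure, not on the observed
phenotypes — two datasets can share a PRESS statistic yet have very
different PEV distributions, which is what makes the per-individual PEV
worth reporting.

The `loocv()` result always satisfies `predictions = y - residuals`
element-for-element, and aggregates to PRESS ($\sum_j \hat e_j^2$) and
accuracy (the Pearson correlation of observed and predicted values), both
restrictable to a subgroup mask — e.g. terminal offspring only, which
avoids the optimism caused by heavily-replicated ancestors.

## Parameters that matter

* `sigma2_beta`, `sigma2_e` (trait units²) and their ratio
  `lambda` — the shrinkage parameter of the mixed model equations. Any two
  determine the third; when only `lambda` is given, `sigma2_e` defaults
  to 1, which matches how worked examples in this literature are usually
  stated ($\sigma^2_\beta = \sigma^2_e / 10$, $\lambda = 10$).
* `sigma2_L` (trait units²) — the random-mean variance of strategy II.
  Default `1000 * sigma2_e`, which both reproduces the canonical worked
  example (where $\sigma^2_e = 1$, $\sigma^2_L = 1000$) and keeps the
  default meaningful when the trait scale changes. The constructor
  enforces `sigma2_L >= 100 * sigma2_e`. Larger values bring strategy II
  closer to the fixed-mean answer at the cost of a worse-conditioned $Q$;
  the residual gap to strategy I shrinks like $O(1/\sigma^2_L)$ and the
  package's tests assert it is non-increasing across
  $\sigma^2_L \in \{10^3, 10^5, 10^7\}$.
* `center` — marker dosages enter **raw** by default. Raw 0/1/2 coding is
  what reproduces the standard worked example; column-centering is offered
  for users who prefer it (it changes $\hat\mu$, never the predictions)
  and is deliberately excluded from the validation fixtures.

## Numerical choices

* Both coefficient matrices are symmetric positive definite for
  $\lambda > 0$, so they are solved by Cholesky factorisation, and the
  full inverse is retained on the fit (`coefficient_inverse`) because
  leverage extraction needs it; memory is $O((\max(n,p)+1)^2)$.
* A `chol()` that merely survives rounding is not accepted as evidence
  that $XX'$ has rank $n$: duplicated genotype rows can leave
  $\sim 10^{-13}$ pivots and a silently wrong BVM fit. The fit requires
  `rcond(XX') > 1e-10` and otherwise raises a numerical-rank error
  advising the MEM route (or `jitter = TRUE`, which adds a documented
  ridge of $10^{-8}\,\overline{\mathrm{diag}(XX')}$).
* Leverages are validated to lie strictly in $(0,1)$; an observation with
  $H_{jj} \ge 1 - 10^{-12}$ is self-predicting and raises a hard error
  rather than propagating infinities. Likewise the strategy-II
  denominator is checked against $10^{-12}\,|q^{1,1}|$.
* At $\sigma^2_L = 1000$ strategy II is a best linear predictor with a
  *random* mean, so its residuals differ from the fixed-mean answer in
  the third decimal (worked example: $-2.6542$ vs $-2.6560$). The test
  suite therefore holds strategy II to the $10^{-3}$ relative agreement
  appropriate at that $\sigma^2_L$, and to exact two-decimal agreement at
  $\sigma^2_L = 10^7$.
* Reliability is reported as $1 - \mathrm{PEV}_j/V^*_{jj}$ with
  $V^*_{jj}$ taken from the augmented covariance actually used, i.e.
  including $\sigma^2_L$. This keeps the quantity internally consistent
  with the strategy-II machinery, but the $\sigma^2_L$ term inflates the
  denominator; users who want reliability against the phenotypic variance
  alone can recompute it as `1 - pev / diag(genomic_covariance(X,
  sigma2_beta, sigma2_e))`.

## The synthetic population generator

`simulate_genotypes()` emulates the design used to benchmark these
shortcuts: a founder pool in Hardy–Weinberg proportions (per-marker allele
frequencies uniform on 0.1–0.5 by default — founder frequencies are not
prescribed anywhere, and this range avoids near-monomorphic columns),
followed by non-overlapping generations of random mating at constant
population size, with the final generation expanded to the requested
number of offspring; each parent transmits one allele per locus
independently. Defaults are 1,000 offspring from 100 parents over 10
generations. `simulate_phenotypes()` draws marker effects iid normal and
rescales them so the realized genetic variance fraction matches the target
heritability, with $\mu = 0$.

What the generator deliberately does **not** model: linkage and
recombination maps (loci are unlinked — the LOOCV algebra is agnostic to
LD), mutation, selection, and pedigree bookkeeping. A green test on this
generator therefore establishes the correctness and scaling of the LOOCV
algebra on realistically-structured dosage data; it says nothing about,
e.g., accuracy under strong LD or selection, which are properties of the
data, not of the cross-validation identities.

## Worked example

```{r example}
g <- read_genotypes(system.file("extdata", "example_geno.csv",
                                package = "gblupcv"))
y <- read_phenotypes(system.file("extdata", "example_pheno.tsv",
                                 package = "gblupcv"), g)
fit <- gblup(g, y, lambda = 10)   # sigma2_e = 1, sigma2_beta = 0.1
round(leverage(fit), 2)
cv <- loocv(fit)
round(cv$residuals, 2)
cv
as.data.frame(loocv(fit, strategy = "bvm2"))
```

## Limitations

Single-trait models only; no fixed effects beyond the overall mean
(pre-correct phenotypes upstream); variance components are inputs, not
estimates (no REML); LOOCV only — k-fold with $k < n$ and
leave-cluster-out designs need different algebra; no imputation, missing
dosages are rejected at load time.
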