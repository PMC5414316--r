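# gblupcv

Efficient leave-one-out cross-validation (LOOCV) for genomic BLUP.

## What it is for

Breeders and quantitative geneticists quantify the predictive ability of a
genomic prediction model by cross-validation, and with small training sets
LOOCV is the design of choice: every candidate is predicted from all the
other records. Refitting the model n times is needlessly expensive.
`gblupcv` computes all n leave-one-out residuals from a **single** fit of
ridge-type genomic BLUP, under either of its equivalent parameterisations:

* **Marker effect model (MEM)** — solve
  `(X*'X* + Dλ) β̂* = X*'y` with `X* = [1 X]`, `D = diag(0, 1, …, 1)`,
  `λ = σ²ₑ/σ²_β`; then

  `ê_j = (y_j − x*_j'β̂*) / (1 − H_jj)`, `H = X*(X*'X* + Dλ)⁻¹X*'`.

* **Breeding value model (BVM / GBLUP) — strategy I** — the same identity
  through the n+1 system `(Z*'Z* + Gλ) û* = Z*'y` with
  `G = blockdiag(0, (XX')⁻¹)`; efficient when p ≥ n.

* **BVM — strategy II** — augment the phenotype covariance
  `V* = X*ΣX*' + Iσ²ₑ` (the overall mean handled as a random effect with
  large variance σ²_L) with a phenotype border,
  `Q = [[y'y, y'], [y, V*]]`, and read every residual, prediction error
  variance (PEV) and reliability off a single `Q⁻¹`.

* **naive** — the n-refits reference oracle, kept for validation and
  benchmarking.

Per-individual residuals aggregate to PRESS (`Σ ê_j²`) and prediction
accuracy (`cor(y, ŷ)` with `ŷ_j = y_j − ê_j`), optionally over a subgroup
mask (e.g. terminal offspring only). A random-mating population simulator
generates realistic dosage data at any scale for testing.

## Worked example

Three individuals, five markers, `σ²_β = σ²ₑ/10` (λ = 10):

```r
library(gblupcv)
g <- read_genotypes(system.file("extdata", "example_geno.csv", package = "gblupcv"))
y <- read_phenotypes(system.file("extdata", "example_pheno.tsv", package = "gblupcv"), g)

fit <- gblup(g, y, lambda = 10)   # auto: BVM here since n < p
as.vector(round(leverage(fit), 2))
#> [1] 0.46 0.51 0.55

cv <- loocv(fit)
round(cv$residuals, 2)
#>     1     2     3
#>  1.13  1.21 -2.66
cv
#> Leave-one-out cross-validation (bvm1 strategy), n = 3
#>   PRESS    = 9.7807
#>   accuracy = -0.9946  (cor of observed and predicted)
```

The leverages are the diagonal of the hat-type matrix (identical between
MEM and BVM); each residual is the error of predicting that individual
from the other two, so PRESS is their sum of squares and the accuracy is
the observed/predicted correlation (negative here — with n = 3 nothing can
be learned; at simulated scale, e.g. 1000 × 100 at h² = 0.5, accuracy is
≈ 0.70). Strategy II adds PEV and reliability per individual:

```r
as.data.frame(loocv(fit, strategy = "bvm2"))
#>   id     y     y_hat     e_hat leverage      pev reliability
#> 1  1  1.97 0.8411260  1.128874       NA 1.846606   0.9981578
#> 2  2  2.12 0.9144028  1.205597       NA 2.050954   0.9979525
#> 3  3 -0.62 2.0341514 -2.654151       NA 2.215198   0.9977890
```

## Command line

A thin wrapper over the same functions ships in `inst/cli/gblupcv`:

```sh
Rscript inst/cli/gblupcv simulate --n-offspring 1000 --n-markers 100 \
    --seed 1 --geno-out geno.tsv --pheno-out pheno.tsv
Rscript inst/cli/gblupcv loocv --geno geno.tsv --pheno pheno.tsv \
    --lambda 10 --out report.tsv        # strategy auto-resolves by n vs p
Rscript inst/cli/gblupcv benchmark --n 1000 --p 100
```

Genotypes are read from CSV/TSV (header of marker ids, first column the
individual id) or PLINK `--recode A` RAW files; phenotypes from a
two-column id/value file, joined by id in genotype order. All flags can be
given through a YAML file via `--config`.

## Acceptance script

`scripts/acceptance.R` re-runs the package end to end from scratch: it
loads the packaged worked example and recomputes the leverages, the
residuals under all four strategies and the augmented Q matrix, then
simulates the two published benchmark shapes (1000 × 100 and
1000 × 10000), runs the auto-selected efficient LOOCV on each and
spot-checks it against the naive refitting oracle, printing every result.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
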