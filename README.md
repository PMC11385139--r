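# h2part

Genome-partitioned heritability and genetic correlation via multi-GRM
REML.

Complex-trait variance is spread over the genome, but not evenly: a small
set of sequence variants -- a functional annotation class, an LD or
allele-frequency stratum -- may carry variance that common genotyping-chip
variants fail to tag. h2part quantifies that by fitting mixed models with
*two* genomic relationship matrices (GRMs): one for the variant subset
under study and one for the chip background. The subset's variance
component then measures what the subset explains *beyond* the chip, and in
the bivariate version its covariance component measures how much of the
correlation between two traits (say, milk yield and a health trait) is
driven by the subset.

## The models

With $y$ a trait vector, the univariate partitioning model is

$$y = \mu 1 + g_{set} + g_{chip} + e,\qquad
  g_k \sim N(0, G_k\,\sigma^2_k),\quad e \sim N(0, I\,\sigma^2_e),$$

with subset heritability
$h^2_{set} = \sigma^2_{set} / (\sigma^2_{set}+\sigma^2_{chip}+\sigma^2_e)$.
The bivariate version gives each term a $2\times2$ trait covariance block
and reports the subset genetic correlation
$r_{g,set} = \sigma_{set,12}/\sqrt{\sigma^2_{set,1}\sigma^2_{set,2}}$,
estimated by average-information REML on stacked records (individuals
missing one trait still contribute to the other). Because subsets differ
enormously in size, estimates are also scaled per variant -- e.g. the
across-trait per-variant $h^2$ divides a subset's summed heritabilities by
the number of traits and variants -- and each subset's LD structure is
characterized by six parameters (intern/extern mean $r^2$, LD decay with
distance, genomic clustering, mean allele frequency).

The package covers the full workflow: PLINK (`.bed`/`.ped`) genotype IO,
GRM construction and GCTA-format binary GRM IO, variant filtering and
LD-score/density/frequency quartile partitioning, the REML fits, derived
statistics with delta-method standard errors, LD metrics, a block-mosaic
simulator with known truth, and a staged pipeline driver with a YAML
config (see `inst/cli/h2part-pipeline.R`).

## Worked example

Simulate two traits with a clustered 100-variant subset
($h^2_{chip} = 0.30$, $h^2_{set} = 0.10$, subset $r_g = -0.5$), then
recover the partition:

```r
library(h2part)

cfg <- sim_config(n_individuals = 500, n_variants = 1000, n_chromosomes = 2,
                  seed = 7,
                  subset_specs = list(list(name = "set1", size = 100,
                                           placement = "clustered")),
                  n_causal_chip = 200, n_causal_subset = 50)
sim <- simulate_genotypes(cfg)
pheno <- simulate_phenotypes(sim$genotypes, sim$variants, cfg, sim$subsets)

set_ids  <- subset_members(sim$subsets, "set1")
grm_set  <- compute_grm(sim$genotypes, set_ids)
grm_chip <- compute_grm(sim$genotypes, setdiff(colnames(sim$genotypes), set_ids))

fit <- fit_univariate(pheno$phenotypes, list(set = grm_set, chip = grm_chip))
heritabilities(fit)
#> # A tibble: 2 × 4
#>   statistic estimate     se converged
#>   <chr>        <dbl>  <dbl> <lgl>
#> 1 h2_set      0.0996 0.0386 TRUE
#> 2 h2_chip     0.277  0.0567 TRUE

bifit <- fit_bivariate(pheno$phenotypes, list(set = grm_set, chip = grm_chip))
genetic_correlations(bifit)
#> # A tibble: 3 × 6
#>   term     estimate     se clamped note  converged
#>   <chr>       <dbl>  <dbl> <lgl>   <chr> <lgl>
#> 1 set        -0.551 0.283  FALSE   <NA>  TRUE
#> 2 chip       -0.205 0.146  FALSE   <NA>  TRUE
#> 3 residual    0.191 0.0630 FALSE   <NA>  TRUE

relative_covariances(bifit)
#> # A tibble: 3 × 6
#>   term     covariance estimate    se note  converged
#>   <chr>         <dbl>    <dbl> <dbl> <chr> <lgl>
#> 1 set         -0.0417   -0.196 0.112 <NA>  TRUE
#> 2 chip        -0.0647   -0.304 0.145 <NA>  TRUE
#> 3 residual     0.107     0.500 0.114 <NA>  TRUE
```

Both true subset parameters ($h^2_{set} = 0.10$, $r_{g,set} = -0.5$) are
recovered within one standard error.

Per-variant scaling of published chip-level estimates (bundled in
`inst/extdata`):

```r
extdata <- system.file("extdata", package = "h2part")
chip  <- read.delim(file.path(extdata, "chip_estimates.tsv"))
sizes <- read.delim(file.path(extdata, "subset_sizes.tsv"))
per_variant_summary(
  h2 = tibble::tibble(subset = "chip", trait = chip$abbreviation, h2 = chip$h2),
  subset_sizes = setNames(sizes$n_variants, sizes$subset))
#> # A tibble: 10 × 5
#>    subset trait statistic                        value note
#>    <chr>  <chr> <chr>                            <dbl> <chr>
#>  1 chip   MY    per_variant_h2              0.00000988 <NA>
#>  2 chip   IH    per_variant_h2              0.00000347 <NA>
#> # ... seven more trait rows ...
#> 10 chip   <NA>  across_trait_per_variant_h2 0.00000341 <NA>
```

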