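# dogpop

Estimating the size, density, and demographic structure of a national pet
dog population from overlapping animal registries.

No register of pet dogs exists; what exists is a patchwork of partial,
overlapping administrative sources — a breed registry, veterinary practice
databases, pet insurers, welfare charities. Each undercounts on its own, and
pooling them double-counts because the same dog appears in several. `dogpop`
is for population ecologists, veterinary epidemiologists, and welfare
researchers who want to turn such a patchwork into a defensible abundance
estimate with uncertainty: it treats the sources as replicate sampling
occasions of a closed population and the cross-source duplication of
individuals as the recapture signal.

## The model

For postcode-area site *i* and data source *j*:

    N_i ~ Poisson(lambda_i)
    y_ij | N_i ~ Binomial(N_i, p_ij)
    logit(p_ij) = alpha_j + beta_j * z(h_i)

where `y_ij` counts the distinct individuals attributed to source *j* at
site *i* after deduplication, and `z(h_i)` is the standardized human
population of the site. Source-level intercepts and slopes are uncorrelated
random effects. The discrete latent `N_i` is summed out of the likelihood
(stable log-space summation in compiled code); sampling is adaptive
Metropolis-within-Gibbs with a dedicated joint move along the
abundance–detection ridge, and `N_i` is reconstructed per retained draw
from its exact conditional. Convergence is assessed with the split-chain
Gelman–Rubin statistic against the conventional 1.05 threshold.

Around the model sit the other stages of the pipeline: a synthetic
multi-source registry generator with known ground truth (the raw registries
a real study uses are commercially sensitive), record cleaning and breed
normalisation against packaged editable alias tables, a four-phase
deduplication (exact duplicates → microchip linkage → key-variable blocks →
partial-key matching), and reporting: per-capita densities with outlier
flags, within/between demographic partitions, breed rankings, lineage and
replacement arithmetic, and external-reference correlation.

## Worked example

```r
library(dogpop)

## 1. a synthetic multi-source registry with known ground truth
params <- sim_params(n_sites = 20, n_sources = 18, seed = 7)
geo    <- generate_geography(params)
truth  <- simulate_truth(geo, params)
tables <- emit_source_tables(truth, params)

## 2. clean, deduplicate, and build the sites x sources count matrix
records <- clean_records(tables, geo)
linkage <- dedup_records(records)
linkage
#> <linkage_result> 12844 records -> 3760 individuals
#>   removed per phase: exact=3687, microchip=2759, keys=2413, partial=225
#>   unresolved fraction: 0.001

y <- build_count_matrix(linkage, geo)
y[1:3, 1:6]
#>   SRC01 SRC02 SRC03 SRC04 SRC05 SRC06
#> A    76    55    40     9    49    70
#> B     6     4     3     1     4     3
#> C    33    23    10     3    14    42
```

12,844 raw rows collapse to 3,760 individuals: 3,687 rows were exact
re-submissions (the injected 28.7% share), 2,759 merged on a shared
microchip suffix, 2,413 on the breed/sex/DOB/name-prefix key within their
postcode area, and 225 on a three-of-four partial key. Only 0.1% of records
could not be assessed for missing keys. Each matrix entry is the number of
distinct dogs source *j* recorded at area *i*; row sums exceed the number
of individuals because a dog seen by k sources contributes to k columns.

```r
## 3. fit the N-mixture model and summarise the posterior
hi <- sim_params(n_sites = 20, n_sources = 18, alpha_mean = -0.6,
                 alpha_sd = 0.4, seed = 7)   # a well-identified detection regime
truth2 <- simulate_truth(geo, hi)
y2 <- build_count_matrix(dedup_records(clean_records(
        emit_source_tables(truth2, hi), geo)), geo)

cfg <- model_config(n_iterations = 10000, thin = 10, burn_in = 1000,
                    n_chains = 2, seed = 1)
fit <- fit_nmixture(y2, geo, cfg)
max(gelman_rubin(fit))
#> [1] 1.036556

posterior_summary(fit, "uk")
#>   group     mean median lower    upper
#> 1    UK 3402.745   3356  2847 4205.025
sum(truth2$N)   # the true total
#> [1] 4201

head(per_capita(fit, geo), 3)
#>   area       mean      lower      upper outlier
#> 1    A 0.13327100 0.11151784 0.16534996   FALSE
#> 2    B 0.06486323 0.05056603 0.08533018   FALSE
#> 3    C 0.12345542 0.10114849 0.15695456   FALSE
```

All R-hat values are below 1.05, and the 95% credible interval
(2,847–4,205) brackets the true total of 4,201 dogs. Per-capita densities
divide every posterior draw by the area's human population; the `outlier`
flag marks areas above 1.5 dogs per person, which in practice indicates a
source-correction artefact rather than real ownership. How well the total
is identified depends on per-source detection: with detection much below
~0.2 per source the flat detection prior dominates and totals shrink toward
the observed counts — the methods vignette
(`vignettes/dog-population-estimation.Rmd`) discusses this regime
dependence, every prior, and the deduplication rules in detail.

`run_all(pipeline_config(...))` chains the five stages under one config and
root seed and writes per-stage artifacts with a hashed manifest. A thin
command-line wrapper lives at `inst/cli/dogpop.R`.

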