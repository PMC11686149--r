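---
title: "Estimating a national pet dog population from overlapping registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating a national pet dog population from overlapping registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

No single register of pet dogs exists. What does exist is a patchwork of
overlapping administrative registries — a breed registry, veterinary practice
databases, pet insurers, welfare charities — each covering an unknown and
uneven slice of the population. Any one source undercounts; naively pooling
them double-counts, because the same dog appears in several. `dogpop` treats
this patchwork as a closed mark–recapture design: each source is a "sampling
occasion", a dog's appearance in a source is a "capture", and the overlap
between sources carries the information needed to estimate how many dogs were
never recorded anywhere.

The pipeline is: generate (or load) per-source record tables, clean and
annotate them, collapse duplicate individuals within and across sources,
build a sites-by-sources count matrix, fit a hierarchical N-mixture model
with imperfect detection, and turn posterior abundances into totals,
densities, and demographic breakdowns.

## The abundance model

Sites are postcode areas (the 1–2 leading letters of a postcode). For site
$i$ and source $j$:

$$N_i \sim \mathrm{Poisson}(\lambda_i), \qquad
  y_{ij} \mid N_i \sim \mathrm{Binomial}(N_i,\, p_{ij}), \qquad
  \mathrm{logit}(p_{ij}) = \alpha_j + \beta_j\, z(h_i),$$

where $y_{ij}$ is the number of distinct individuals attributed to source
$j$ at site $i$ after deduplication, $h_i$ is the site's human population
and $z(\cdot)$ standardises it to mean 0, sd 1. Detection varies by source
(market share, record completeness) and with how populous the site is; the
intercepts and slopes are uncorrelated random effects — a correlated
specification is a known convergence trap for this model family and is
deliberately not offered.

### The $\lambda$ structure

Site abundances vary over orders of magnitude, so the default
(`lambda_mode = "site"`) gives every site its own $\lambda_i$ under a
log-normal hierarchy, $\log\lambda_i \sim N(\mu_\lambda, \sigma_\lambda)$.
Two alternatives are kept behind the `lambda_mode` flag: `"shared"`, the
literal single-scalar-$\lambda$ reading (useful for replication exercises
but unable to generate realistic heterogeneity), and `"site_regression"`,
which adds a log-linear trend of abundance on $z(h_i)$.

### Priors

* $\alpha_j \sim \mathrm{Logistic}(0, 1)$ — the Uniform(0,1)-equivalent on
  the baseline detection probability scale, i.e. a flat prior on
  $\mathrm{logit}^{-1}(\alpha_j)$.
* $\beta_j \sim N(0, \sigma_\beta)$, $\sigma_\beta \sim
  \text{half-}N(0, 1)$.
* $\mu_\lambda \sim N(0, 10^2)$ (log scale), $\sigma_\lambda \sim
  \text{half-}N(0, 2.5)$.

All are configurable through `model_config(prior_spec = ...)` and the prior
settings travel with every fit object.

### Marginalised likelihood and truncation

Rather than sampling the discrete $N_i$ inside the chain, the likelihood
sums it out:

$$\mathcal{L}_i = \sum_{N = \max_j y_{ij}}^{K_i}
  \mathrm{Poisson}(N;\lambda_i) \prod_j \mathrm{Binomial}(y_{ij}; N, p_{ij}),$$

computed in log space with stable summation (`marginal_site_loglik()`,
compiled). The truncation bound is
`K_i = max(qpois(0.999, max(y_i)/p_floor), max(y_i) + 50)` with
`p_floor = 0.15`: the bound assumes no source's detection is plausibly below
0.15, and the `max(y)+50` floor guarantees headroom at tiny rates. The
marginal likelihood is non-decreasing in $K$ and converges once $K$ exceeds
the effective support; a test asserts both properties. Inside the sampler
the sum exits early once terms are decreasing and 45 log-units below the
running maximum (relative error below $e^{-45}$); the exported function
always sums the full range so that oracle comparisons are exact.

### Sampling

`fit_nmixture()` runs adaptive random-walk Metropolis-within-Gibbs chains in
compiled code: per-site moves on $\log\lambda_i$, per-source moves on
$\alpha_j$ and $\beta_j$, conjugate draws for $\mu_\lambda$ (and the
regression slope), and log-scale random walks for the scale
hyperparameters. Proposal scales adapt toward 44% acceptance during burn-in
only.

The model's known weak-identifiability axis is the abundance–detection
trade-off: multiplying all $p_{ij}$ by $c<1$ and $\lambda$ by $1/c$ leaves
expected counts invariant, so the posterior has a ridge along which
single-parameter moves travel slowly. Each sweep therefore adds a joint
"ridge" move — $\log\lambda_i \mathrel{+}= \delta$ for every site (with
$\mu_\lambda$ sliding along), $\alpha_j \mathrel{-}= \delta$ for every
source — repeated five times, which dominates the integrated
autocorrelation time at negligible cost. The practical consequence, asserted
by the recovery tests, is that the posterior of $\sum_i N_i$ recovers the
simulated truth even where $\lambda$ and $p$ individually trade off.

$N_i$ is reconstructed at each retained draw from its exact conditional
(truncated discrete distribution proportional to the summand above), so
posterior summaries of abundance include both parameter and Poisson
uncertainty, and every retained $N_i$ respects $N_i \ge \max_j y_{ij}$.

Initialisation: $\lambda_i = \max_j y_{ij} / 0.5$, $\alpha_j$ at the logit
of a crude source detection fraction, $\beta_j = 0$, all jittered per chain
from the seed; a non-finite starting likelihood triggers re-jittered
restarts (bounded at 10) before erroring.

Convergence is judged by the split-chain Gelman–Rubin statistic
(`gelman_rubin()`), with the conventional threshold of 1.05 used throughout.
The default schedule is 100,000 iterations per chain, thinning 50, burn-in
10,000, two chains; tests and the acceptance script use a reduced schedule
(10,000 / 10 / 1,000 / 2) sized so a 20-site, 5-source fit takes seconds.

### Aggregation

`posterior_summary()` aggregates per draw — site abundances are summed
within a region/country/overall before any summarisation — so posterior
dependence is preserved and region draws sum exactly to country draws.
Credible intervals are equal-tailed 2.5/97.5 percentiles. `per_capita()`
divides each draw by the site's human population before summarising and
flags areas whose mean exceeds 1.5 dogs per person: densities that high are
essentially always a source-correction artefact (one source applying a
strong correction factor on a thin customer base), not real ownership, and
the flag marks them for caution rather than removal.

## Cleaning and annotation

* **Breed normalisation** (`normalize_breed()`): case/whitespace-insensitive
  lookup against a packaged, editable alias table; `"X x Y"` resolves to a
  recognised named cross (Cockerpoo, Labradoodle, …) or a canonical
  `"X x Y"`; `"X Cross"`/`"X Type"` become `"X cross/type"`; more than two
  parents or unknown lineage becomes `"Mix Breed"`; anything else matches
  the nearest alias within edit distance 1 or stays `"Unclassified"`.
  Unmatched input is a value, never an error. The shipped table is a
  starter covering the breeds a national ranking exercise needs; it is data,
  not code.
* **Ages** (`compute_age()`): DOBs arrive at month resolution and are
  resolved to the 15th — the unbiased within-month expectation — making age
  arithmetic exactly testable. The endpoint is the termination date for dead
  dogs, otherwise the date the data were received. Six developmental age
  groups partition $[0, \infty)$ with inclusive lower bounds (puppy < 0.5y,
  juvenile < 1y, young adult < 2y, mature adult < 7y, senior < 12y,
  geriatric ≥ 12y).
* **Filters** (`apply_filters()`): completeness (crossbred flag, status,
  sex) → age cap → liveness, in that order; the order affects only how drops
  are attributed per rule, not the surviving set, and the report's per-rule
  counts sum exactly to input minus output. The 18.3-year cap is the age by
  which ~95% of the pet population is dead; it exists to exclude dogs
  unlikely to still be alive in the study year. Liveness applies both
  conditions separately reported: status alive, or termination on/after the
  study-year start. Records with missing DOB are kept for abundance counts
  but flagged, since they cannot enter age demographics — keeping them
  preserves the count matrix while keeping age tables honest.

## Deduplication

Four phases, each a plain state-to-state function behind `dedup_records()`
so alternative phase definitions can be swapped in without touching the API:

1. **Exact** — byte-identical re-submissions: equality on all 18 schema
   fields with more than 10 populated. The stricter pairwise
   "mutually-non-missing agreement" reading is quadratic and its extra
   matches are recovered by the later phases' field-union merging.
2. **Microchip** — records sharing any 6-character chip suffix (directly or
   through chains) merge unless the group conflicts on sex or DOB; conflicts
   are counted and left alone.
3. **Keys** — blocking on postcode area; equality on the key quadruple
   (canonical breed, sex, DOB, name prefix) merges. A record with no
   reported breed text is treated as *missing* the breed key rather than
   carrying its fallback category.
4. **Partial** — records missing exactly one key merge with each other
   (same pattern, same area, equal on the three present keys) and then into
   a key-complete cluster when exactly one matches and chip evidence does
   not conflict. Records missing two or more keys stay singletons and form
   the unresolved fraction (denominator: records remaining after phase 1).

Survivorship is most-complete-record, ties to lowest record id — chosen so
the outcome is deterministic and invariant to input row order (a tested
property). Merged representatives union their members' non-missing fields so
later phases see everything known about the individual. Cluster membership
keeps per-source attribution, because the count matrix needs it.

`build_count_matrix()` defaults to **attributed** mode: $y_{ij}$ counts
distinct individuals attributed to source $j$ at area $i$ after global
deduplication, so a dog seen by $k$ sources contributes 1 to each of its
$k$ columns — that cross-source redundancy *is* the recapture signal, which
is why attributed is the default. `"per-source"` mode (within-source
deduplication only) is kept for sensitivity analysis. A cluster's area is
the modal member area, ties resolved to the most complete member's.

## The synthetic registry generator

Real registries are commercially sensitive; the generator stands in for
them with known ground truth so every downstream stage is testable. What it
emulates, and the calibration behind each default:

* **Abundance vs people.** Dogs-per-person follows a saturating
  (Michaelis–Menten-shaped) curve $d(h) = a\,h/(h_{1/2}+h)$, with
  $\lambda_i = h_i\,d(h_i)$ — per-capita ownership rises with population
  and levels off at the asymptote $a$ (default 0.25), matching the
  asymptotic relationship observed empirically between dog counts and human
  population. The closed-form limit makes the curve exactly testable.
* **Scale.** Defaults are 124 sites × 18 sources with log-normal human
  populations (log-mean $\log 1000$, log-sd 0.7). The site/source counts are
  the real study's; the populations are scaled down so a full
  simulate-clean-dedup cycle runs in seconds (~25,000 dogs, ~85,000 raw
  rows) while preserving the structure — per-capita levels, duplication,
  noise — that the pipeline must survive. Passing tests on this world shows
  the machinery is correct at realistic *structure*, not that it has been
  exercised at 12-million-dog *volume*.
* **Detection.** $p_{ij} = \mathrm{logit}^{-1}(\alpha_j + \beta_j z(h_i))$
  with $\alpha_j \sim N(-1.68, 0.6)$, $\beta_j \sim N(-0.3, 0.15)$ —
  detection worse in populous areas, heterogeneous across sources. The
  intercept mean was set by numerical calibration so that a detected dog is
  recorded by ≈ 2.8 distinct sources on average (the observed multi-source
  duplication factor); across seeds the realised value varies ≈ ±0.25.
* **Duplication and noise.** Byte-identical duplicate rows are injected to
  form 28.7% of the raw table (the observed exact-duplicate share);
  microchips are carried by 50.3% of dogs (0.02% with a second chip);
  per-field missingness rates are set so ≈ 6.2% of records lack at least
  one of the four deduplication keys
  ($1 - 0.990\cdot0.990\cdot0.980\cdot0.976 \approx 0.062$); breed text is
  perturbed by single-character edits, alias substitutions, and case jitter
  at a 5% row rate, giving `normalize_breed()` realistic work.
* **Demographics.** Roster attributes are drawn from packaged categorical
  tables: the national age-group distribution, a 51:49 sex ratio, an
  85.8/14.2 purebred/crossbred split with 39.3% of crossbreds being
  mix-breeds, and breed popularity weights.

What it does **not** emulate: real postcode strings, per-source market-share
structure (source coverages beyond the aggregate duplication factor are
free parameters, since only aggregate shares are published), insurance
policy semantics, socioeconomic gradients in ownership, and
under-registration of young dogs. Conclusions about those features cannot
be drawn from synthetic-world tests.

Every generator output is byte-deterministic given `sim_params()` including
the seed; sub-stages draw from seeds derived from the root.

## Problem sizes and schedules used by the tests

Unit tests run on a 20-site × 5-source world. The recovery and coverage
experiments simulate 20 sites × 5 sources with $\lambda_i \in [100, 500]$
and fit at the reduced schedule; coverage uses 20 replicates and expects
the 95% interval for $\sum N_i$ to cover truth in at least 16 (the binomial
tolerance around a nominal 0.95). Deduplication fidelity runs on the full
124 × 18 default world. These sizes keep the whole suite to a few minutes
while leaving each check statistically meaningful.

## Numerical and degenerate-input conventions

* Percentages round half away from zero to 1 decimal; ratios to 2 decimals
  in `r:1` form; replacement rates to 2 decimals in millions. Reported
  tables are therefore exactly reproducible.
* A zero crossbred count yields an infinite ratio with an explicit flag,
  not an error; an empty filter input yields zero counts; unmatched breed
  text is a value.
* `gelman_rubin()` returns 1 for identical constant chains and `Inf` for
  differing constant ones.
* Ties: breed rankings break alphabetically; dedup survivorship breaks to
  the lowest record id; modal-area ties go to the most complete member.

## Known limitations

* With one replicate per source, $\lambda$ and $p$ are only weakly
  separable; totals $\sum N_i$ are the reliable quantity, and per-parameter
  posteriors should be read with that in mind. How well even the total is
  identified depends on the detection level: the recovery and coverage
  experiments operate at per-source detection ≈ 0.2–0.6, where the
  posterior brackets the truth. When per-source detection drops well below
  ~0.2 — as in the generator's default registry world, calibrated to the
  observed ≈ 2.8 detections per dog across 18 sources — the flat
  Uniform(0,1)-equivalent detection prior dominates the split, detection is
  pulled toward the prior, and the abundance total shrinks toward the
  observed counts. This is a property of the model-plus-prior, not of the
  sampler (the fitted region has verifiably higher posterior density than
  the generating truth); analysts working in that regime should treat
  totals as lower-anchored and consider informative detection priors via
  `prior_spec`.
* Human population enters detection, so per-capita outputs partially reuse
  that covariate and deserve caution — the outlier flag exists for exactly
  the failure mode where one source's correction factor inflates a
  thin-coverage area.
* The phase 2–4 linkage rules are the package's operationalisation of a
  staged identifier/key procedure; the strategy interface exists so an
  exact replication of any other staged rule set can be dropped in.
* The model is closed-population: no births, deaths, or migration between
  occasions; all sources must reference the same study year.
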