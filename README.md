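# pacnet

Quantifying potential interspecific and intraspecific competition among
flower-visiting bee species that share floral resources.

## What it does, for whom

Pollination ecologists working with transect-based visitation surveys face a
recurring question: which bee species are pressing on which, and does that
pressure track floral scarcity, competitor abundance, or trait specialization
(proboscis length)? Direct competition experiments are infeasible at
community scale, but quantitative visitation networks carry the signal.
`pacnet` turns raw visitation records into that signal:

1. **Daily bipartite networks** — visitation counts pooled across transects
   per census day (`build_daily_networks()`).
2. **Müller's potential apparent competition (PAC) index** per network
   (`pac_matrix()`):

   $$d_{ij} = \sum_k \frac{a_{ik}}{\sum_l a_{il}} \cdot
     \frac{a_{jk}}{\sum_m a_{mk}}$$

   the potential influence of acting species $j$ on target species $i$
   through shared plants. Rows sum to 1; the diagonal $d_{ii}$ is the
   potential *intraspecific* competition; the off-diagonal column mean is the
   *interspecific* pressure an acting species exerts on the rest of the
   community.
3. **Mass-action abundance estimation** (`estimate_abundances()`): effective
   relative abundances inferred from the interaction matrix itself via the
   decomposition $F_{ij} = x_i x_j c_{ij}$, avoiding circularity between
   capture counts and visitation frequencies.
4. **Chao2 interaction sampling completeness** per year plus a
   Spearman effort check (`chao2_completeness()`).
5. **Gaussian mixed models** (glmmTMB, ML) of both indices against log-z
   floral density, log-z abundance, their interaction, z proboscis length,
   year and flowering period, with a species random intercept; type-II Wald
   tests, VIF screening and partial-residual tables
   (`fit_interspecific_model()`, `fit_intraspecific_model()`).
6. **A synthetic multi-year community generator** with skewed abundances,
   proboscis–corolla trait matching and seasonal floral phenology
   (`generate_community()`, `generate_competition_scenario()`), so the whole
   pipeline is testable without field data.

## Worked example

The hand-checkable 2×2 case — bee B1 makes 2 visits to plant P1; bee B2
makes 1 visit to each of P1 and P2:

```r
library(pacnet)
a <- matrix(c(2, 0, 1, 1), 2, 2, byrow = TRUE,
            dimnames = list(c("B1", "B2"), c("P1", "P2")))
pac_matrix(a)
#>       acting
#> target        B1        B2
#>     B1 0.6666667 0.3333333
#>     B2 0.3333333 0.6666667
```

B1 puts all its visits on P1, where it makes 2 of 3 bee visits, so two-thirds
of its resource use falls on plants it dominates itself ($d_{11} = 2/3$) and
one-third on B2's share ($d_{12} = 1/3$). Each row sums to 1.

A full synthetic run (5 years, 38 census days, 14 bee species):

```r
cfg <- pipeline_config(synthetic = synthetic_config(seed = 11),
                       outdir = "pacnet_out")
res <- run_pipeline(cfg, quiet = TRUE)
res
#> pacnet pipeline result: 38 daily networks, 511 model rows
res$completeness
#> # A tibble: 5 × 7
#>    year S_obs    Q1    Q2     m S_est completeness
#>   <int> <int> <int> <int> <int> <dbl>        <dbl>
#> 1  2018   331   163    69     5  482.        0.687
#> 2  2019   408   165    77     9  562.        0.726
#> 3  2020   405   175    69     9  598.        0.677
#> 4  2021   404   168    82     8  552.        0.732
#> 5  2022   369   168    60     7  566.        0.652
```

Interpretation: each year's observed distinct bee–plant links (`S_obs`)
against the Chao2-estimated link richness (`S_est`) — around 65–73% of the
interaction structure was sampled, and the per-year values can be tested
against survey effort with `effort_completeness_correlation()`. The fitted
models live in `res$model_inter` and `res$model_intra` (coefficient, Wald
and VIF tables are also written as CSVs under `outdir`), and
`partial_residuals(res$model_inter, "abundance_lz:floral_density_lz")`
returns the predicted interaction display at the 10th/50th/90th
floral-density quantiles.

A thin command-line wrapper ships at `inst/cli/pacnet.R`
(`Rscript pacnet.R all --seed 11 --outdir out`).

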