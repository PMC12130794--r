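---
title: "Quantifying potential competition for floral resources in visitation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying potential competition for floral resources in visitation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacnet)
```

## The problem

When several bee species forage in the same meadow they rarely interact
directly, yet they can still suppress one another by draining the standing
crop of shared flowers. The strength of that *potential* competition — both
between species and within a species — should depend on how much floral
resource is available, how abundant each competitor is, and how specialized
its feeding apparatus is. `pacnet` implements a complete analysis pipeline for
asking these questions with transect-based visitation data: daily quantitative
bipartite networks, a resource-overlap competition index per network,
abundance estimation that avoids circularity with the visitation counts
themselves, a sampling-completeness check, and Gaussian mixed models relating
the competition indices to floral density, abundance, proboscis length,
flowering period and year.

Because field data of this kind are expensive and often unavailable, the
package ships a first-class synthetic generator that produces multi-year
visitation and floral-survey datasets with the statistical structure the
analysis assumes. Every stage of the pipeline, including both mixed models, is
exercised and tested against that generator.

## The potential apparent competition (PAC) index

For one census day, pooling all transects, let $a_{ik}$ be the number of
individuals of bee species $i$ recorded on plant species $k$. Müller's index

$$
d_{ij} \;=\; \sum_k
  \frac{a_{ik}}{\sum_l a_{il}} \cdot
  \frac{a_{jk}}{\sum_m a_{mk}}
$$

measures the potential influence of *acting* species $j$ on *target* species
$i$ through the plants they share: the first factor is the fraction of $i$'s
visits that go to plant $k$, the second is $j$'s share of all bee visits that
plant $k$ receives. The index is 0 when the pair shares no plants and 1 when
$j$ monopolizes every plant $i$ uses; rows sum to exactly 1, an algebraic
identity the test suite asserts on random networks. The diagonal $d_{ii}$ is
the species' own contribution to the visitation of its plants — the potential
*intraspecific* competition; a species that monopolizes its resources competes
mostly with itself. Interspecific pressure exerted by species $j$ is
summarized as the mean of column $j$ excluding the diagonal.

Two conventions worth making explicit:

* the diagonal term is included in the defining sum (it *is* the
  intraspecific index), and
* aggregation is by acting species (columns), i.e. "how strongly does this
  species press on the rest of the community", not "how much pressure does it
  receive".

The index is computed in double precision with no smoothing or pseudo-counts;
a species absent on a day has no row that day rather than a zero row, so
degenerate zero-marginal matrices never reach the index.

## Mass-action abundance estimation

Bee abundance recorded as "individuals caught on flowers" is circular with
the interaction frequencies that define the networks. `estimate_abundances()`
therefore infers *effective relative abundances* from the interaction matrix
itself. Under the mass-action principle the frequency of a link is
$F_{ij} = x_i\,x_j\,c_{ij}$: the product of the partners' relative abundances
and a preference term. On the log scale over observed links this is an
additive two-way decomposition,

$$\log F_{ij} = \mu + r_i + s_j + \varepsilon_{ij},$$

fitted by least squares with sum-to-zero constraints; $x_i \propto e^{r_i}$
normalized to sum 1 per side, and $c_{ij} = F_{ij}/(x_i x_j)$ absorbs the free
scale. This is the minimal deterministic estimator consistent with the
principle: exact when the matrix is truly multiplicative (the tests require
recovery to $10^{-9}$), scale-invariant, and agnostic about unobserved links
(zeros are treated as unobserved, never as $\log 0$). Disconnected bipartite
graphs are estimated per connected component — the cross-component scale is
not identified, so components are weighted by their share of total visits and
a warning is raised.

A rank-recovery simulation in the acceptance suite draws log-normal
abundances (sd 1.2 across 6 bee species, 8 plants) and Poisson-noised
matrices with roughly $3\times10^5$ expected visits. That scale comes from an
a-priori power analysis of identifiability: per-cell expected counts in the
low thousands make the log-count noise an order of magnitude smaller than
typical adjacent gaps between log-abundances, so species ranks are recovered
perfectly in well over 95% of replicates. At much smaller totals the
estimator is unbiased but ranks of nearly-tied species can flip — a property
of the information content of the data, not of the estimator.

## Sampling completeness

Within each year, each distinct bee–plant link is treated as an incidence
"species" and each census day as a sampling unit. The bias-corrected Chao2
estimator

$$\hat S = S_{obs} + \frac{m-1}{m}\,\frac{Q_1(Q_1-1)}{2(Q_2+1)}$$

uses singleton ($Q_1$) and doubleton ($Q_2$) incidence counts across the $m$
days; completeness is $S_{obs}/\hat S$. The bias-corrected form is the
default because it remains defined when $Q_2 = 0$; the classic
$Q_1^2/(2Q_2)$ variant is available when doubletons exist. A Spearman rank
correlation between per-year effort (transects walked) and completeness
flags effort-driven artifacts.

## The competition models

Both responses are modeled with Gaussian mixed models (fitted with
`glmmTMB`): the mean interspecific index of each acting species per census
day, and the intraspecific (diagonal) index. Fixed effects are log-z floral
density, log-z estimated abundance, their interaction (abundant species are
predicted to press harder when flowers are scarce, i.e. a negative
interaction), z-scored proboscis length, year and flowering period
(categorical; first year and "early" are reference levels). Species identity
enters as a random intercept — no random slopes, since with a handful of
species slope variances are not estimable.

Numerical and reporting choices:

* **ML, not REML**, by default, so Wald tests and comparisons across
  fixed-effect structures are coherent; REML is a switch.
* **Transforms are computed over the rows entering each model** (not per
  year, not over the full table), and standardize to sample sd 1.
* **VIF screening** uses the main effects only: an interaction is collinear
  with its components by construction, so including it would inflate VIFs
  spuriously. Values are reported (generalized VIF for factors), not
  enforced; < 3 is the usual comfort zone.
* **Wald type-II chi-square** tests per term (via `car::Anova`); for a term
  not marginal to a higher-order term the single-df chi-square equals the
  squared coefficient z value, which the tests assert.
* Marginal p-values are reported as-is with no multiplicity correction.
* Non-convergence is flagged on the returned object, never silent.

`partial_residuals()` produces component-plus-residual tables for any term
and, for the abundance × density interaction, predicted fixed-effect lines at
the 10th, 50th and 90th floral-density quantiles — the standard display for a
continuous-by-continuous interaction.

## What the synthetic generator emulates

`generate_community()` produces the raw inputs (visitation records, floral
plot counts, a trait table) for a five-year weekly survey. Defaults mirror an
alpine-meadow study system: census days per year of `c(5, 9, 9, 8, 7)`
(38 networks), 14 bee species with log-normal relative abundances
(sdlog 1.5, so the top species takes > 40% of visits), 60 bee-visited plant
species, proboscis lengths spanning 6.5–14.5 mm against corolla depths of
2–16 mm, ~37 transects per census day and ~7.5 expected captures per
transect (≈ 10,000 individuals over five years). Floral availability follows
per-plant Gaussian phenologies whose peak days are centered in mid-July
(sd 18 days) with an extra exponential decline after early August, giving
the community-level late-season scarcity the analysis leans on. Visit counts
are Poisson with mean proportional to
$x_{\text{bee}} \times \text{availability}_{\text{plant}}(day) \times
c(\text{proboscis}, \text{corolla})$, where $c$ is a Gaussian kernel on the
trait mismatch (sd 3 mm) plus a floor of 0.2 so short-tongued generalists
still visit open flowers broadly.

What it does **not** emulate: colony dynamics and within-season worker
phenology, spatially explicit foraging, weather-driven sampling gaps,
observer error, or inflorescence-to-flower conversion (assumed applied
upstream). Passing tests therefore demonstrate that the pipeline recovers
known structure from data obeying its assumptions — not that real meadows
obey them.

`generate_competition_scenario()` skips the raw-data layer and directly
constructs a model-ready table whose responses follow the mixed-model linear
predictor with known coefficients (defaults: abundance +0.07 and
interaction −0.02 on the interspecific response, proboscis +0.08 on the
intraspecific response, residual sd 0.1, 38 days × 7 species = 266 rows).
It refuses coefficient vectors whose expected response leaves the index's
[0, 1] range over the typical (±2 sd) covariate box. Its species random-
intercept SD defaults to **zero**: the proboscis effect is a between-species
contrast identified from only 7 species, and unmodeled species-level noise
degrades the coverage of its Wald interval in a way no estimator can repair
(the classic few-clusters problem). With the default, the planted fixed
effects are the complete species-level structure and 2-SE coverage is
nominal; set `sd_species > 0` deliberately to stress the fitter.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_total` | 20 | total-count threshold below which a bee species is excluded (between the most abundant excluded and least abundant retained species of the motivating system) |
| season months | July–August | census window with adequate interaction frequencies |
| period boundaries | Jul 20 / Aug 20 | early ends Jul 20 (inclusive), middle ends Aug 20 (inclusive); the boundary day is assigned to the earlier stage, configurable |
| `chao2_variant` | bias-corrected | defined at $Q_2=0$; classic form optional |
| `ml` | TRUE | ML vs REML estimation |
| `kernel_sd_mm` | 3 | width of the trait-matching kernel; large values flatten preferences toward uniform |

## Degenerate inputs and tie-breaks

Zero-count rows are dropped at read time with a warning naming the lines;
unparseable dates are hard errors naming the row. A single-species daily
network has intraspecific index 1 and no interspecific value (absent, not
zero). Constant vectors are rejected by the z-transforms and by the
effort–completeness correlation. The rare-species filter is idempotent and
monotone in its threshold. All randomness flows from explicit mandatory
seeds; rerunning any generator or the full pipeline with the same
configuration is byte-identical.

## Problem sizes used in the test suite

Unit tests run on networks of up to 6 × 8 species and tables of a few
hundred rows. The heavier simulations — 100 Poisson rank-recovery
replicates, 50 planted-effect model-recovery replicates at 266 rows each —
complete in about a minute total; they are sized to make the Monte-Carlo
acceptance thresholds (≥ 95% and ≥ 90% success) statistically comfortable
rather than marginal.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  synthetic = synthetic_config(seed = 11),
  outdir = "pacnet_out"
)
res <- run_pipeline(cfg)
res$completeness
res$model_inter$coefficients
partial_residuals(res$model_inter, "abundance_lz:floral_density_lz")$lines
```

## Known limitations

* The PAC index quantifies *potential* competition through resource overlap
  and dominance; it is not evidence of realized fitness effects.
* The mass-action decomposition assumes preferences and abundances are
  separable on the day scale; systematic within-day turnover would be
  absorbed into the preference term.
* Gaussian models of a [0, 1] index are an approximation; near-boundary
  communities (a single hyper-dominant species) would call for a beta-type
  response instead.
* Effective abundances are relative within a day; cross-day comparisons
  inherit that normalization.
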