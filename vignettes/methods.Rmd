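---
title: "Models and methods behind kinomescanr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kinomescanr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kinomescanr` analyses kinome-wide competition-binding screens in which
every compound–kinase pair is summarised by percent-of-control (PoC)
readings at a handful of concentrations. This vignette documents the
statistical model, the synthetic-data generator, the parameter defaults
and the numerical choices, so that a user can judge what the package's
tests do — and do not — establish about real assay data.

## The observation model

The mean response of a binding pair follows the single-site
competition-binding (Hill) form

$$\mathrm{PoC}(c) = \frac{100}{1 + (c / K_d)^{h}},$$

where $c$ is the free compound concentration (nM), $K_d$ the
dissociation constant (nM) and $h$ the Hill slope ($h = 1$ for ideal
single-site binding). Non-binders have mean 100 at every concentration.
Observed PoC values are modelled as truncated normal around this mean on
$[0, U]$, with $U$ = 140 by default: real panels report values above
100 (the DMSO control is itself noisy), and a hard cap reflects the
bounded readout. The assay's observation-noise magnitude and
distribution are not published; additive Gaussian noise with sd 5
percent-control units is the package default — large enough that
single-dose binder calls are imperfect, small enough that four-dose
inference recovers affinities, which is the regime that makes multi-dose
screening worth evaluating. Both the noise sd and the cap are ordinary
configuration, not claims about the chemistry.

## Quality control

Curves are classified against the conventional 35%-control hit cutoff
into five classes (`non_binding`, `binding`, `weak_high`, `weak_low`,
`discordant`); see `?classify_curve` for the exact rules. Choices the
class definitions leave open, fixed here as recorded configuration:

- The weak-binder trend test is ordinary least squares of PoC on
  log10 concentration — the natural abscissa for Hill-type data — with a
  two-sided slope p-value plus an explicit negative-sign requirement.
- The discordant rule is read as: some reading below the cutoff is
  followed, at a higher concentration, by a reading above the cutoff at
  least two-fold higher than *any* lower-concentration reading.
  Discordance is tested first, because true binding requires all
  measurements to be concordant.
- Single-point curves are classified by the cutoff alone (`weak_low`
  below it, `non_binding` otherwise): one sub-cutoff point without a
  dose trend is weak evidence by construction.

A property test checks the classifier against an independent brute-force
statement of the five rules on all $6^4$ PoC grids over
$\{5, 20, 34, 36, 70, 100\}$.

## Bayesian hierarchical K_d inference

Per curve $j$ the parameters are $\theta_j = \log_{10} K_{d,j}$ and
$\eta_j = \log h_j$. Priors and pooling:

- $\theta_j \sim \mathrm{Uniform}(-0.5,\; 6.5)$ (about 0.3 nM–3 mM),
  spanning the assay's four tested decades with margin on both sides so
  the data, not the prior, locate in-range estimates;
- $\eta_j \sim N(m_{c(j)}, \sigma_w)$ with compound-level means
  $m_c \sim N(0, \sigma_b)$ and
  $\sigma_w = \sigma_b = 0.35/\sqrt{2}$, so the marginal Hill-slope
  distribution is log-normal centred at 1 with sd 0.35 on the log scale
  and compounds share slope information across their targets;
- a single observation sd pooled across all curves, half-normal(10).

Sampling is a random-walk Metropolis-within-Gibbs sweep, vectorised
across curves: all $(\theta_j, \eta_j)$ pairs are proposed jointly per
iteration, compound means are conjugate normal draws, and the global log
observation sd takes a scalar step. Step sizes adapt per curve during
warmup toward ~30% acceptance. Defaults are 4 chains of 1000 draws after
500 warmup iterations; split-Rhat and effective sample size come from
`coda`, and estimates with Rhat > 1.1 are flagged `nonconverged` but
retained. A deterministic MAP-plus-Laplace mode (`sampler = "map"`)
serves bulk runs that do not need calibrated intervals; it initialises
from a coarse grid over $\theta$ to avoid the flat-likelihood plateau of
non-binding curves.

The point estimate is the posterior median, which is robust to the skew
of partially censored posteriors. Censoring flags are asymmetric on
purpose: a pair is `above_range` when the posterior median (or the whole
95% interval) exceeds the top tested concentration — such pairs are
consumed downstream as non-binding — but `below_range` only when the
*entire* interval falls below the lowest dose, because a potent median
whose interval reaches into the tested range is still data-constrained,
and sub-range potencies are precisely what such screens are used to
report. Curves classified `weak_low` are fitted but flagged, since a
single sub-cutoff reading without trend support is low-confidence
evidence; `discordant` curves and listed qPCR dropouts are excluded
before fitting.

On a seeded synthetic set of 200 binder curves at the default noise
(sd 5, four doses), the test suite requires mean absolute error of
$\log_{10} K_d$ at most 0.25 and 95%-interval coverage within
$[0.85, 0.99]$.

## Selectivity metrics

For one compound with finite affinities $K_{d,i}$:

- partition index $PI_i = (1/K_{d,i}) / \sum_j (1/K_{d,j})$;
- predicted engagement
  $E_i = 100 / (1 + (K_{d,i}/K_{d,\mathrm{ref}})^{h_i})$ at the
  concentration $K_{d,\mathrm{ref}}$ of the most potent target;
- $\mathrm{CATDS}_{\text{most-potent}} = E_{\mathrm{ref}} / \sum_i E_i$.

Censored-above pairs are excluded from both sums (non-binder
semantics); missing Hill slopes default to 1; ties for the reference
target break lexicographically and are recorded. TAS bins are half-open
and lower-inclusive: below 100 nM → 1, 100 nM–1 µM → 2, 1–10 µM → 3,
at or above 10 µM → 10. Assay descriptions sometimes bound the
strongest bin at the lowest tested concentration (12.5 nM), leaving
12.5–100 nM unassigned; this package closes that gap at 100 nM, the
boundary consistent with the TAS-2 bin starting there. The
chemical-probe filter requires minimum $K_d$ < 100 nM and CATDS > 0.5
attributed to a single kinase.

## Design evaluation

Single-dose screening is scored by confusion counts of "PoC below
cutoff" against a reference binder definition ($K_d$ below a goal
threshold), over an integer cutoff grid 1–99. The optimal-cutoff
objective is configurable — Youden's J by default, F1, or fewest false
positives under a false-negative ceiling, the trade-off screening
scenarios usually articulate.

Two-dose designs are compared with the four-dose reference by R² and
MSE of $\log_{10} K_d$. Two computations are provided: restricted to
pairs uncensored in both fits (`pairs = "co_finite"`), or over every
shared pair using posterior medians regardless of censoring
(`pairs = "all"`). The all-pairs form is the more informative ranking
statistic: a design that lacks the top assay concentration mislocates
every non-binder, and the co-finite restriction silently discards
exactly those failures. On the default seeded dataset the
(100 nM, 10 µM) pair minimises the all-pairs MSE across all six dose
pairs, and multi-dose binder classification (F1 at a 1 µM threshold)
beats the best single-dose cutoff — the direction of effect that
motivates two-dose screening.

## Affinity-profile clustering

Kinase–kinase distances are 1 minus the Spearman correlation of
$\log_{10} K_d$ profiles over compounds measured for both kinases.
Missing-data policy: pairwise-complete profiles with a minimum overlap
of 10 compounds by default; imputation is rejected outright, since
fabricating affinities would manufacture similarity. Censored-above
cells enter the ranking as a shared top rank by default, so joint
non-binding counts as agreement (configurable to `"missing"`). Linkage
is average by default and the cluster count is exposed (`k = 9` in the
pipeline, mirroring the major-cluster granularity such analyses report);
both are configurable because no linkage or cut is canonical for this
distance. Cluster labels are compared with sequence-based kinome groups
by cross-tabulation and the adjusted Rand index.

## The synthetic generator and what the tests do (not) show

`generator_config()` defaults describe a desk-scale screen: 24 compounds
by 50 kinases at the four standard concentrations, collected in the
two-batch structure real panels use (10 µM with 100 nM, 1 µM with
12.5 nM); a 15% binder fraction; binder $\log_{10} K_d$ uniform on
$[0, 4]$ (1 nM–10 µM, the assay's informative span); Hill slopes
log-normal(0, 0.35); qPCR dropouts at 0.3% of measurements (the order
observed in practice) written as exactly 100; and discordant artifacts
injected into 2% of curves by post-hoc corruption — the lowest reading
forced below the hit cutoff and a higher-concentration reading inflated
above it — matching their interpretation as liquid-handling/batch
errors rather than any binding mechanism. Compound metadata uses
clinical-status quotas 44:98:50 (approved:clinical:tool) and kinase
categories 406:59:3 (WT:mutant:non-mammalian), the composition of a
full-scale 192 × 468 screen, scaled to the configured sizes. Assigned
targets are drawn from each compound's binders with weight
$1/\sqrt{K_d}$, so the assigned target is usually potent but not always
the top-affinity target — leaving room for the assigned-target-rank
analysis to be non-trivial.

Because the generator samples from the same Hill-plus-truncated-normal
family the model fits, parameter-recovery results certify the inference
machinery, not the adequacy of the Hill form for real qPCR readouts. The
generator does not simulate bead-competition kinetics, plate layouts,
correlated plate effects, or compound insolubility at high
concentration; passing tests therefore demonstrate correctness of the
implementation and internal calibration, not assay-level validity.

## Numerical choices and limitations

- Truncated-normal sampling uses the inverse-CDF transform; a zero
  noise sd degenerates to clipping the mean, which keeps noiseless
  fixtures exact.
- Deterministic quota allocation (largest remainder) makes metadata
  category counts reproducible and exact at any library size.
- All randomness flows from explicit integer seeds; the pipeline
  derives stage seeds from one master seed and its outputs are
  byte-identical across reruns.
- Problem sizes in the test suite (e.g. 200 recovery curves, a
  24 × 50 design-evaluation screen, 8 × 12 pipeline runs) are chosen so
  the whole suite runs in minutes on a single CPU while keeping the
  Monte-Carlo error of the checked statistics well inside their
  tolerances.
- Known limitations: no batch-effect correction terms in the model (the
  generator's batch labels are carried but not modelled); enrichment
  tests condition on the library's type composition rather than a
  per-kinase matched null; hierarchical pooling is on Hill slopes only,
  not on affinities, so compounds with many weak targets borrow no
  strength across pairs.
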