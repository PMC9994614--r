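---
title: "Partitioning biodiversity effects and decomposing community trait change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning biodiversity effects and decomposing community trait change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overyield)
library(dplyr)
```

## The problem

Grassland biodiversity experiments sow plant communities of controlled
species richness and composition and ask whether mixtures outperform the
expectation built from monocultures ("overyielding"), and why. `overyield`
implements the analysis chain for a blocked dominance-experiment design:

1. **Additive partitioning** of each mixture plot's net biodiversity effect
   (NE) into complementarity (CE) and selection (SE) components.
2. **Community-weighted mean (CWM) traits** and their decomposition into a
   composition/abundance component and an intraspecific adjustment
   component, with a sequential ANOVA attribution of how much of each the
   richness gradient explains.
3. A **two-order mixed-model comparison** that separates "more species" from
   "a particular species is present" explanations, including a
   neutralization verdict.
4. A **synthetic experiment generator** with known ground truth, used for
   calibration and recovery testing of everything above.

## Additive partitioning

For species $i$ sown at proportion $p_i$ in a plot of richness $S$, with
monoculture yield $M_i$ and observed mixture yield $Y_i$, the expected
relative yield is $RY_{E,i} = p_i$, the observed one $RY_{O,i} = Y_i/M_i$,
and $\Delta RY_i = RY_{O,i} - RY_{E,i}$. Per species,

$$SE_i = (\Delta RY_i - \overline{\Delta RY})\,(M_i - \bar M), \qquad
  CE_i = M_i\,\Delta RY_i - SE_i,$$

with unweighted means over the $S$ sown species; the plot totals are
$SE = \sum_i SE_i$, $CE = \sum_i CE_i$ and $NE = CE + SE$, which equals both
$\sum_i M_i \Delta RY_i$ and $\sum_i Y_i - \sum_i p_i M_i$. These identities
are enforced in the test suite to $10^{-9}$ relative tolerance, against
independent closed-form oracles ($CE = S\,\overline{\Delta RY}\,\bar M$ and
$SE = S\,\mathrm{cov_{pop}}(\Delta RY, M)$).

Conventions worth making explicit:

* $RY_{E,i}$ is the sown proportion ($1/S$ under equal-density sowing); the
  field is kept general so unequal designs remain representable.
* Species sown but absent at harvest enter with $Y_i = 0$, hence
  $\Delta RY_i = -p_i$. Dropping them would bias NE upward and break the
  sown-composition bookkeeping.
* Monoculture reference yields average **all** monoculture plots of a
  species across blocks. A species with no usable monoculture cannot be
  partitioned; the package asks the caller to flag it inactive (the standard
  treatment for species that went extinct experiment-wide).
* Monoculture plots carry no biodiversity effect: they are reported with
  $NE = CE = SE = 0$ and excluded from the tests against zero.
* A mixture where every species died is not an error: it returns the
  all-negative $NE = -\sum_i p_i M_i$.

Because NE, CE and SE take both signs and have right-skewed magnitudes, the
tests against zero first apply the odd square root
$\operatorname{sign}(y)\sqrt{|y|}$ (`signed_sqrt()`). The grand-mean test
fits an ANOVA on block, log2 richness and mixture identity among mixture
plots and compares $n\,\bar y^2$ against the model's residual mean square
($F_{1,\nu}$ with $\nu$ the residual df). We deliberately use the plain
grand mean over plots rather than the fitted intercept of an effect-coded
model: the latter weights mixture identities equally, and under the strong
variance heterogeneity that dominance induces (plots containing the dominant
are far noisier) its model-based standard error is badly miscalibrated,
whereas $\mathrm{Var}(\bar y) = \overline{\sigma^2}/n$ matches the residual
mean square under heteroscedasticity. Whether such tests should use the
residual stratum after mixture identity or a dedicated mixture-identity
stratum is ambiguous in practice; the residual stratum is used and recorded
in the result's metadata (`glance()`).

## CWM decomposition and variance attribution

The CWM of trait $t$ in a plot is $\sum_i p_i t_i$ with $p_i$ the species'
share of sown-species biomass among species **present at harvest** — weights
are defined by biomass, and extinct species have none. Three variants are
computed per plot:

* `cwm_specific`: plot-specific trait values $t_{i,\text{plot}}$;
* `cwm_fixed`: the same weights with pool-wide species means (unweighted
  over the plots where the species was measured), so it moves only with
  composition and abundance;
* `cwm_adjust = cwm_specific - cwm_fixed`: intraspecific adjustment.

The identity `specific = fixed + adjust` holds exactly by construction. To
attribute richness-driven variance, each component is the response of a
sequential (Type-I) ANOVA with terms ordered block, richness, mixture
identity, and the richness sum of squares is expressed as a percentage of
the **total SS of the specific CWM** for all three responses. Using one
common denominator is what makes the shares commensurable and gives the
additive identity

$$\text{specific\%} = \text{fixed\%} + \text{adjust\%} + \text{covariation\%},$$

where the covariation share is negative when the two components trend in
opposite directions along the gradient (e.g. a trait whose composition
component rises with richness while individuals adjust downward). Because
Type-I SS of richness depends only on terms fitted before it, the placement
of mixture identity after richness does not affect the attribution; it is
retained to mirror the testing model. Richness enters as log2(sown
richness) by default, consistent with the log-linear models elsewhere in
the pipeline; a categorical coding is exposed
(`richness_coding = "factor"`).

Community-level root traits (RLD, SRL) and soil variables have no
species-level values, so they bypass the decomposition and are analyzed
only at plot level.

## The two-order model comparison

For a response $y$ per plot, a focal species' 0/1 sown-presence indicator,
and richness $r$ (log2 sown richness by default; realized richness
optionally), the procedure fits by maximum likelihood:

* null: $y \sim 1 + (1|\text{block}) + (1|\text{mixture identity})$
* model 1: add $r$, then presence;
* model 2: add presence, then $r$.

Each added term is assessed with a 1-df likelihood-ratio test against the
preceding model. Verdicts at $\alpha = 0.05$ with a marginal band up to
0.10 (both configurable):

* **identity significant** — the presence term is significant in *both*
  orders;
* **richness neutralized** — richness is at least marginally significant
  when fitted first but not significant once fitted after presence. This is
  the signature that the focal species' presence, which is itself more
  probable at high richness, carries the apparent richness effect.

Species are tested one at a time in separate model pairs; interaction terms
between richness and identity are not fitted. ML (not REML) is required for
valid LRTs on fixed effects. When every mixture identity occurs in a single
plot its random intercept is indistinguishable from the residual and the
model downgrades to a block-only random structure with a warning.
Non-convergence is surfaced as an error naming the failing model. The LRT
statistics are invariant to affine rescaling of the response (verified to
$10^{-6}$ in the tests).

## The synthetic generator

The generator emulates the statistical structure the pipeline assumes — it
is a study design, not a mechanistic plant-soil model:

* **Design**: 4 blocks; richness levels 1/2/6/7 over a seven-species pool
  (four grasses, one forb, two legumes; the top level is the full pool);
  every species has a monoculture, every unordered pair occurs with two or
  three replicates, higher-level subsets are replicated round-robin;
  replicate identities are placed in different blocks. The default plot
  counts (7/46/24/8, 85 plots) match the sampled size of the long-term
  dominance experiment the design emulates.
* **Biomass**: monoculture yields are lognormal around the species'
  expected yield `mu_M` with CV `biomass_cv` (default 0.15 — biomass is
  positive and right-skewed, so noise is multiplicative); mixture yields are
  $p_i\,\mu_i\,(1 + \texttt{ce\_slope}\,\log_2 S +
  \texttt{se\_dominance}\,\mathbb{1}[\text{dominant}])$ times a shared
  log-scale block factor and mean-one lognormal noise. `ce_slope` (default
  0.15 per doubling) produces a uniform proportional gain — pure
  complementarity (SE exactly 0 when it acts alone); `se_dominance`
  (default 0.25) gives the dominant an extra relative yield — positive
  selection. The default pool's yields and trait means are realistic values
  for mesophilic grassland dominants, with one tall, highly productive
  grass (`Ae`) as the default dominant.
* **Ground truth**: the noise-free expected yields are fed through the
  package's own partition against the true monoculture means, so every
  recovery test compares estimates against an exactly known target.
* **Traits**: species-level values are pool mean + plasticity slope ×
  log2 richness + Gaussian noise, generated only for species present at
  harvest; defaults encode taller growth in mixtures and declining leaf N,
  leaf P and AMF colonization. **Plot-level variables** (RLD, SRL, soil pH,
  organic C, total N, available P and K) are linear in log2 richness with an
  additive shift under dominant presence, additive Gaussian block
  intercepts, and Gaussian noise; default directions follow long-term
  grassland observations (pH falls with richness, organic C, N, P, K and
  RLD rise, SRL falls).
* Optional Bernoulli extinction at high richness exercises the
  realized-richness paths.

What the generator does **not** emulate: temporal dynamics (the design is a
single-harvest snapshot), spatial autocorrelation within blocks, density
compensation or size-asymmetric competition, and any causal coupling
between soil change and trait change — the causal template is imposed by
configuration, not learned. Passing recovery tests therefore demonstrates
that the estimators recover the effects they target under the assumed
noise structure, not that those assumptions hold in any particular field
dataset.

## Calibration, scenarios and problem sizes

The test suite runs Monte-Carlo checks at deliberately chosen sizes:

* *Type-I calibration* (1000 replicate experiments, all generator effects
  zero): the grand-mean F test of NE and the per-term LRTs must reject in
  [0.03, 0.07] at $\alpha = 0.05$. The partition in this check uses the
  generator's true monoculture means as reference. With an *estimated*
  reference (one monoculture per species), the reference's sampling error
  is shared by every mixture plot and shifts the grand mean of NE
  coherently; no per-plot test can hold its size under that dependence.
  This is a real limitation of partitioning with few monoculture replicates
  — the package documents it rather than hiding it: grand-mean tests on
  empirically referenced effects are conditional on the realized
  monoculture draw.
* *Neutralization recovery* (200 replicates per scenario at the 85-plot
  design): an identity-only scenario (soil pH shifted by −0.2, i.e. 2.5
  residual SDs, under the dominant; no richness slope) must be flagged
  neutralized ≥ 90% of the time, and a richness-only scenario (slope −0.1
  per doubling, no identity shift) must not.
* *Plasticity recovery*: with zero plasticity the adjustment share of
  richness-explained variance stays at the noise floor (the null
  expectation of a Type-I share with 1 numerator df among ~83 total is
  ≈ 1.2%); with a tall dominant gaining share while height plasticity is
  negative, the covariation share is reliably negative — the qualitative
  signature of anticorrelated composition and adjustment components.
* *Parameter recovery*: over replicate experiments at default noise, the
  implied complementarity slope (from regressing CE against
  $\log_2 S \cdot \bar M_{\text{sown}}$) recovers `ce_slope` with a modest
  upward bias caused by the convexity of $1/\hat M_i$ — another documented
  consequence of estimating the reference from a single monoculture.

Numerical conventions: partition identities are asserted to $10^{-9}$
relative tolerance; `ztransform()` refuses constant input; a CWM is
undefined for a plot with zero total biomass; missing trait values for
present species either error (default) or renormalize the weights with a
warning; saturated error strata (zero residual df) are refused with an
instruction to drop terms; design terms with a single level are dropped
from the ANOVA formulas automatically.

## A compact worked session

```{r pipeline}
sim <- simulate_experiment(seed = 42)
pe <- partition_effects(sim$dataset)
tidy(test_effects_positive(pe))

attribute_variance(decompose_cwm(sim$dataset, "plant_height"), sim$dataset)

pf <- plot_frame(sim$dataset) |>
  dplyr::left_join(tibble::as_tibble(pe)[c("plot_id", "NE")], by = "plot_id")
grid <- seq_test_grid(pf, c("biomass_total", "NE"), c("Ae", "Gp", "Tp"),
                      transforms = list(biomass_total = sqrt,
                                        NE = signed_sqrt))
classify_table(grid)
```

## Known limitations

* Grand-mean tests of empirically referenced effects are conditional on the
  monoculture draw (see above); with one or two monocultures per species
  this is unavoidable in the design itself.
* The tri-partite extensions of the partition (dominance/trait-dependent
  complementarity) and Rao-based functional-diversity decompositions are out
  of scope.
* No multiple-testing correction is applied across the response × species
  grid; the two-order "significant in both models" rule is itself a
  conservative filter, but users scanning many responses should apply their
  own control.
* REML-based small-sample df corrections (Satterthwaite, Kenward-Roger) are
  not provided; the LRT calibration at the default design size is verified
  by simulation instead.
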