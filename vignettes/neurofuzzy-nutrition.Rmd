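---
title: "Neurofuzzy modeling of mineral nutrition in plant tissue culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neurofuzzy modeling of mineral nutrition in plant tissue culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrifuzz)
```

## The problem

Culture media for plant tissue culture are assembled from mineral salts, but
plants respond to ions, not reagents: varying CaCl~2~ varies calcium and
chloride together, and several salts contribute to the same sulfate pool.
`nutrifuzz` analyses factorial nutrition experiments in three stages:

1. **Ion split.** Salt-based formulations (mg/L) are converted to ion molar
   concentrations (mM), removing the reagent-level confounding. The shipped
   registry covers the Murashige & Skoog (MS) salts, and the packaged media
   table holds a nine-medium dilution series: full MS, plus half, quarter,
   eighth and zero strength of either the macronutrient or the micronutrient
   salt group, with the EDTA-chelated iron source constant.
2. **Classical screen.** Factorial ANOVA with Tukey HSD letters flags which
   design factors matter at all, plus Kolmogorov–Smirnov and Levene checks.
3. **Neurofuzzy model.** An additive model of small tensor-product B-spline
   submodels is grown by an ASMOD-style structure search, and the fitted
   basis is read back as linguistic IF–THEN rules with membership degrees.

## The model

For output $y$ the model is

$$\hat y(x) = w_0 + \sum_j s_j(x), \qquad
  s_j(x) = \sum_{k} w_{jk}\, B_{jk}(x),$$

where each submodel $s_j$ depends on at most three inputs and $B_{jk}$ are
tensor products of order-2 (piecewise-linear) B-splines over normalized
inputs, or indicator bases for categorical inputs (genotype, subculture).
Order-2 splines are triangular membership functions, so each basis function
*is* a fuzzy set (Low/Mid/High), which is what makes the rule readout exact
rather than post-hoc.

Fit quality uses
$\mathrm{MSE} = \tfrac1n\sum_i (y_i - y_i')^2$ and the train-set
$R^2 = \big(1 - \sum_i (y_i-y_i')^2 / \sum_i (y_i-\bar y)^2\big)\times 100$,
with an F-style ratio $(R^2/df_1)\,/\,((100-R^2)/df_2)$, $df_1 = p-1$,
$df_2 = n-p$. A model is accepted when $R^2 > 70\%$ and the f-ratio exceeds
both 4 and the $F_{0.05}(df_1, df_2)$ critical value; $R^2 > 99.9\%$ is
flagged as over-fitting.

**Coefficient bookkeeping.** Every tensor-product block spans the constant
function, so from the second submodel on one coefficient is redundant with
the global bias: $p = 1 + \sum_j c_j - \max(0, m-1)$ for $m$ submodels with
block sizes $c_j$. A genotype(3)×Cu(2) block plus an NH~4~(2) block gives
$p = 8$, hence $df = (7, 100)$ at $n = 108$; a genotype(3)×SO~4~(2)×MoO~4~(3)
block plus subculture(4)×Na(2) gives $p = 26$, hence $(25, 82)$.

## Structure search and model selection

The search starts from the bias-only model and, at each step, scores every
legal refinement with ridge-refitted weights (ridge factor $10^{-6}$,
applied uniformly; it also regularizes the one-per-extra-submodel rank
deficiency of the stacked partition-of-unity blocks):

* add a univariate submodel on an unused input at the initial set density
  (two sets);
* merge two submodels into a tensor product (≤ 3 inputs);
* tensor-expand an existing submodel with an unused input. This classical
  ASMOD refinement is essential in practice: an interaction whose marginal
  effect is weak never earns a univariate submodel first, and without the
  expand move the greedy search stalls well short of the attainable fit;
* insert one node at the midpoint of the widest inter-knot interval of a
  continuous input (ties to the lower interval; ≤ 15 nodes per input);
* prune — delete a submodel, split a tensor into its marginals, or remove a
  node.

The best strictly-improving move is accepted (ties broken by lower
criterion, then fewer parameters, then the lexicographic move label), and
the search stops at the first local optimum. Final submodels are ordered by
their drop-one criterion contribution.

The default selection criterion is structural risk minimization,
$\mathrm{score} = \mathrm{MSE} / (1 - \sqrt{\varepsilon})$ with
$\varepsilon = C_1\,[\,p(\ln(2n/p)+1) + C_2\,]/n$, $C_1 = 0.95$,
$C_2 = 4.8$, and an infinite score once the capacity term reaches 1. The
commercial implementations of this criterion are proprietary; this
Vapnik-style guaranteed-risk form with the standard constants is isolated
behind the criterion interface, and MDL, BIC, 5-fold CV (genotype-
stratified, seeded — the only stochastic step in training) and LOOCV (exact
ridge hat-matrix form) are available alternatives. Note that at very small
$n$ the SRM capacity term exceeds 1 for every $p$, so toy-scale comparisons
in the tests use MDL.

## Rule extraction

For each submodel and each combination of one fuzzy set (or categorical
level) per input, the submodel is evaluated at the combination's
characteristic point — at a basis peak the activation is exactly the
corresponding coefficient — plus the global bias and the other submodels'
average contribution. The value is normalized against the model's
fitted-value range and clamped to $[0,1]$, giving the High membership $m$;
the rule is emitted as High with membership $m$ when $m \ge 0.5$ (the tie
goes to High, an arbitrary but documented choice) and Low with $1-m$
otherwise, so the two memberships of every combination sum to one.
Characteristic values at the peaks can overshoot the fitted range slightly;
clamping is what produces saturated 1.00 memberships at the extremes of the
experimental space. Support intervals of each fuzzy set are reported back
in original units (mM or µM) from the fitted knot positions.

## The synthetic-data generator

No raw measurements ship with the package, so every downstream stage is
exercised on generated data with the statistical structure the analysis
assumes: the full 3 genotypes × 9 media × 4 subcultures crossing
(108 treatments), responses built from planted effect surfaces on the
normalized ion/factor space plus homoscedastic Gaussian noise with standard
deviation equal to `noise_fraction` (default 0.10) of each output's signal
range. The default planted structure mirrors the interaction pattern this
kind of screen reports on *Bryophyllum*-type data — genotype×Cu and an NH~4~
ramp for shoot length; genotype×SO~4~×MoO~4~ plus subculture×Na for root
length and plantlet number; genotype×NH~4~ for leaf number;
genotype×SO~4~×MoO~4~ for aerial fresh weight; genotype×Cu×SO~4~ plus a
negative molybdate ramp for root fresh weight — with the qualitative
directions of the corresponding rule summaries (BT benefits from low
copper, high sodium raises rooting at every subculture, and so on).
Surfaces are piecewise-linear in the normalized inputs so that a
triangular-membership learner can represent them exactly. Count-like
outputs (PN, LN) are rounded to nonnegative integers, and plantlet number
is forced to zero on media lacking a whole nutrient group, emulating the
total inhibition of plantlet formation on mineral-free media. By default
one noisy treatment-mean row is generated per treatment ($n = 108$, the
scale at which the published degrees of freedom are consistent);
replicate-level generation (20 replicates) is available.

**What the generator does not emulate.** Real measurements have
heteroscedastic, possibly skewed errors, epigenetic drift across
subcultures, and responses that are not exactly piecewise-linear in ion
space. Passing tests therefore demonstrate that the pipeline recovers
planted structure under its own assumptions, not that any particular
biological conclusion is correct.

**Confounding is a property of the design, not a bug of the learner.** In a
grouped dilution series all pure-macronutrient ions carry exactly the same
normalized column (NH~4~, NO~3~, Ca, Mg, H~2~PO~4~, and K and Cl up to a
0.03% admixture), and likewise all pure-micronutrient ions including sodium;
sulfate is the one mixed column (≈ 0.92·macro-dose + 0.09·micro-dose).
Individual ions are therefore identifiable only up to the linear span of the
selected columns, and `recovery_report()` scores planted-input recall
accordingly: a planted ion counts as recovered when its design column is
reproduced ($R^2 \ge 0.995$) by the inputs the model selected; categorical
factors must be selected themselves. The exact alias classes are attached to
every generated dataset. A related limitation: some linguistic cells of the
published rule format (for example low sulfate with mid molybdate) do not
exist on the design manifold — low sulfate occurs only in macro-diluted
media, where molybdate is at full strength — so the default surfaces are
parameterized to be non-degenerate on the realizable cells.

## Numerical choices and degenerate inputs

* Continuous inputs are affinely normalized to $[0,1]$ over their observed
  range; out-of-range prediction inputs are clamped. Constant columns are
  dropped with a warning.
* Ion concentrations are carried in mM throughout; reports print micro ions
  in µM.
* Dilution-series amounts are rounded half-up to two significant figures
  (never coarser than one decimal), the precision at which such media
  tables are printed, so the packaged table regenerates exactly.
* A constant response returns the bias-only model flagged `uninformative`;
  fit statistics require $n > p$ and a non-constant response.
* Treatment-mean tables have one row per design cell, so the pipeline's
  factorial ANOVA drops interaction terms there (they are saturated);
  replicate-level tables keep the full factorial decomposition.
* Type-I sums of squares on the balanced full crossing (identical to
  Type III there); count responses are analysed by ANOVA, not Poisson
  regression, matching the large-replicate practice this pipeline mirrors.
* Tukey letters come from a greedy insert-absorb sweep over groups ordered
  by mean; ties are broken by group order.

## Problem sizes used by the tests

The test-suite and the acceptance script run at the design scale of the
study they emulate: 108 treatment means, six outputs, 18 candidate inputs.
Monte-Carlo properties use 20 seeds (recall monotonicity across noise
fractions 0.3/0.1/0.03), 50 seeds (null calibration of the quality gate on
pure-noise responses) and 1000 permutations (ANOVA level calibration);
exhaustive-enumeration checks of the greedy search run on 8-row, two-input
toys where all reachable structures can be scored directly.

## Known limitations

* The structure search is greedy; equality with exhaustive enumeration is
  verified on two-input toys, but global optimality is not guaranteed at
  scale.
* SRM constants $C_1, C_2$ are taken as given; the criterion form is a
  reconstruction, pluggable but not validated against any proprietary
  implementation, and published per-output $R^2$/MSE values from real data
  are explicitly not reproduction targets.
* Only order-2 splines are supported: interpretability as triangular fuzzy
  sets is the point of the method, and higher orders would break the exact
  rule readout.
* No speciation/chelation chemistry, pH, or activity corrections: the ion
  split is stoichiometric arithmetic.
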