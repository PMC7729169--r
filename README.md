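# nutrifuzz

Neurofuzzy analysis of mineral-nutrition factorial experiments in plant
tissue culture.

Culture media are assembled from salts, but plants respond to ions: varying
CaCl₂ varies calcium and chloride together, and several salts feed the same
sulfate pool. `nutrifuzz` is for researchers running media-optimization
experiments (typically Murashige & Skoog dilution series crossed with
genotypes and subcultures) who want to know *which ions, at which levels,
drive which growth responses* — including interactions that factorial ANOVA
flags but cannot localize to individual nutrients.

The pipeline has three stages:

1. **Ion split** — salt formulations (mg/L) become ion molar concentrations
   (mM): for each ion, concentration = Σ over salts of
   (mg/L ÷ molar mass) × stoichiometric count. The packaged registry covers
   the MS salts; the packaged media table holds the nine-medium dilution
   series (full MS; half/quarter/eighth/zero strength of the macro- or
   micronutrient group; iron/EDTA constant).
2. **Classical screen** — factorial ANOVA with Tukey HSD compact letters,
   Kolmogorov–Smirnov and Levene checks.
3. **Neurofuzzy model** — an additive model of tensor-product order-2
   B-spline submodels (≤ 3 inputs each), grown by an ASMOD-style
   grow/refine/prune search with ridge-fitted weights (ridge 10⁻⁶) under a
   structural-risk-minimization criterion
   score = MSE / (1 − √ε), ε = C₁[p(ln(2n/p)+1) + C₂]/n (C₁ = 0.95,
   C₂ = 4.8; MDL/BIC/CV/LOOCV pluggable). Fit quality per output:
   MSE = Σ(yᵢ − yᵢ′)²/n, Train-Set R² = (1 − Σ(yᵢ − yᵢ′)²/Σ(yᵢ − ȳ)²)×100,
   f-ratio = (R²/df₁)/((100 − R²)/df₂) with df₁ = p − 1, df₂ = n − p;
   accepted when R² > 70%, f-ratio > 4 and > F₀.₀₅(df₁, df₂); R² > 99.9%
   is rejected as over-fitting. Because order-2 B-splines are triangular
   fuzzy membership functions, the fitted basis is read out exactly as
   linguistic IF–THEN rules (Low/Mid/High antecedents, Low/High consequents)
   with membership degrees in [0, 1].

A seeded synthetic-data generator emulates the full 3 genotypes × 9 media ×
4 subcultures design (108 treatments, six growth responses) with planted
genotype-dependent ion interactions, so the whole pipeline is testable
end-to-end without any raw measurements.

## Worked example

```r
library(nutrifuzz)
report <- run_pipeline(pipeline_config(sim = sim_config(), seed = 42))
print(report)
```

```
Neurofuzzy nutrition analysis (seed 42 )

 output submodel              inputs   MSE Train Set R2 f ratio     df f critical  quality
     SL        1        genotype x I  0.17        86.87   94.53 7, 100       2.10 accepted
     SL        2                 SO4                                                  <NA>
     RL        1    genotype x H2PO4  0.47        75.99   53.29 6, 101       2.19 accepted
     PN        1            SO4 x Cu 18.63        90.17   80.04 11, 96       1.89 accepted
     ...
     RFW       2               H2PO4                                                  <NA>

Dominant rules: 45 of 54
```

Each output row is one trained model: its submodels (the significant inputs
and interactions the search retained), MSE in squared output units,
Train-Set R² (percent of variance explained), the f-ratio against its
F critical value at α = 0.05, the df pair implied by the coefficient count,
and the quality-gate verdict. For shoot length here, the model kept a
genotype × iodide interaction (iodide is exactly collinear with the whole
micronutrient dose in this design — see the vignette on confounding) plus a
sulfate ramp, with R² = 86.87% on 108 treatment means and df (7, 100), i.e.
8 coefficients.

The dominant rules for shoot length read:

```
 output submodel genotype    I  SO4 consequent membership
     SL        1       BD  Low <NA>        Low       0.74
     SL        1       BD High <NA>        Low       0.80
     SL        1       BH High <NA>        Low       0.72
     SL        1       BT  Low <NA>       High       0.93
     SL        1       BT High <NA>        Low       0.84
     SL        2     <NA> <NA>  Low        Low       0.82
```

Read row four as: IF genotype is BT AND the micronutrient level (here
labelled by iodide) is Low THEN shoot length is High, with membership 0.93
— the planted "BT grows best at low copper/micronutrient supply" structure,
recovered from noisy data. On synthetic runs the report also includes
`recovery`, comparing selected inputs against the planted truth (recall up
to the design's collinearity, false-input count, correlation of the fit
with the noise-free surface).

The same functions work stage by stage: `ion_profile()`,
`dilution_series()`, `build_factor_table()`, `factorial_anova()`,
`tukey_hsd()`, `asmod_search()`, `train_all_outputs()`, `extract_rules()`,
`dominant_rules()`, `generate_dataset()`, `recovery_report()`. Measured
data go in through `pipeline_config(data = your_table)` with `genotype`,
`subculture`, ion columns and response columns.

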