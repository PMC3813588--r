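# cogineq

Measuring and decomposing socioeconomic inequality in children's cognitive
function.

`cogineq` implements the full analysis pipeline used to study
household-expenditure-related inequality in children's cognitive test scores
across two survey rounds, in the style of the Indonesia Family Life Survey
(IFLS): age-specific standardization of a skewed 0–12 raw score, the relative
concentration index (RCI) with delta-method inference, a regression-based
(Wagstaff-type) decomposition of the index into contributor shares, an
Oaxaca-type decomposition of the change in inequality between rounds, a Gibbs
sampler for equal-tail credible intervals on contribution shares, and
chained-equations multiple imputation pooled by Rubin's rules. Because the
underlying microdata are not redistributable, the package ships a seeded
synthetic household-survey generator with the same statistical structure, so
every stage is testable end to end.

It is aimed at epidemiologists and health economists who work with
concentration indices on weighted survey data, and at anyone who needs a
transparent, fully scripted reference implementation of the
decomposition-of-change machinery.

## The statistics

**Relative concentration index.** With outcome `y_i` (here an age-specific
z-score of the raw cognitive score), normalized sampling weights `w_i`
(Σw = 1), and `R_i` the weighted fractional rank of child `i` in the
per-capita-expenditure distribution,

    RCI = (2 / μ) Σ_i w_i y_i (R_i − 1/2),      μ = Σ_i w_i y_i,

twice the weighted covariance between outcome and expenditure rank divided by
the mean outcome — equivalently, twice the area between the concentration
curve and the line of equality. Positive values mean the outcome is
concentrated among the better-off. Standard errors use the
Kakwani–Wagstaff–van Doorslaer delta-method estimator in its weighted form.

**Wagstaff decomposition.** From a weighted linear model
`y_i = α + Σ_k β_k x_ik + ε_i`, the index decomposes exactly as

    RCI = Σ_k η_k C_k + GC_ε / μ,      η_k = β_k x̄_k / μ,

where `C_k` is contributor `k`'s concentration index over the same ranks and
`GC_ε` is the generalized (unscaled) concentration index of the residual.
Each contributor's share is `η_k C_k / RCI`.

**Oaxaca-type change decomposition.** Between a base round `t−1` and a later
round `t`,

    ΔRCI = Σ_k [ η_kt (C_kt − C_k,t−1) + C_k,t−1 (η_kt − η_k,t−1) ] + Δ(GC_ε/μ),

splitting each contributor's effect into changing inequality in the
contributor and changing outcome-elasticity; both identities hold to machine
precision on every input.

**Hozo standardization.** Because raw item-count scores are left-skewed, the
per-(round, age) mean and SD used for z-scoring are recovered from each
cell's minimum, median, maximum and size with Hozo et al.'s formulas rather
than taken from sample moments.

## Worked example

Generate two synthetic rounds patterned on the 2000 and 2007 IFLS structure
and run the whole pipeline (z-scoring, complete-case RCI, multiple
imputation, decompositions, curve export):

```r
library(cogineq)

cfg00 <- survey_config("2000", n_children = 4000, seed = 1, missing_rate = 0.04)
cfg07 <- survey_config("2007", n_children = 4000, seed = 2, missing_rate = 0.045)
res <- run_pipeline(pipeline_config(
  rounds = list("2000" = cfg00, "2007" = cfg07),
  imputation = imputation_config(m = 20, cycles = 10, seed = 3),
  out_dir = "cogineq-demo"))

res$rci[["2000"]]
#> Relative concentration index: 0.3732 (SE 0.0406, 95% CI 0.2936 to 0.4527)
#>   n = 2716, mean outcome = 0.3895, method = delta
res$rci[["2007"]]
#> Relative concentration index: 0.3280 (SE 0.0467, 95% CI 0.2366 to 0.4195)
#>   n = 2536, mean outcome = 0.3535, method = delta
res$rci_mi[["2000"]]
#> Relative concentration index: 0.4085 (SE 0.0376, 95% CI 0.3348 to 0.4822)
#>   n = 4000, mean outcome = NA, method = rubin
```

Both synthetic rounds show pro-rich inequality (RCI > 0): children with
higher age-standardized scores are concentrated in better-off households.
The multiply-imputed estimate exceeds the complete-case one because the
missingness mechanism concentrates gaps among poorer households, so
complete-case analysis truncates the poor tail — the qualitative pattern
reported for the real survey.

```r
head(decomposition_report(res$decompositions[["2000"]]), 3)
#>   contributor                  beta elasticity concentration_index contribution_pct
#> 1 Log per capita expenditures  0.1        3.07                0.03               27
#> 2 Mother attended high school  0.37       0.27                0.34               25
#> 3 Use improved sanitation      0.19       0.24                0.25               16
```

Per-capita expenditure, maternal high-school attendance and improved
sanitation carry the largest contribution shares: each combines a sizable
outcome elasticity with strong concentration among richer households.
`change_report(res$change)` prints the analogous table for the between-round
change, and `autoplot()` methods draw the concentration curve and the
contribution bars.

The bundled published complete-case tables for the real 2000/2007 rounds are
available via `published_table()` for arithmetic cross-checks.

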