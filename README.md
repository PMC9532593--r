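# enzlim

Microbial communities in lake sediments secrete extracellular enzymes to
acquire the element that currently limits them. **enzlim** quantifies that
limitation from the five routinely assayed hydrolases — β-1,4-glucosidase
(BG) and cellobiohydrolase (CBH) for carbon, β-1,4-N-acetylglucosaminidase
(NAG) and leucine aminopeptidase (LAP) for nitrogen, alkaline phosphatase
(AP) for phosphorus — and links the resulting limitation indices to water
and sediment chemistry and to bacterial/fungal community turnover. It is
aimed at microbial ecologists running sediment or soil enzyme surveys of a
few dozen sites.

## The method

With per-site acquisition sums C = BG + CBH, N = NAG + LAP, P = AP, the
vector analysis of ecoenzymatic stoichiometry places each site at

```
x = C / (C + P),   y = C / (C + N)
```

and computes

* **vector length** `sqrt(x^2 + y^2)` — the C-limitation index,
* **vector angle** (degrees of `(x, y)` from the x-axis) — above 45°
  P-limited, below 45° N-limited,
* **N-limitation index** `90 − angle`.

All three are invariant to rescaling activities by a common factor. The
water column is classified separately against the Redfield ratio: molar
TN:TP > 16 reads as P limitation. Around the per-site indices the package
provides the survey's standard statistical layer: Bray–Curtis community
dissimilarity, element-cycle (z-scored Euclidean) and per-index difference
matrices, one-tailed Mantel permutation tests (exact n! enumeration at ≤ 7
sites), Pearson/OLS screens, quadratic fits with principled hump detection,
and AIC stepwise predictor selection. A seeded synthetic survey generator
with known directional effects (salinity and sediment TP → C limitation,
water TN → N limitation, hump-shaped pH responses, bacterial turnover
coupled to enzyme turnover) makes the whole pipeline testable end to end.

## Worked example

One site with C = 600, N = 150, P = 300 nmol g⁻¹ h⁻¹:

```r
library(enzlim)
vector_limitation(data.frame(c_acq = 600, n_acq = 150, p_acq = 300))
#>   site_id       x   y vector_length vector_angle_deg n_limitation limitation_class
#> 1     S01 0.66667 0.8        1.0414           50.194       39.806        P_LIMITED
```

The vector length 1.04 (of at most √2 ≈ 1.41) indicates substantial C
limitation; the angle above 45° says the community invests relatively more
in P than in N acquisition, so the site is classed P-limited.

A full synthetic survey and analysis:

```r
sv     <- generate_survey(survey_config(seed = 1))   # 23 sites by default
report <- run_analyze(sv, seed = 1)
report
#> Limitation analysis of 23 sites
#>   mean vector length (C limitation) 1.076; mean angle 47.32 deg; mean N-limitation 42.68
#>   class counts: N_LIMITED=6, P_LIMITED=17, BALANCED=0
#>   mean C fraction of total EEA: 0.614
#>   Mantel tests: 12 (min p = 0.001)

subset(report$mantel, pair == "bacteria_vs_element_cycle")
#>                        pair matrix_a      matrix_b     r p_value n_perm       seed
#> 1 bacteria_vs_element_cycle bacteria element_cycle 0.154   0.047    999 1140350788

report$stepwise
#>        response                                       selected criterion final_r2
#> 1 vector_length water_salinity,sed_tp,water_tn,water_tp,sed_ph     -59.2    0.866
#> 2  n_limitation        water_tn,water_salinity,water_ph,sed_tp      94.6    0.852
```

About 61% of total enzyme activity is directed at C acquisition; bacterial
community turnover correlates significantly with enzyme-allocation turnover
(Mantel r = 0.15, p = 0.047); and the stepwise screen recovers salinity and
sediment TP as the leading predictors of C limitation and water TN of N
limitation — the directional structure the generator encodes.
`run_analyze(sv, out_dir = "results/")` writes all tables
(`limitation.tsv`, `mantel.tsv`, `correlations.tsv`, `regressions.tsv`,
`stepwise.tsv`, `summary.json`, …) deterministically. A thin shell wrapper
is included: `exec/enzlim simulate … | analyze …`.

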