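# swotahp

Quantitative SWOT strategic analysis with the analytic hierarchy process
(AHP), for analysts and policy researchers who have expert-scored SWOT
factors and want a defensible, reproducible strategic recommendation
rather than a qualitative four-box diagram.

## What it computes

For each SWOT group (strengths, weaknesses, opportunities, threats) the
experts supply a positive reciprocal pairwise-comparison matrix `A` on
the Saaty 1–9 scale and a signed intensity `I_i` per factor (positive
for S/O, negative for W/T). The package then:

1. **Weights** — sum-product (column-normalise, row-average) priorities:
   `w_i = (1/n) Σ_j a_ij / Σ_k a_kj`.
2. **Consistency** — `λ_max = mean_i (Aw)_i / w_i`,
   `CI = (λ_max − n)/(n − 1)`, `CR = CI/RI` against the order-n random
   index; judgments pass when `CR < 0.1`.
3. **Strengths** — `s_i = I_i · w_i`, summed into the four signed totals
   `S′, W′, O′, T′`.
4. **Strategy** — quadrilateral vertices `(S′,0), (0,O′), (W′,0),
   (0,T′)`; centroid `P = ((S′+W′)/4, (O′+T′)/4)`; azimuth
   `θ = atan2(Y, X)` mapped onto eight strategy zones; intensity
   coefficient `ρ = O′S′ / (O′S′ + T′W′)` read as conservative /
   maintain / aggressive.

Delphi-style expert panels can be aggregated (arithmetic or geometric
mean on the upper triangle), and a seeded synthetic-panel generator
supports Monte-Carlo sensitivity analysis of `θ`, `ρ` and the zone
under controlled judgment noise.

## Worked example

The package ships a complete case study (new-media channels for
public-health promotion; 4/3/4/3 factors) under
`inst/extdata/media_health/`.

```r
library(swotahp)

# one group in isolation: weights + consistency test
m <- comparison_matrix(rbind(c(1, 1/7, 1/2),
                             c(7, 1,   4),
                             c(2, 1/4, 1)),
                       factor_ids = c("W1", "W2", "W3"), group_id = "W")
consistency(m)
#> AHP result for group 'W' (n = 3)
#>  factor weight     AW
#>      W1 0.0978 0.2935
#>      W2 0.7151 2.1483
#>      W3 0.1871 0.5615
#> lambda_max = 3.0020, CI = 0.0010, RI = 0.52, CR = 0.0019 -> consistent (CR < 0.1)

# the full pipeline on the bundled study
study <- run_pipeline(media_health_config())
study$strategy
#> SWOT strategy quadrilateral
#>   totals: S' = 4.8013, W' = -3.9581, O' = 4.6229, T' = -4.8217
#>   centroid P = (0.21079, -0.04968)
#>   azimuth theta = -13.261 deg (346.739 deg normalised), quadrant 4
#>   zone: resistant strategic area / aggressive type
#>   U = 22.1961, V = 19.0847, rho = 0.53769 -> maintain
```

Reading the result: every group passes the consistency test, so the
weights are usable. The centroid sits in the fourth quadrant — large
strengths coexisting with large threats (the "resistant / aggressive"
zone: lean on strengths to fend off threats) — and `ρ ≈ 0.538` falls in
the maintain band `[0.45, 0.55]`: keep the current development
intensity rather than expanding or retrenching.

`render_report(study, "out/")` writes a full-precision JSON report and a
4-decimal text report; add `"plot"` to `formats` for an SVG of the
quadrilateral. A thin command-line front end with `validate`, `run` and
`simulate` subcommands is installed at
`system.file("scripts", "swotahp-cli.R", package = "swotahp")`.

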