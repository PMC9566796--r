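---
title: "Quantitative SWOT-AHP analysis: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative SWOT-AHP analysis: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swotahp)
```

## The problem

A SWOT analysis sorts the factors bearing on a development strategy into
internal strengths (S) and weaknesses (W) and external opportunities (O)
and threats (T), but by itself it is purely qualitative: it cannot say
*how much* each factor matters. This package quantifies a SWOT study with
the analytic hierarchy process (AHP). A panel of domain experts scores,
for each group, the relative importance of every pair of factors on the
Saaty 1–9 ratio scale, and the expected signed intensity of each factor
(positive for S and O, negative for W and T, magnitude on the same 1–9
scale). From those scores the package derives priority weights, tests
whether the judgments are internally consistent, combines weights with
intensities into four signed group totals, and reads off a strategic
recommendation from the geometry of the resulting quadrilateral.

The bundled worked example (`media_health_config()`) is a health-policy
case study on new-media channels for public-health promotion, with 4, 3,
4 and 3 factors in the S, W, O and T groups.

## The model, stage by stage

### Pairwise judgments

A comparison matrix \(A = (a_{ij})\) for \(n\) factors is positive and
reciprocal: \(a_{ii} = 1\) and \(a_{ji} = 1/a_{ij}\). In strict mode every
entry must lie on the Saaty grid \(\{1,\dots,9\} \cup \{1/2,\dots,1/9\}\);
non-strict mode admits off-grid entries, which arise legitimately as
panel averages. `validate_matrix()` reports each broken rule with the
offending cells; inputs that give only the upper triangle are completed
by reciprocity, while fully specified matrices are checked and never
silently repaired.

### Weights: the sum-product method

Weights are derived by column normalisation followed by row averaging:

\[ w_i = \frac{1}{n} \sum_{j=1}^{n} \frac{a_{ij}}{\sum_{k} a_{kj}} . \]

This arithmetic-mean (sum-product) approximation of the principal
eigenvector is the package's *definition* of the weights, not a fallback:
the worked example's printed tables are reproducible only under this
estimator. The exact principal eigenvector differs from it in the third
decimal place for mildly inconsistent matrices; the test suite uses an
independent eigen-decomposition as a sanity oracle (agreement within 0.05
per component when CR < 0.1) but the package never computes weights that
way.

### Consistency test

With \(AW = A w\) (the *original* matrix times the weights — see the
design notes below), the maximum-eigenvalue estimate, consistency index
and consistency ratio are

\[ \lambda_{\max} = \frac{1}{n}\sum_i \frac{(Aw)_i}{w_i}, \qquad
   CI = \frac{\lambda_{\max} - n}{n - 1}, \qquad CR = CI / RI, \]

where \(RI\) is the average random-consistency index for order \(n\).
A matrix passes when \(CR < 0.1\); exactly 0.1 fails. For \(n \le 2\),
\(RI = 0\) and any reciprocal matrix is perfectly consistent, so \(CR\)
is defined as 0. \(\lambda_{\max} \ge n\) always, with equality exactly
for consistent matrices — both facts are asserted property-style in the
tests.

The default \(RI\) table is

```{r}
random_index_table()
```

Its entries at \(n = 3, 4\) (0.52, 0.89) differ from Saaty's classic
values (0.58, 0.90). The table is kept as the source study used it and
can be overridden per call (`consistency(m, ri_table = ...)`); the
override changes only CR, never the weights.

### Strengths and the strategy quadrilateral

Each factor's strength is its signed intensity times its weight,
\(s_i = I_i\,w_i\), and the group totals \(S', W', O', T'\) are the group
sums. Because weights are a convex combination, \(|{\rm total}| \le
\max_i |I_i|\). The totals are placed as the vertices \((S',0)\),
\((0,O')\), \((W',0)\), \((0,T')\) of a convex quadrilateral around the
origin, and the strategy is read from the centroid

\[ P = (X, Y) = \left( \frac{S' + W'}{4}, \frac{O' + T'}{4} \right): \]

* the **azimuth** \(\theta = \operatorname{atan2}(Y, X)\) locates the
  strategy among eight half-quadrant zones (pioneering, ambitious,
  conservative and resistant areas, each split into two types);
* the **strategic intensity coefficient**
  \(\rho = U / (U + V)\) with \(U = O'S'\) and \(V = T'W'\) grades how
  aggressively to pursue it: below 0.45 conservative, within
  \([0.45, 0.55]\) maintain the current pace, above 0.55 aggressive
  (band configurable).

A one-argument \(\arctan(Y/X)\) cannot distinguish opposite quadrants, so
the implementation uses the two-argument form and reports the angle both
signed in \((-180°, 180°]\) and normalised to \([0°, 360°)\), the range
on which the zone partition is defined. Zone intervals are half-open
\([a, b)\), except that the opportunity-type zone is closed at \(\pi/2\)
as the partition is published; \(2\pi\) wraps to 0, making
`classify_zone()` a total function on \([0, 2\pi)\) (verified by a dense
grid sweep).

### Expert aggregation

Panels are pooled cell-wise on the *upper triangle only*, then mirrored:
the cell-wise mean of full reciprocal matrices is generally not
reciprocal, so aggregating the full matrix would manufacture invalid
inputs. The default pooling is the arithmetic mean, matching the
final-round Delphi convention the bundled study used; the geometric
mean — the classical recommendation for ratio-scale judgments — is
available as an option. Aggregated cells are deliberately *not* snapped
back to the Saaty grid. Intensities are pooled by arithmetic mean with
the sign convention enforced; experts disagreeing on a factor's sign is
treated as a scoring error, not a tie to average away.

## The synthetic panel generator

`panel_spec()` fixes a latent truth per group — a positive weight vector
and signed intensities — and simulated experts perceive it through
multiplicative log-normal noise: each latent ratio \(w_i/w_j\) is
multiplied by \(e^\varepsilon\), \(\varepsilon \sim N(0, \sigma^2)\).
Log-normal noise is the natural choice for ratio-scale judgments: it is
symmetric on the log scale, keeps entries positive and makes
\(\sigma = 0\) the exactly consistent limit. Optional snapping maps each
noisy judgment to the nearest grid value in log space, with midpoint ties
resolved toward 1 (the less extreme judgment). Intensity noise is an
integer jitter of at most ±1 per expert, clamped to magnitude 1–9 and
sign-preserving.

What the generator emulates: panel-to-panel judgment scatter around a
shared latent opinion, and its effect on CR failure rates and on the
stability of \(\theta\), \(\rho\) and the zone. What it does not
emulate: systematic expert bias, correlated judgments within an expert,
Delphi convergence across rounds, or disagreement about the latent
ordering itself. Passing simulation tests therefore demonstrates the
pipeline's correctness and noise response, not that any real panel is
well described by independent log-normal errors.

`simulate_strategy_distribution()` runs the full pipeline per replicate
and rejects (and counts) replicates in which any group fails CR,
mirroring how an inconsistent real panel would be sent back for another
round. Replicates are seeded as `seed + r`, so results are reproducible
and individual replicates can be re-run in isolation. The test suite
uses 100–200 replicates per property, sizes at which every Monte-Carlo
check runs in seconds on one CPU; the monotone decrease of the CR pass
rate in \(\sigma\) and the growth of azimuth dispersion with \(\sigma\)
are asserted at those sizes.

## Numerical choices and edge cases

* All computation is in double precision; rounding (half-even, 4
  decimals) happens only in printed reports. JSON output carries full
  precision, and `U`, `V`, `rho` are always recomputed from
  full-precision totals, never from rounded intermediates.
* Reciprocity and diagonal checks use relative tolerance `1e-9`; weight
  normalisation is exact to the same tolerance by construction.
* Matrix CSV cells accept fraction strings (`"1/7"`), parsed as numerator
  over denominator — one correctly rounded division, no string `eval`.
* Degenerate inputs: all-zero totals and an origin centroid are errors
  (`swotahp_degenerate`) because the azimuth is undefined there; a
  single-factor group is accepted as trivially consistent with weight 1;
  matrices of order above 9 are rejected because the RI table ends there.
* Exactly mirror-symmetric latents (\(S' = -W'\), \(O' = -T'\)) are the
  one configuration where \(\rho = 1/2\) is *not* observable through the
  pipeline, since the centroid degenerates first; balanced products
  (\(O'S' = T'W'\)) with an off-origin centroid do yield \(\rho = 1/2\).

## Design decisions

* **AW uses the original matrix.** The source study's tabulated layout
  suggests multiplying the column-normalised matrix by the weights, but
  its printed `AW` values are reproduced only by `A %*% w` on the raw
  judgments; that is also what makes \(\lambda_{\max} = n\) exact for
  consistent matrices. The package follows the numbers, not the layout.
* **Signed intensities are stored signed** (W/T negative) rather than as
  magnitudes with signs applied later — the stored values then equal the
  published inputs line for line.
* **Group sizes are free** (2–9 factors each); the four groups need not
  be equally sized and are treated symmetrically — there is no
  inter-group weighting layer.
* **CR threshold behaviour** and the boundary policy of the zone
  partition are exposed as arguments but default to the published
  conventions (strict `< 0.1`; half-open intervals with the one closed
  bound at \(\pi/2\)).

## Known limitations

* The sum-product weights are an approximation; studies requiring exact
  eigenvector weights (or fuzzy/interval AHP, ANP, missing-entry
  completion) are out of scope.
* Aggregation assumes complete panels: every expert scores every pair
  and factor. Partial response handling and consensus diagnostics
  (e.g. Kendall's W) are not implemented.
* The zone vocabulary is a fixed eight-label partition; it does not
  attempt to interpolate guidance near zone boundaries, where small
  perturbations of the totals can flip the label while \(\theta\) and
  \(\rho\) move continuously — the simulation module exists precisely to
  quantify that sensitivity.
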