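# mcda4hta

Multi-criteria decision analysis for Health Technology Assessment (HTA).

HTA panels must weigh a technology's clinical, economic, ethical,
organizational, social and legal implications at once. `mcda4hta` implements
an integrated decision model for that setting: the nine domains of the HTA
Core Model become the main criteria of a four-level hierarchy; a
multi-disciplinary panel's pairwise judgments are turned into criterion
weights by the Analytic Hierarchy Process (AHP); the evidence table extracted
from the HTA report — numeric values, yes/no findings and 7-level linguistic
appraisals — is encoded as triangular fuzzy numbers; and three independent
ranking engines (fuzzy TOPSIS, fuzzy VIKOR, goal programming) score the
technology alternatives. All three engines report **lower-is-better**
indices, so rank 1 always has the minimal index.

## The model in brief

* **Weights (AHP).** For each parent criterion with two or more children the
  panel fills a reciprocal Saaty-scale matrix `A` (`a_ij ∈ {1..9}` and
  reciprocals, `a_ij · a_ji = 1`). Respondents are pooled by element-wise
  geometric mean; local weights are the normalized principal right
  eigenvector of the pooled matrix (power iteration, tolerance 1e-12);
  coherence is monitored by the consistency ratio
  `CR = ((λ_max − n)/(n − 1)) / RI(n)` with Saaty's random-index table, and
  `CR > 0.1` is flagged. Global leaf weights are products of local weights
  along each root-to-leaf path and sum to 1.
* **Scores (fuzzy encoding).** Numeric evidence `x` becomes the degenerate
  triangular fuzzy number (TFN) `(x, x, x)`; yes/no becomes `(1,1,1)` /
  `(0,0,0)`; a 7-level linguistic term takes its TFN from the scale (the
  built-in `default7` scale puts term *k* at `((k−2)/6, (k−1)/6, k/6)`
  clipped to `[0,1]`). Benefit columns are normalized by the column's maximal
  upper support; cost columns use the reciprocal form `(a⁻/u, a⁻/m, a⁻/l)`.
* **Rankings.** Fuzzy TOPSIS measures vertex distances of the weighted
  normalized TFNs from the fuzzy positive ideal `(w_j, w_j, w_j)` and
  negative ideal `(0,0,0)` and reports `d⁺/(d⁺+d⁻)`. Fuzzy VIKOR blends
  group utility `S` and individual regret `R` into
  `Q = v(S−S*)/(S⁻−S*) + (1−v)(R−R*)/(R⁻−R*)` (default `v = 0.5`). Goal
  programming scores each alternative by its weighted normalized absolute
  deviation from the per-criterion goals, solved in closed form.

## Worked example

The packaged dialysis case compares peritoneal dialysis (PD) with
hemodialysis (HD) under the full nine-domain criteria tree. Its structure is
the published one — level counts 9/45/115/113, 85 pairwise matrices in 10
questionnaires, a 12-person panel — while the panel weights and evidence
scores are deterministic synthetic stand-ins (see
`?synthetic_dialysis_case`).

```r
library(mcda4hta)
case <- synthetic_dialysis_case()
case$hierarchy
#> <criteria_hierarchy: 'Select the preferred dialysis modality'>
#>   282 nodes (L1: 9, L2: 45, L3: 115, L4: 113), 198 leaves
case$plan
#> <elicitation_plan: 85 pairwise matrices in 10 questionnaires>

report <- run_pipeline(run_config(
  hierarchy = case$hierarchy,
  table     = case$performance,
  weights   = case$weights
))
report
#> <decision_report: 3 method(s), 2 alternative(s)>
#>   fuzzy_topsis     best: PD   indices: PD=0.193, HD=0.341
#>   fuzzy_vikor      best: PD   indices: PD=0.500, HD=0.500
#>   goal_programming best: PD   indices: PD=0.320, HD=0.535
```

Lower is better throughout, so PD wins under TOPSIS and goal programming;
under VIKOR the two alternatives split group utility and regret (PD best on
one, HD on the other), both land at `Q = 0.5`, and the tie is broken by
document order. `write_report(report, "out/")` writes one CSV per method and
a self-contained markdown summary (configuration echo, consistency table,
dropped-column log).

A synthetic study with known ground truth for every stage comes from the
generator:

```r
study <- gen_study(synthetic_spec(seed = 1, shape = c(4, 3),
                                  planted_dominance = TRUE))
run_pipeline(run_config(hierarchy = study$hierarchy,
                        responses = study$judgments,
                        table = study$performance))
```

A thin command line covering `plan`, `weights`, `rank`, `synth` and `report`
is in `inst/cli/mcda4hta.R`.

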