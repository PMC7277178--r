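---
title: "An integrated multi-criteria decision model for health technology assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated multi-criteria decision model for health technology assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcda4hta)
```

## The decision problem

Health technology assessment asks whether a technology (a device, drug or
intervention) should be adopted, given evidence spread over very different
dimensions: the health problem and current use of the technology, its
technical characteristics, safety, clinical effectiveness, costs, and
ethical, organizational, social and legal implications. Deliberative panels
struggle to hold all nine dimensions in view at once and to keep their value
judgments transparent. `mcda4hta` structures that deliberation as a
multi-criteria decision analysis: the nine HTA Core Model domains are the
main criteria of a hierarchy up to four levels deep, a multi-disciplinary
panel supplies the *weights*, the HTA report supplies the *scores*, and
three ranking engines turn both into an ordering of the technology
alternatives. Using three engines with different logics (distance to ideal,
compromise between group utility and individual regret, deviation from
goals) is deliberate: agreement across them is evidence the conclusion is
not an artifact of one aggregation rule.

## The criteria hierarchy and the elicitation plan

A hierarchy is a tree: a goal, level-1 main criteria, and up to three levels
of sub-criteria. Leaves carry two attributes the internal nodes do not: a
`direction` (`benefit`: more is better; `cost`: less is better) and a
`data_kind` (`numeric`, `binary`, `linguistic`) that fixes how evidence
cells are parsed. Hierarchies load from human-editable JSON/YAML documents
in which `level` is implied by nesting; validation rejects duplicate ids,
orphans, depth beyond 4 and leaves missing their attributes, each with a
distinct error class naming the offending node.

Weight elicitation needs one reciprocal pairwise-comparison matrix per
parent with at least two children; a single child inherits local weight 1
and needs no matrix (the only choice consistent with AHP semantics — a 1×1
comparison is vacuous). Matrices are grouped into questionnaires: one
instrument for the nine main criteria plus one instrument per main
criterion's subtree, always `1 + n_main` instruments even when a domain
contributes no internal matrices, so the instrument count is structural
rather than data-dependent. Document order is the single node ordering used
everywhere — matrix indexing, leaf order, report rows — which makes every
run reproducible from the input files alone.

## AHP weighting

Each panel member expresses relative importance on Saaty's 1–9 ratio scale.
The group's matrices for one comparison are pooled by element-wise geometric
mean (*aggregation of individual judgments*), the standard group-AHP rule
that preserves reciprocity algebraically; an *aggregation of individual
priorities* alternative (arithmetic mean of per-respondent eigenvectors) is
available via `compute_weights(aggregation = "priorities")` since panels
differ in which they regard as fair. Local weights are the normalized
principal right eigenvector, computed by power iteration with tolerance
1e-12 and a 10,000-iteration cap (positive reciprocal matrices have a simple
dominant eigenvalue, so convergence is fast; the cap only guards degenerate
input). The geometric-mean row method is available as
`principal_weights(method = "geometric")`; the two coincide exactly on
consistent matrices.

Consistency is monitored by `CR = CI / RI(n)` with `CI = (λ_max − n)/(n−1)`
and Saaty's random indices for orders up to 10 (larger sibling groups are
rejected with advice to restructure — a 10+-way pairwise comparison is not
reliably answerable anyway). `CR > 0.1` warns and is recorded in the report
but does not abort by default: an assessment record with a flagged
inconsistency is more useful than a refusal, and a revision loop with the
panel is outside the software's control. `strict_cr = TRUE` makes it fatal
for workflows that do enforce revision. Respondents missing a matrix reduce
the pool for that matrix with a logged count rather than failing the run:
with a panel committed to full participation an absence is an anomaly worth
surfacing, not a structural error.

Global leaf weights are products of local weights along each root-to-leaf
path; they sum to 1 by construction, which the tests verify against a
brute-force path-product oracle.

## Fuzzy encoding of mixed evidence

HTA reports mix hard numbers, yes/no findings and graded qualitative
appraisals. All three become triangular fuzzy numbers (TFNs) `(l, m, u)`,
`l ≤ m ≤ u`:

* numeric `x` → `(x, x, x)` (degenerate: no added uncertainty);
* `yes` → `(1, 1, 1)`, `no` → `(0, 0, 0)`;
* a 7-level linguistic term → its TFN on the scale in use.

The built-in `default7` scale places term *k* (k = 1..7) at
`((k−2)/6 clipped at 0, (k−1)/6, k/6 clipped at 1)` — seven equally spaced,
half-overlapping triangles covering `[0, 1]`, the common textbook
construction for 7-level scales. Alternative scales load from a small CSV
(`term, l, m, u`) so a panel's own anchors can be used; the packaged
dialysis case uses `default7` because the original study's scale anchors are
not redistributable.

Defuzzification (needed by VIKOR's crisp route and goal programming) is the
graded mean `(l + 4m + u)/6` by default — it weights the modal value the
way the fuzzy VIKOR literature usually does — with the centroid
`(l + m + u)/3` as the config alternative. Both return `m` for symmetric
TFNs and `x` for degenerate ones, so crisp data pass through unchanged.

Normalization is linear max/min: a benefit column divides by the column's
largest upper support; a cost column maps `(l, m, u)` to
`(a⁻/u, a⁻/m, a⁻/l)` with `a⁻` the smallest lower support. The reciprocal
form keeps `l ≤ m ≤ u` valid without sign flips (which is also why negative
scalar multiplication of TFNs is simply excluded). It requires strictly
positive cost supports; zero or negative values are rejected with guidance
to pre-shift, because a reciprocal through zero has no meaningful scale. A
column with a missing cell for *any* alternative is dropped entirely with
weight renormalization and a prominent log entry: a comparison scored for
only one technology cannot inform a choice between technologies, and silent
imputation would manufacture evidence.

## The three ranking engines

All three report lower-is-better indices so they share one orientation and
one reading: rank 1 minimizes the index.

**Fuzzy TOPSIS.** On the weighted normalized matrix `v_ij = w_j · r_ij` the
fuzzy positive ideal is `(w_j, w_j, w_j)` per column and the negative ideal
`(0, 0, 0)`. Distances are vertex distances
`d(A,B) = sqrt(((a_l−b_l)² + (a_m−b_m)² + (a_u−b_u)²)/3)` summed over
columns, and the index is `d⁺/(d⁺ + d⁻)` — the complement of the classical
closeness coefficient, chosen so TOPSIS agrees with the other engines'
orientation. An alternative with `d⁺ + d⁻ = 0` (a fully degenerate matrix)
gets 0.5 by convention, logged.

**Fuzzy VIKOR.** The default route defuzzifies each cell and runs crisp
VIKOR: per column the direction-aware best `f*_j` and worst `f⁻_j`, per
alternative `S_i = Σ_j w_j (f*_j − x_ij)/(f*_j − f⁻_j)` and `R_i` its
largest summand, then
`Q_i = v (S_i − S*)/(S⁻ − S*) + (1−v)(R_i − R*)/(R⁻ − R*)` with `v = 0.5`
("consensus") by default. A column with `f* = f⁻` contributes zero, and a
degenerate `S` or `R` spread zeroes that Q term, so identical alternatives
all get `Q = 0`. A fuzzy-arithmetic route (`vikor_fuzzy_arith = TRUE`)
keeps `S` and `R` as TFNs via component-wise ideals and fuzzy subtraction
and defuzzifies only before the Q blend; both routes ship because published
fuzzy-VIKOR implementations differ on exactly this point, and on crisp
inputs they coincide (tested). The classical acceptable-advantage and
acceptable-stability conditions are computed and reported as booleans but
never alter the indices.

**Goal programming.** Goals are the per-column direction-aware best
defuzzified values on the normalized scale; the index is
`Σ_j w_j |g_j − x_ij| / (g_j − b_j)` with `b_j` the worst value (a column
with `g = b` contributes zero). Because the deviation variables of the
underlying program `x + d⁻ − d⁺ = g`, `d± ≥ 0` decouple across criteria and
alternatives, this closed form *is* the LP optimum; the test suite verifies
that equality to 1e-9 against an independent simplex solve on 100 random
instances rather than trusting the argument. Normalized (not raw) scores
are the default so deviations are commensurable across criteria with
different units.

Ties in any ranking are broken by alternative document order, and reports
print indices to 3 decimals while the CSVs keep full precision.

## The synthetic-study generator

The generator exists so every stage is testable against known ground truth.
It emulates the study conditions of a real elicitation campaign: a
**12-person** multi-disciplinary panel (the default), Saaty-scale
questionnaires for every planned matrix, and an evidence table mixing
numeric, yes/no and linguistic columns (default mix 0.4/0.2/0.4). Judgment
noise is multiplicative log-normal on consistent ratios —
`a_ij = (w_i/w_j) e^ε`, `ε ~ N(0, σ²)` judged once per pair and mirrored,
so matrices stay valid by construction — with σ = 0.1 as the default
"realistic panel" level: it produces the mid-single-digit percent weight
errors one sees in practice while keeping most matrices within CR ≤ 0.1.
Generated ratios are snapped to the nearest Saaty value by default to mimic
questionnaire output; at σ = 0 the exact consistent ratios are emitted
unsnapped, so the noiseless limit recovers planted weights to numerical
precision (snapping a consistent matrix would destroy the very consistency
the noiseless case is meant to exhibit). Everything is deterministic in the
seed, which is recorded in the generated files.

What the generator does **not** emulate: systematic respondent bias,
correlation between evidence columns, disagreement structured by profession,
or missingness patterns. Passing tests therefore demonstrate algorithmic
correctness and statistical recovery under idealized noise, not robustness
to the failure modes of real panels.

## The packaged dialysis case

`synthetic_dialysis_case()` ships a complete PD-vs-HD decision problem at
the published scale of the original dialysis assessment: nine HTA Core
Model domains with the published per-domain criteria distribution (level
counts 9/45/115/113), an elicitation plan of exactly 85 pairwise matrices
in 10 questionnaires, and a 12-person simulated panel. The intra-domain
parent/child wiring, the panel's judgments and every evidence score are
deterministic **synthetic stand-ins**, because the original appendix tables
are not redistributable; the function names and documentation say so
explicitly. Consequently the case exercises the full pipeline at realistic
scale and pins the structural counts, but its indices are not expected to
match the originally reported reference values; `compare_reference()`
documents the difference value by value, and the property-based suite — not
the reference comparison — is what validates the engines.

## Numerical choices and degenerate inputs

* Power iteration: tolerance 1e-12 on the iterate, cap 10,000.
* Reciprocity and weight-sum checks: tolerance 1e-9.
* Zero spans (identical alternatives in a column) contribute zero to S, R
  and GP deviations; fully identical alternatives give equal indices by
  symmetry (tested).
* TOPSIS degenerate `d⁺ + d⁻ = 0` → 0.5, logged; VIKOR all-identical → all
  `Q = 0`, logged.
* Cost columns with non-positive supports and benefit columns with
  non-positive maxima are rejected by name with pre-shift guidance.
* Ties: document order, both in ranks and in VIKOR's advantage check.

## Validation problem sizes

The test suite validates at deliberately small scale so the full run stays
fast: consistent-matrix recovery on 100 random matrices of order 3–8;
dominance consistency on 500 two-alternative problems with 2–6 criteria;
GP-vs-LP and TOPSIS-vs-brute-force equivalence on 100 random instances
each; VIKOR limit identities on 100 instances; weight recovery on
6–9-criterion panels of 12 respondents averaged over 5 replicates per noise
level. The packaged dialysis case (282 criteria, 85 matrices) is the
full-scale end-to-end exercise; a complete pipeline run on it takes well
under a second.

## Known limitations

* Fuzzy AHP, interval judgments and incomplete-matrix completion are out of
  scope; every planned matrix must be fully answered by at least one
  respondent.
* Only triangular fuzzy numbers are supported (no trapezoidal or type-2
  memberships, no alpha-cut arithmetic).
* Crisp TOPSIS/VIKOR are available only implicitly, as the fuzzy engines on
  degenerate TFNs.
* The missing-cell policy (drop the column) is the only one offered;
  imputation of evidence is deliberately not provided.
* Sensitivity analysis is limited to re-running with perturbed
  configuration; no automated weight-sensitivity scan is included.
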