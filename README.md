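# rsifreg

Globally optimal 7-DoF similarity registration of 3D point sets by
transformation decomposition.

## The problem

Given a *moving* point set `X = {x_i}` and a *reference* set `Y = {y_j}`
related by an unknown similarity transformation

```
y_j = s · R · (x_i + t),    s > 0,  R ∈ SO(3),  t ∈ R³,
```

estimate `(s, R, t)` with **no initialization and no known
correspondences**, in the presence of gross outliers in the reference set
and missing points in the moving set. This is the setting of surface-based
registration in image-guided interventions (e.g. aligning a skin surface
from MRI with a laser range scan), where local methods (ICP variants, CPD)
converge to the nearest local optimum and fail without a good starting
pose, while a joint global branch-and-bound over all 7 degrees of freedom
is computationally hopeless.

`rsifreg` decomposes the problem into three globally solvable stages:

1. **Translation** — point triples are summarized by
   *rotation-and-scale-invariant features* (RSIFs): the triple of pairwise
   angular distances `p = (∠(x₁,x₂), ∠(x₁,x₃), ∠(x₂,x₃))` of the position
   vectors, which is unchanged by any rotation/scaling about the origin.
   Corresponding reference features satisfy `q = F(p, t)` — a function of
   the unknown translation alone. The count of features matched within a
   threshold (the consensus) is maximized over a cubic domain in `R³` by
   best-first branch and bound, with guaranteed interval bounds
   (uncertainty angle bound `β(x,T) = arcsin(δ/‖x+t₀‖)` plus a natural
   interval extension of the feature distance).
2. **Rotation** — after applying `t*`, the consensus of point *directions*
   (`∠(R(x+t*), y) ≤ ε_r`) is maximized over the axis-angle ball of radius
   π by a second branch and bound; the objective never sees the norms, so
   the unknown scale is irrelevant. The final rotation is read off the
   consensus correspondences by a closed-form orthogonal-Procrustes fit
   (the counting objective is flat within `ε_r` of the truth; see the
   methods vignette).
3. **Scale** — the median of the norm ratios `‖y‖ / ‖x + t*‖` over the
   consensus correspondences.

Candidate feature pairs are screened beforehand with the
translation-invariant difference-angle triple `g′`, so both branch-and-
bound searches run on a few hundred features/points and typically finish
in about a second per 200-point registration.

The package also ships the synthetic benchmark protocol (uniform points in
`[-1,1]³`, random transforms with `s ∈ [1,5]`, outlier and missing-point
sweeps, 20 seeded trials per cell, success = rotation error < 0.1 rad ∧
relative translation error < 0.1 ∧ absolute scale error < 0.1), target
registration error (TRE) evaluation, PLY/XYZ/CSV I/O, and a small CLI
(`exec/rsifreg`) with `register`, `simulate`, `sweep` and `evaluate`
commands.

## Worked example

Register a 200-point set against a reference contaminated with 100%
outliers (outlier-to-inlier ratio 1.0):

```r
library(rsifreg)

trial <- gen_trial(scenario_config(n_points = 200, outlier_ratio = 1.0,
                                   seed = 42), 1)
res <- register_point_sets(trial$moving, trial$reference,
                           registration_config(seed = trial$seed),
                           ground_truth = trial$ground_truth)
print(res)
#> <registration_result>
#>   consensus: translation 25/42 features, rotation 200 points, 200 scale pairs
#>   s = 3.4872, |angle| = 1.0313 rad, t_pre = (-0.4482, 0.1073, 0.1199)
#>   vs truth: rot 0.0019 rad, trans rel 0.0131, scale abs 0.0059 -> SUCCESS
```

Reading: 42 moving features survived screening against the
outlier-diluted reference ranking, 25 of them reached consensus at the
optimal translation; all 200 moving directions found a rotation-stage
match; and the recovered transform (`s = 3.487`, rotation off by
0.002 rad, translation off by 1.3% relative) meets all three success
thresholds. The true transform had `s = 3.481`,
`t_pre = (-0.454, 0.107, 0.117)`.

Registering two files from the shell:

```sh
Rscript exec/rsifreg register --moving moving.ply --reference scan.csv \
        --out result.json --seed 3
```

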