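---
title: "Differential network testing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential network testing: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The statistical problem

Given two groups of multivariate samples -- say `S` samples of `N`
physiological parameters for each of two patient groups -- we ask whether
the *association networks* of the two groups differ.  Each group's network
is summarized by a symmetric weighted adjacency matrix `A = (a_ij)` with
zero diagonal, where `a_ij` is the estimated association between variables
`i` and `j` and `a_ij = 0` encodes "no edge".  The null hypothesis is
network invariance with respect to a chosen *network difference
characteristic* `X(A, B)`; the alternative is that the groups differ in
that characteristic.

## Network estimation

Three estimators are provided by `estimate_network()`:

* **Spearman** (`method = "spearman"`, the default and the headline
  estimator): pairwise Spearman rank correlations in `[-1, 1]` with
  average ranks under ties.  P-values use the large-sample t
  approximation `t = r sqrt((S-2)/(1-r^2))` on `S - 2` degrees of freedom;
  at the study scale of `S = 123` samples this approximation is accurate,
  and an exact permutation test would be interchangeable.
* **Distance correlation** (`method = "dcor"`): values in `[0, 1]`, zero
  in the population iff the two variables are independent, sensitive to
  nonlinear dependence.  No installed distribution for its null exists, so
  p-values come from a seeded permutation independence test
  (`dcor_n_perm` replicates, default 1000) with the add-one convention
  `(1 + #{perm >= obs})/(1 + n_perm)`, which keeps p-values strictly
  positive.
* **EBIC graphical lasso** (`method = "ebicglasso"`): penalized Gaussian
  graphical models are fitted along a log-spaced path of `n_lambda = 100`
  penalties from the smallest penalty yielding an empty graph down to
  `lambda_min_ratio = 0.01` of it; the model minimizing
  `EBIC = -2 loglik + E log(S) + 4 E gamma log(N)` is selected
  (`E` = number of edges).  The input is the Spearman correlation matrix,
  so the partial-correlation weights are adjusted versions of the same
  rank correlations used elsewhere in the package.  `gamma = 0.5`
  (default) prefers sparse models; the selected edge count is provably
  non-increasing in `gamma` for a fixed path, which the test suite
  asserts.  The penalized fits use block coordinate descent
  (column-by-column lasso updates on the covariance estimate).

For the two pairwise estimators, an edge is drawn only when the
(adjusted) p-value is at most `alpha = 0.05`.  Adjustment (`"bh"`,
`"bonferroni"`, or `"none"`) is applied once per network over the
`N(N-1)/2` unique pairs -- each network is treated as one family of
tests.  Bonferroni dominates Benjamini-Hochberg, so Bonferroni edge sets
are always nested inside BH edge sets; this containment is asserted on
random data in the tests.

Degenerate inputs are rejected rather than patched: missing values are an
error (imputation is a study-design concern upstream of estimation), and
constant columns are an error because silently assigning them zero edges
would bias the difference characteristics.  Non-PSD correlation inputs to
the graphical lasso are repaired by eigenvalue clipping with a warning.

## The ten difference characteristics

For two networks on the same nodes the package computes

* global strength difference `G = |sum_ij (|a_ij| - |b_ij|)|`,
* Frobenius metric `F = sqrt(sum_ij |a_ij - b_ij|^2)`,
* maximum metric `M = max_ij |a_ij - b_ij|`,
* spectral distance `S` = Euclidean distance between descending-sorted
  eigenvalue vectors,
* Jaccard distance `J` on the edge sets,
* differences in the number of edges `E`, of Girvan-Newman communities
  `C`, and of isolated nodes `I`,
* per-node degree differences `D_i` (unweighted edge counts), and
* per-pair edge strength differences `E_ij = |a_ij - b_ij|`.

Sums run over the full matrix exactly as the formulas are written, so
each unordered pair is counted twice.  Permutation p-values are invariant
to this factor of two, but the reported statistic values follow the
printed formulas.

Conventions worth recording:

* *Edge presence* means weight strictly nonzero -- the estimators emit
  exact zeros for pruned edges, so no epsilon tolerance is needed.
* *Jaccard of two empty networks*: the ratio is 0/0; since the networks
  are identical the distance is defined as 0.
* *Community counts* are computed on the binarized topology by divisive
  edge-betweenness (Girvan-Newman) clustering, cutting the hierarchy at
  the maximum-modularity partition, with isolated nodes counted as
  singleton communities (the empty graph on `N` nodes has `N`
  communities).  The topology-only choice keeps `C` consistent with the
  other set-based characteristics (`J`, `E`, `I`); where several cuts of
  the hierarchy tie in modularity the implementation's choice is
  arbitrary, which the oracle tests account for.
* *Degree* is the unweighted number of incident edges, not strength.

## The permutation test

`permutation_test()` and `compare_networks()` implement the four-step
procedure: estimate both networks and the observed statistic `x0`;
randomly permute the group assignment; re-estimate *both* networks and
recompute the statistic; repeat `M` times; report
`P = (1/M) * #{x_m >= x0}`.  The printed estimator is used verbatim --
the common `(1 + #)/(1 + M)` variant is deliberately not used -- so ties
count toward the p-value and `P = 0` is possible in principle.  The
default is `M = 10000` replicates; the calibration and power studies in
the test suite scale `M` down (500 and 1000) to keep hundreds of
replications tractable, which leaves the test's level unaffected.

Two permutation schemes cover the two study designs:

* **unpaired** (cross-sectional comparisons): labels are shuffled
  preserving both group sizes;
* **paired** (longitudinal comparisons, both conditions measured on the
  same subjects): each pair's two condition assignments are swapped
  independently with probability 1/2.

`compare_networks()` evaluates all requested characteristics over one
*shared* permutation stream: each permuted assignment triggers one
re-estimation from which every statistic is computed.  This is both
cheaper and internally consistent across characteristics; a
per-characteristic stream would differ only stochastically, and the suite
asserts that a subset run with the same seed reproduces the corresponding
rows of a full run.  The stream is generated up front from the seed, so
it does not depend on which characteristics are requested.

`exhaustive_test()` enumerates all `C(S_A + S_B, S_A)` assignments
(unpaired) or `2^pairs` swap patterns (paired), capped at 10^4, and is
the oracle against which the sampling path is checked exactly at full
enumeration.

No multiplicity correction is applied across characteristics or across
node/edge rows: significance is flagged at raw `p <= 0.05`, matching the
reporting convention of the application; the flag column is informational.

## Synthetic data generators

All tests run on seeded synthetic data, generated to have exactly the
structure the framework assumes:

* `simulate_correlated()` draws a latent Gaussian copula whose normal
  correlation is `2 sin(pi rho_S / 6)`, so the *Spearman* correlation of
  the output matches the target -- estimator tests compare like with
  like.  Monotone marginal transforms (log-normal, shifted gamma) mimic
  skewed laboratory values without touching Spearman structure.
* `simulate_paired_stages()` couples the two stages of one subject with a
  cross-stage correlation, using a joint latent covariance
  `[[A, rho A^{1/2}B^{1/2}], [rho B^{1/2}A^{1/2}, B]]` that is PSD by
  construction.
* `simulate_null()` / `simulate_planted()` drive the calibration and
  power studies: both groups share one structure, or the listed pairwise
  correlations differ by `delta` in group B (PSD-repaired if needed).
* `simulate_icu_cohort()` emits encounter-level data in the shape the
  study pipeline consumes.

Default generator settings are fixed once as the study conditions:
`N = 9` variables named after the organ-system parameters (Bil, Na, Cre,
CRP, Glu, PF, Hb, MAP, Plt), `S = 123` pairs, weak correlation targets
(`|rho| <= 0.5`, reflecting that correlations in this setting are
characteristically weak), cross-stage coupling 0.3, cohort size 1000 with
15% mortality, lengths of stay of at least 72 h drawn as
`72 h + Gamma(1.2)` with scale 180 h for non-survivors and 360 h for
survivors (about 12.6 vs 22 days on average), measurements every 12 h
with 2 h jitter and noise sd 0.1 on the standardized scale.  The group-
and stage-specific default structures encode a persistent negative
bilirubin-platelet edge and a survivor-event block around CRP.  What the
generator does *not* emulate: non-stationary drift within a stage,
informative missingness, measurement batching, or treatment feedback --
passing tests demonstrate correctness of the machinery under the assumed
sampling model, not robustness to those real-data features.

## The matched case-control pipeline

`match_cohort()` implements control selection for the four-network study:

1. encounters need at least one value of every network parameter in the
   admission window (the 0-24 h interval after admission, half-open);
2. a logistic propensity model for death is fitted on covariates plus the
   admission values of the network parameters (the model family is the
   standard reading of the propensity score; separation is an error);
3. each case's risk set holds all encounters -- irrespective of survival,
   so an encounter may serve as control before becoming a case -- treated
   at least as long as the case, with complete admission values and at
   least one value per parameter in the event window (48-24 h before the
   index time, the control's admission plus the case's treatment
   duration);
4. the nearest control by Mahalanobis distance on `[log ps,
   admission values]` is matched to each case, with the covariance
   estimated over all eligible encounters (ridge-inflated diagonal when
   numerically singular);
5. pairs with either score outside the common support are dropped, and
   among pairs sharing a control only the smallest `|ps_case -
   ps_control|` survives.

Ties (nearest control, duplicate pruning) break lexicographically by
encounter id, making the pipeline deterministic under cohort row
permutations.  Window values are summarized by the measurement closest to
the window's anchor (admission time, or death/index time), generalizing
the propensity rule of using data recorded closest to admission; `mean`
and `median` summaries are available as options since the aggregation
rule for the network matrices is not uniquely determined by the design.
Greedy per-case matching (with duplicate pruning afterwards) is used
rather than globally optimal matching, which is out of scope.

`run_study()` then assembles the four `S x N` matrices and runs C1
(groups at admission, unpaired), C2 (groups at event, unpaired), C3
(survivors admission vs event, paired) and C4 (non-survivors admission
vs event, paired).  A `drop_dual_role` flag supports the sensitivity
re-analysis that removes pairs whose case also serves as a control
elsewhere.

## Numerical choices and problem sizes

* Spearman p-values: `t` approximation; `|r| = 1` maps to `p = 0`.
* Graphical lasso: coordinate-descent tolerance `1e-5`, at most 100 outer
  sweeps; penalties where the fit degenerates are skipped with a warning,
  and only if every penalty fails is an error raised.
* PSD repairs clip eigenvalues at `1e-8` and renormalize to unit
  diagonal, with a warning.
* The test suite sizes its simulations to desk scale: calibration uses
  500 null replicates at `M = 500` (rejection rates required in
  `[0, 0.07]`, the upper edge being the 95% Monte-Carlo band around the
  nominal 0.05 for a conservative discrete test), power uses 200
  replicates at `M = 1000` against a single planted `rho = 0.6` edge in
  otherwise unstructured data (with background edges present, threshold
  jitter widens the null spread of the global-strength statistic and its
  power drops well below that of the edge-level statistic), and the
  pipeline calibration uses 100 synthetic cohorts of 400 encounters with
  `M = 200` (bound 0.10, the corresponding band at 100 replicates).  One
  full comparison at the operating point (`S = 123`, `N = 9`, all 53
  characteristic rows, `M = 10000`) is timed in the suite and completes
  in well under a minute.

## Known limitations

* Networks must share the same node set; comparing networks over
  different variables is not supported.
* The permutation test is generic but computational: estimators with
  internal resampling (distance correlation, EBIC selection) multiply its
  cost, and the graphical lasso path inside a 10^4-replicate test is
  expensive -- the Spearman estimator is the practical default.
* The distance correlation matrix is computed from dense `S x S` distance
  matrices per variable; memory grows quadratically in `S`.
* Cluster-count differences inherit the arbitrariness of modularity ties
  noted above.
* The Spearman edge test is a test of zero rank correlation, not of
  independence: under strong non-monotone dependence with zero
  correlation (e.g. `y = x^2` with symmetric `x`) the sampling variance
  of the rank correlation is inflated beyond its independence value, so
  the t-approximation rejects at well above the nominal level (about 17%
  at `S = 200` for that example) even though the population Spearman
  correlation is exactly zero.  Spurious Spearman edges under such
  dependence are expected; the distance-correlation estimator is the
  appropriate tool there.
* The propensity pipeline treats score-like covariates as given inputs;
  computing clinical severity scores from raw data is out of scope, as is
  any imputation of missing parameter values.
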