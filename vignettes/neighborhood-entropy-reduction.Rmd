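---
title: "Neighborhood roughness joint entropy and greedy attribute reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood roughness joint entropy and greedy attribute reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrhreduct)
```

## The problem

Gene-expression-style data — tens to thousands of continuous measurements
per sample, a categorical phenotype, few samples — resists classical
rough-set reduction because equivalence classes under exact value matching
collapse to singletons on continuous data. Neighborhood rough sets replace
exact matching with a metric ball: two samples are indiscernible on an
attribute subset `B` when their Euclidean distance on `B` is at most a
radius `delta`. This package implements an uncertainty measure on that
granulation and a greedy search for a minimal attribute subset preserving
it.

## The model

For a decision table with `n` samples, attributes `C`, decision `d` and
`delta` in `[0, 1]`:

* **Neighborhood class** `n_B(x)`: all samples within Euclidean distance
  `delta` of `x` on subset `B`. The comparison is *inclusive* (`<= delta`):
  a pair at exactly the radius are neighbors. This matters in practice —
  in the bundled 4x3 example, two samples sit at distance exactly 0.30 on
  attribute `a` and are neighbors at `delta = 0.3`.
* **Counting measure**: all set sizes use `m(S) = |S|`. The measure-
  theoretic formulation of the approximations extends to infinite sample
  spaces, but on finite data the Lebesgue measure specializes to
  cardinality, which is what the package computes.
* **Approximations**: for each decision class `d_j`, the lower
  approximation collects samples whose whole neighborhood lies in `d_j`,
  the upper those whose neighborhood meets it; precision
  `rho = |lower| / |upper|`, roughness `gamma = 1 - rho`.
* **Entropies** (base-2 throughout; all values in bits): per-sample
  neighborhood entropy `-log2(|n_B(x)|/n)`, its mean over the sample set,
  and the joint entropy with the decision,
  `-(1/n) sum_i log2(|n_B(x_i) ∩ [x_i]_d| / n)`.
* **Neighborhood roughness joint entropy (NRH)**:

  `NRH(d, B) = -(1/n) sum_j log2(2 - gamma_B(d_j)) * sum_{x_i in d_j} log2(|n_B(x_i) ∩ d_j| / n)`

  combining the algebra view (the roughness weight, 1 when a class is
  exactly describable, `log2(2) = 1` down to `log2(1) = 0` as roughness
  reaches 1) with the information view (the joint-entropy inner sum).

A deliberate interpretive choice: the inner sum ranges over the *members
of class* `d_j` only, i.e. each sample contributes through its own
decision class, mirroring the joint-entropy definition. A literal sum of
every sample against every class would hit `log2(0)` whenever a
neighborhood misses a foreign class entirely. The adopted reading keeps
every term finite (a sample always belongs to its own neighborhood and
class) and reproduces all hand-computed values of the worked example
(`NRH = 0.8301`, significances `0.5081 / 0 / 0.2075`, `NRH({c}) =
0.3219`); the alternative readings do not.

Two useful limits, both asserted in the test suite: with a single decision
class, roughness is 0 everywhere and NRH reduces to the mean neighborhood
entropy; with a radius below every nonzero pairwise distance, every
neighborhood is a singleton and NRH equals `log2 n`.

### Empty subsets

The empty attribute subset uses the convention that all distances are 0,
so every neighborhood is the whole sample set. With two or more classes
every class is then fully rough and `NRH(d, {}) = 0`. This anchors the
greedy search and the monotonicity chain `{} ⊆ B1 ⊆ B2 ⊆ C`.

## The reduction algorithm

`arnrje()` implements a core-plus-greedy heuristic:

1. **Core**: every attribute whose sole removal from `C` drops NRH by more
   than `epsilon` joins the starting subset.
2. **Forward greedy**: while `NRH(B) < NRH(C) - epsilon`, add the
   candidate maximizing `NRH(B + {a})`; ties go to the earlier attribute
   index (a deterministic, reproducible rule).
3. **Completeness pruning**: walk `B` in addition order; drop any
   attribute whose removal keeps NRH within `epsilon` of the full-set
   value, recomputing against the shrinking subset after each removal.

The result always attains `NRH(C)` within `epsilon` and every retained
attribute is necessary in the pruned subset's own terms. NRH values are
cached per attribute subset during the search; caching is a pure speed
optimization and cannot change results. The search is a pure function of
`(table, delta, epsilon)`.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `delta` | — (0.3 in the CLI) | normalized distance | granulation radius; smaller = finer granules, larger reducts. Sweep `0.05–1` with `sweep_delta()` and pick the knee of accuracy vs. reduction rate. |
| `epsilon` | `1e-10` | bits | tolerance for "NRH equal" / "significance > 0"; absorbs double-precision noise only, not a model parameter. |
| `eps_var` | `1e-12` | variance | Fisher-score denominator guard so zero-within-variance attributes score large but finite. |
| `folds`, `seed` | 10, 0 | — | stratified cross-validation; folds deterministic given the seed. |

Distances are compared to `delta` with raw `<=` in double precision — no
tolerance is applied to the comparison itself, so the radius is meaningful
only on normalized data. `normalize_minmax()` (the CLI default) maps every
column to `[0, 1]`; constant columns map to zeros rather than erroring, so
degenerate attributes flow through and are simply never selected. The
bundled worked example is consumed as printed, without re-normalization.

## The synthetic generator

`simulate_decision_table()` emulates a heavily down-scaled expression
matrix with known structure: informative columns are per-class Gaussians
whose means sit `class_separation` within-class standard deviations apart
(default 3: clearly separated but overlapping clusters), min–max
normalized; redundant columns are noisy copies of informative ones
(`noise_sd = 0.05` on the normalized scale by default); irrelevant columns
are uniform noise; classes are as balanced as possible. The generator is a
pure function of its arguments including `seed`, and restores the caller's
RNG state.

What it does *not* emulate: heavy-tailed and count-like marginal
distributions, gene–gene correlation blocks, batch effects, class
imbalance, or missingness. Passing tests on this generator therefore
demonstrates algorithmic correctness — the measure's algebra, the search's
contracts — not robustness to real expression data's pathologies.

## Relations between reduct definitions

Three predicates classify a subset: `is_nrh_reduct()` (NRH preserved,
every member necessary), `is_positive_region_reduct()` (algebra view) and
`is_entropy_gain_reduct()` (information view). When NRH equality between
two subsets arises from identical neighborhood structures, an NRH reduct
is also a positive-region reduct and coincides with an entropy-gain
reduct. The equality can, however, arise without structural identity, and
the minimality clauses genuinely diverge: NRH can strictly drop on an
attribute removal purely through same-class neighborhood growth (the
positive region unchanged), and the joint entropy can sit at its maximum
(all class-constrained neighborhoods singletons) while roughness still
differs between subsets. The test suite therefore enumerates all subsets
of small random tables, cross-checks every anomaly against an independent
brute-force oracle, and *reports* confirmed counterexamples with the full
table rather than asserting the inclusions universally.

## Known limitations

* **Exact duplicate columns are retained.** Under the plain Euclidean
  distance, a duplicated column doubles its coordinate's squared
  contribution; the full-set NRH is computed with that doubled weight, and
  attaining it generally *requires* keeping both copies. Duplicates are
  therefore not removed by the reduction — a real property of the
  formulation, not an implementation artifact. (Constant columns, by
  contrast, contribute nothing to any distance and are provably never
  selected.) Deduplicate columns upstream if this matters.
* Greedy search is heuristic: the reduct preserves NRH and is pointwise
  minimal, but is not guaranteed to be a globally smallest such subset.
* The naive distance path costs `O(n^2 |B|)` per subset evaluation; the
  package targets the post-prefilter regime (tens of candidate attributes,
  up to a few hundred samples).
* Fisher prefiltering is univariate: attribute pairs that are only jointly
  informative can be discarded before the search sees them.
* Multi-class recall is reported as the unweighted (macro) mean of
  per-class recalls, with per-class values alongside.

## Test design notes

Golden values come from the bundled 4x3 worked example, verified by hand
arithmetic. Property tests run the measure's bounds, monotonicity
(in subset and radius), and oracle equivalence on 200 random tables of up
to 12 samples and 6 attributes; reduct-theory enumeration covers all
subsets of 50 random tables with up to 6 attributes. These sizes keep
exhaustive enumeration exact (the point of the exercise) while the whole
suite completes in about a minute.
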