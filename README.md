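# nrhreduct

Attribute reduction (feature selection) for continuous-valued decision
tables with **neighborhood rough sets** and an entropy-based uncertainty
measure. The package targets the situation common in transcriptomics and
other tabular omics work: a samples-by-features matrix with a categorical
outcome, far more features than samples, and a need for a small feature
subset that preserves the discriminating structure of the full table —
without discretizing the data first.

## The method

A *neighborhood decision system* is a table of `n` samples with `m`
continuous attributes `C`, a decision label `d`, and a radius
`δ ∈ [0, 1]`. On an attribute subset `B ⊆ C`, the neighborhood class of a
sample is

```
n_B(x) = { y : ||x_B − y_B||₂ ≤ δ }       (inclusive Euclidean threshold)
```

Sets are measured with the counting measure `m(S) = |S|` (the
finite-sample specialization of the Lebesgue measure). For each decision
class `d_j` the lower/upper approximations, precision `ρ` and roughness
`γ = 1 − ρ` are the usual rough-set granules. The package's central
quantity is the **neighborhood roughness joint entropy**

```
NRH(d, B) = −(1/n) Σ_j log2(2 − γ_B(d_j)) · Σ_{x_i ∈ d_j} log2( |n_B(x_i) ∩ d_j| / n )
```

which weights an information-view joint-entropy term per class by an
algebra-view roughness factor. NRH is nonnegative and monotonically
non-decreasing as attributes are added, so greedy forward search is
well-behaved. The **ARNRJE** algorithm seeds the search with the attribute
core (attributes whose sole removal from `C` drops NRH), greedily adds the
candidate maximizing NRH until the full-set value is reached, then prunes
any attribute whose removal no longer costs NRH. For high-dimensional
tables, a **Fisher-score** filter reduces the candidate set first, and a
stratified cross-validation harness (3-NN and linear SVM) scores the
selected subset.

## Worked example

The package ships a hand-checkable 4-sample, 3-attribute table
(`inst/extdata/example_4x3.csv`):

```r
library(nrhreduct)
dt <- read_decision_table(system.file("extdata", "example_4x3.csv",
                                      package = "nrhreduct"))
nrh(dt, delta = 0.3)
#> [1] 0.830075
sig_inner(dt, "a", delta = 0.3)   # 0.5081: removing a costs half a bit
#> [1] 0.5081469
sig_inner(dt, "b", delta = 0.3)   # 0: b is redundant at this radius
#> [1] 0
arnrje(dt, delta = 0.3)
#> # ARNRJE reduct trace (delta = 0.3)
#>   NRH(full set)  : 0.830075 bits over 3 attributes
#>   core           : {a, c}
#>   reduct         : {a, c} (2/3 attributes, reduction rate 0.3333)
```

At `δ = 0.3` the neighborhoods split into `{x1} {x2,x3} {x2,x3} {x4}`;
both decision classes have precision 1/3 (roughness 2/3), giving
`NRH = 2·log2(4/3) ≈ 0.83` bits. Attributes `a` and `c` each carry
irreplaceable information (internal significances 0.5081 and 0.2075 bits),
`b` carries none, and the reduct is `{a, c}` — one third of the attributes
eliminated with the granulation structure fully preserved. A run over
synthetic data:

```r
dt <- simulate_decision_table(100, 4, n_redundant = 2, n_irrelevant = 14,
                              seed = 1)
glance(arnrje(dt, delta = 0.2))
sweep_delta(dt, classifier = "knn3") |> autoplot()
```

A thin CLI wraps the same functions
(`Rscript inst/cli/nrhreduct.R reduce --input table.csv --delta 0.3 ...`,
subcommands `reduce`, `sweep-delta`, `evaluate`, `simulate`,
`verify-example`).

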