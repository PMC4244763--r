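---
title: "Measuring and testing nestedness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and testing nestedness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestkit)
```

## The statistical model

`nestkit` treats nestedness as a property of a non-negative biadjacency
matrix and nothing else. Two assumptions shape everything in the package:

* **Context freedom.** The row/column order of a biadjacency matrix is an
  arbitrary storage choice; permuting it does not change the network. A
  nestedness score should therefore not depend on it. Some measures (the
  spectral radius SR, the configuration-model overlap ratio JDM) are
  intrinsically order-invariant; the others (NODF, WNODF, MD, BR, NTC) are
  scored on a canonical maximal-nestedness arrangement computed by the
  package, so that each matrix has a single well-defined score.
  `sort = FALSE` relaxes this deliberately, e.g. when rows follow a real
  environmental gradient whose order is meaningful.
* **Scores are only interpretable against a null distribution.** All
  nestedness measures co-vary strongly with matrix size and fill, so the
  package never asks "is 44.4 a large NODF?" but "how often does a random
  matrix that conserves the chosen features score higher?".

## Sorting and tie-breaking

The canonical arrangement orders rows and columns by descending degree
(number of nonzero entries). Degree ties are where design choices were
genuinely open:

* *Weighted matrices*: of two tied lines, the one with larger weights on
  the majority of positions where both are nonzero ranks first; remaining
  ties by larger total weight; then by original index. These keys never
  reference cell positions, so they are invariant under input
  permutations by construction.
* *Binary matrices*: tied lines are compared lexicographically
  (descending). A lexicographic key is read against an ordering of the
  *opposite* axis, which is itself being sorted; to break the circularity
  deterministically, columns are first ranked by degree plus their
  *degree profile* (the sorted multiset of degrees of the rows they touch
  — a permutation-invariant key), rows are then ranked by degree, profile
  and lexicography over those columns, and columns re-ranked once against
  the final rows. Residual ties fall back to the original index; at that
  point the tied lines are almost always identical, in which case the
  arrangement (as a matrix) is unaffected.

This matters because two of the reported measures are sensitive to the
order *within* tied-degree blocks (BR through column packing, NTC through
the full arrangement). The package's property tests permute fixture
matrices 100 times and require bit-identical scores from every measure;
the profile-seeded scheme is what makes that hold. NODF, WNODF, MD, JDM
and SR are provably indifferent to tie order (equal-fill pairs contribute
zero, or the statistic is order-free), which the ensemble scorer exploits
by switching to a plain degree sort when neither BR nor NTC is requested.

NTC is reported on a further refinement: starting from the degree sort, a
deterministic hill climb over adjacent row-pair and column-pair swaps
accepts a swap only when the temperature strictly decreases and stops when
a full pass changes nothing. A local optimiser is used on purpose — the
global ordering problem is combinatorial, and a deterministic climb keeps
the score reproducible and cheap; the trade-off is that the reported
temperature is an upper bound on the unknown global minimum.

## The temperature geometry

Cell (i, j) of an n×m matrix is mapped to the unit square at its midpoint
(x = (j−½)/m, y = (i−½)/n, origin at the top-left corner, where a nested
matrix concentrates its presences). The *isocline of perfect order* is
modelled as the p-norm curve x^a + y^a = 1; the exponent a is solved
numerically (`uniroot` on `integrate`, bracket a ∈ [0.02, 2000]) so that
the area on the presence side equals the fill proportion p = F/(nm). Each
unexpected presence (outside the isocline) or absence (inside it) scores
u = (d/D)², with d the distance from the cell to the isocline along the
cell's main-diagonal direction and D the full diagonal chord, found by
root-bracketing along that chord (the bracket provably straddles the
isocline). The temperature is T = 100·Σu/(U_max·n·m) with the classic
normalisation U_max = 0.04145. Completely full matrices are defined to
have T = 0 (no absence can be unexpected), and matrices with fewer than 4
cells are rejected as having no meaningful geometry. Because the grid of
midpoints, the isocline and hence every cell's u depend only on (n, m, F),
they are computed once and cached; re-sorting and hill-climbing only
re-sum a lookup table, which is what makes NTC affordable inside null
ensembles.

The choice of the p-norm isocline family is this package's own: the
classic temperature literature fixes the idea (a monotone curve splitting
the unit square at the fill proportion) but not one formula. Any smooth
monotone family with a fill-matching parameter yields T = 0 on perfectly
nested arrangements and grows with disorder; results are therefore
comparable within this package, and close to — but not cell-for-cell
identical with — other temperature implementations.

## Null models

Binary models (applied to presence/absence patterns):

| id | mechanism | conserved exactly | conserved in expectation |
|----|-----------|-------------------|--------------------------|
| SS | F cells placed uniformly without replacement | shape, fill | — |
| FF | curveball trades | shape, fill, both degree sequences | — |
| CC | F cells, weight (k_i/m + d_j/n)/2, without replacement | shape, fill | degree structure (tendency) |
| DD | independent Bernoulli, p_ij = (k_i/m + d_j/n)/2 | shape | degrees |
| EE | independent Bernoulli, p = F/(nm) | shape | fill |

Weighted models (zero pattern always conserved): `SHUFFLE` permutes the
multiset of nonzero weights over the fixed positions; `CRT` redraws each
row's weights over its occupied cells scaled to the row total; `CCT` is
its column mirror; `RCTA` is the elementwise mean of an independent CRT
and CCT draw (marginal totals then hold in expectation, the grand total
exactly).

Numerical choices worth knowing:

* **FF sampling** uses curveball trades: two random rows swap a uniformly
  re-dealt subset of their exclusive columns. Each draw applies
  5·max(n, m) trades, and consecutive draws continue the same chain
  (draw k starts from draw k−1), which mixes fast at the matrix sizes the
  package targets; the uniformity of the sampled distribution over an
  enumerable degree-preserving class is asserted by a chi-square test in
  the suite.
* **CRT positivity.** Occupied cells must stay nonzero or the zero
  pattern would change. Rows whose weights are all integers get 1 unit
  per occupied cell plus a uniform-multinomial remainder (row totals stay
  exactly integer); other rows get symmetric Dirichlet(1) shares of the
  row total, which are positive almost surely.
* **CC semantics.** Only shape and fill are hard constraints; the
  degree-derived cell weights bias — but do not pin — the marginal
  structure. Other implementations of a "partly structured" shuffle may
  differ; treat CC comparisons across software with care.
* **Degenerate draws.** DD/EE (and rarely CC) can produce empty lines.
  Generators return them untouched so the conservation contracts stay
  literal; the ensemble pipeline strips empty lines before sorting and
  scoring, and redraws entirely empty matrices (aborting after 1,000
  consecutive failures).
* **Aliases.** The numeric ids accepted for binary models are 1 = SS,
  2 = CC, 3 = FF, 4 = DD, 5 = EE.

## Ensembles and significance

One ensemble per null model serves all selected measures — every null
matrix is stripped, sorted and scored by each measure — so per-measure
results are directly comparable. With `ensemble = "fixed"` the user picks
N. With `ensemble = "adaptive"` two groups grow from 500 draws each, 500
per group per round; after each round a two-sided Mann–Whitney U-test
compares the groups on the first selected measure, and the groups merge
as soon as p > 0.10 (the remaining measures inherit the merged ensemble).
The minimum final size of 1,000 keeps p-values down to 0.001 assignable;
growth stops unconditionally at 100,000 members in case the test always
rejects. Per-round increment, cap, test level and the test itself are
arguments of `run_adaptive_ensemble()`, mainly so the stopping logic can
be exercised deterministically.

For each (model, measure) pair, with the measure's direction of
increasing nestedness (detected empirically, below):

* `p` counts null scores *strictly* more nested than the observed one;
  ties count against significance, and when the count is zero the
  conservative bound p = 1/N is reported with an explicit flag (rendered
  `<1/N`).
* `z = (Measure − ⟨Measure⟩)/σ` with the sample (N−1) standard
  deviation; a zero-variance ensemble leaves z undefined (NA with a
  warning) rather than infinite.
* `T = Measure/⟨Measure⟩`; a zero mean leaves T undefined. For
  higher-is-more-nested measures T > 1 means more nested than expected;
  for lower-is-more-nested measures the reading flips.

The U-test wrapper delegates to `stats::wilcox.test`: exact enumeration
for small untied samples, otherwise the normal approximation with tie and
continuity corrections (group sizes in the adaptive path are always
≥ 500); two all-identical groups return p = 1 by convention.

Reproducibility: every generator consumes the standard R RNG; ensemble
builders accept a seed, and `nested_test()` derives one sub-seed per null
model at a fixed offset so adding or removing a model never perturbs the
draws of the others.

## Direction detection

Whether a larger score means more nested is not hard-coded per measure.
It is detected by scoring two reference matrices with equal fill (55) and
equal total weight (220): a strongly nested 10×10 staircase with weights
decreasing away from the top-left corner, and a strongly non-nested
10×11 weighted checkerboard. Whichever fixture scores higher orients the
measure, the result is memoised, and a measure that cannot be oriented
(identical scores) is rejected. The benefit is extensibility — a measure
added later is oriented automatically by the same mechanism.

## The synthetic-data generators

`make_fixture()` produces the archetypes the tests and demos are built
from: perfectly nested binary staircases (cells added along successive
anti-diagonals, so every prefix is a valid staircase), their weighted
counterparts (weights decreasing with anti-diagonal index, reproducing
the nested reference matrix at 10×10/fill 55), parity checkerboards, and
uniform random fill. These emulate the *structural* extremes and the
unstructured middle, deterministically. They do not emulate features of
real interaction data — degree heterogeneity beyond what uniform filling
produces, sampling effort gradients, detection error, modularity mixed
with nestedness — so green property tests demonstrate correctness of the
machinery, not that any field dataset is well described by these nulls.

Validation problem sizes were chosen to keep the full suite comfortably
desk-scale: property loops use matrices between 2×2 and 12×10;
permutation invariance uses 100 permutations; the NODF-vs-oracle check is
exhaustive over all binary matrices up to 4×4; null-model conservation is
asserted over 1,000 seeded draws per model; the p-value calibration
experiment uses 200 replicates of N = 1000 ensembles on a dense 8×8,
fill-40 base (dense so that draws essentially never lose a line when
stripped, keeping the self-null experiment exchangeable on a fixed
shape).

## Known limitations

* The NTC optimiser is a local hill climb; reported temperatures are
  upper bounds and, like all temperature implementations with an
  unstandardised isocline, not directly comparable across software.
* Binary-tie lexicography can, for adversarially symmetric matrices with
  non-identical tied lines, leave BR/NTC weakly dependent on the input
  order; degree profiles resolve all generic cases.
* p-values across multiple null models are reported uncorrected; if you
  screen many models, apply your own multiplicity control.
* CC and the weighted total-conserving models fix only what the table
  above says; they are this package's operationalisation of "partly
  structured" shuffles and may differ from other software's.
* Exact uniform sampling of fixed-margin matrices (e.g. via sequential
  importance sampling) and weighted degree-preserving nulls are out of
  scope.
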