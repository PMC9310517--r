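---
title: "Hierarchical classification of tree-structured labels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical classification of tree-structured labels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierclass)
```

This vignette documents the models, conventions and design decisions behind
`hierclass`. The package targets single-path tree hierarchies of the kind
found in protein structural classification (CATH-style codes) and enzyme
function annotation (EC numbers): each instance carries one label path from
the top of the tree down to either a leaf (full-depth labelling, FD) or an
internal node (partial-depth, PD, as when an enzyme is annotated only to two
EC digits). Directed acyclic graphs, multi-parent nodes and multi-label
instances are out of scope.

## The hierarchy and its conventions

A hierarchy is the minimal rooted tree containing every observed label path.
Three conventions fix the semantics everywhere in the package:

* **Full-path keys.** Nodes are identified by the `/`-join of their labels
  from level 1 (`"3/40/50"` rather than `"50"`), because bare tokens recur
  across branches — EC numbers reuse the same digits under different
  parents. The delimiter `/` is reserved and may not appear inside a token.
* **A synthetic root at level 0.** The root is a sentinel, never a class:
  it is excluded from ancestor sets, from every metric, and from model
  counts.
* **1-based levels.** Level 1 holds the children of the root, matching how
  database characterisation tables number their "1st … 4th" levels.

With these conventions the hierarchy constraint — a predicted class implies
all its superclasses — is structural: any node determines its unique chain
of ancestors, and every approach below emits paths, never bare nodes.

## The three approaches

All three approaches delegate flat multiclass work to an injected *base
learner factory*: `make(seed)` returns a learner with `fit(x, y)`,
`predict(fit, x)` and optionally `predict_confidences(fit, x)`. Built-in
factories wrap `ranger` (probability forest) and `rpart`, and two diagnostic
learners (memorizing, majority) support testing. Class predictions break
probability ties by the lexicographically smallest class key, so every
pipeline is deterministic given its seed.

**Global.** One learner whose classes are entire observed label paths. A PD
path is its own, shorter, joint class — so a dataset can have more joint
classes than last-level classes. Prediction decodes the joint label back
into a path, which is valid by construction. A dataset with a single
distinct path is rejected as degenerate.

**Local per Level.** One learner per level `l`, trained on the instances
whose label reaches `l` with the full-path key at `l` as the class. PD
instances are excluded from the levels they do not reach — including them
would require inventing deeper labels for them. A level with a single
observed class becomes a pass-through. Because the per-level learners are
independent, their outputs need not be mutually consistent; prediction
therefore has two modes. `raw` returns each level's output untouched (the
form in which per-level results are usually reported). `path_constrained`
(the default) assembles a path top-down, accepting the level-`l` prediction
only when it is a child of the accepted level-`(l-1)` node and truncating at
the first conflict, which yields a valid, possibly partial, path.

**Local per Node.** One learner per parent node with at least two children
carrying training data, trained under the *siblings policy*: all instances
passing through the parent, labelled by their immediate child. The policy is
the standard minimal-leakage choice — each node's model sees exactly its
subtree. Single-child parents are recorded as pass-throughs and descended
without a model. Prediction routes each instance from the root downwards.
Under `leaf_policy = "mandatory"` descent continues while children exist;
under `non_mandatory` it additionally stops when the learner's maximum class
confidence falls below `confidence_threshold` (default 0, i.e. never stop
early, so that stopping is driven by label availability rather than by
confidence; learners without confidences always descend). A stop at the
root yields an `NA` path; that can only occur with a positive threshold.

Model counts follow the structure: 1 for Global, one per multi-class level
for per-Level, one per multi-child parent for per-Node, so
`per_node >= per_level >= global` on any hierarchy with depth and branching
of at least 2.

## Hierarchical metrics

For instance `i`, `C_i` is the ancestor-augmented true set (the true node
plus all ancestors, root excluded) and `Z_i` the predicted set. The package
computes

$$\mathrm{hP} = \frac{\sum_i |Z_i \cap C_i|}{\sum_i |Z_i|}, \qquad
  \mathrm{hR} = \frac{\sum_i |Z_i \cap C_i|}{\sum_i |C_i|}, \qquad
  \mathrm{hF} = \frac{2\,\mathrm{hP}\,\mathrm{hR}}{\mathrm{hP} + \mathrm{hR}}.$$

Aggregation is micro: the sums run over instances before the ratio is
taken. Because both sets are chains of path prefixes,
$|Z_i \cap C_i|$ equals the length of the longest common prefix of the two
paths; the test suite checks this fast path against a brute-force
implementation that materialises every ancestor set. When
$\mathrm{hP} + \mathrm{hR} = 0$, hF is defined as 0, the usual F-measure
convention. No extra normalisation is applied to predictions deeper than
the truth: they raise $|Z_i|$ and so lower hP, exactly as the defining sums
dictate. Flat per-level metrics (balanced accuracy, multiclass Matthews
correlation from the confusion matrix, macro F1, and macro one-vs-rest AUC
when scores are available) complement hF; a single-class truth makes MCC
undefined and it is reported as `NA` with a warning.

## Dataset characterisation and preparation

`summarize_levels()` reports, per level, the number of classes, the mean
children per parent (reported as a rounded integer; `NA` at level 1), and
the mean, SD and Variation coefficient `V = SD/mean` of per-class sample
counts. Two conventions are worth stating. The SD is the sample SD
(denominator `n - 1`); published characterisation tables generally do not
state which convention they use, and with hundreds of classes the two
differ negligibly. `V` is stored at full precision and rounded to 2
decimals for display. The dispersion threshold `V = 1` — the V of an
exponential distribution — separates low- from high-variance levels, and
the boundary value `V = 1` itself is assigned to the low-variance branch.

Preparation has two steps, both applied before any train/test split:

* `filter_min_samples(min_n = 10)` drops instances whose class at the
  reference level (deepest level by default; PD instances shallower than
  the reference are grouped by their deepest available class) has fewer
  than `min_n` members. With `min_n >= k` this guarantees one sample per
  class per fold in k-fold cross-validation.
* `semi_balance(cap)` under-samples every class above `cap` down to exactly
  `cap` using the NearMiss heuristic: retained majority samples are those
  with the smallest mean distance to the `k = 3` farthest samples of the
  other classes (NearMiss version-2 semantics; version 1, distance to the
  `k` nearest, is available via `version = 1`). Classes at or below `cap`
  are untouched — the set is *semi*-balanced, never equalised, so small
  classes are not sub-sampled away. Distances are Euclidean on the raw
  features; no scaling is applied by default since the built-in tree
  learners are scale-invariant. Ties in the distance ranking are broken by
  original row order, making the result deterministic.

Balancing before splitting means the under-sampling selection has seen the
full data; the alternative (balancing within each training fold) avoids
that mild leakage at the cost of fold-dependent class sizes. The package
balances before splitting and documents the caveat here; users who prefer
per-fold balancing can compose the verbs themselves.

`aac_features()` provides the one featuriser in scope: amino-acid
composition (20 relative frequencies per sequence, rows summing to 1), with
non-standard letters either rejected or skipped.

## Cross-validated comparison

`cross_validate()` stratifies folds by each instance's deepest available
class (per-class fold counts differ by at most one, and a class smaller
than `k` is a hard error naming the class), trains every requested approach
on the same folds, and records per fold the hierarchical metrics on full
paths plus flat metrics per level. Sharing folds across approaches makes
per-fold differences paired; `compare_approaches()` runs the two-sided
paired Student's t-test on them (sidedness is a package choice; two-sided
is the conservative default). When every per-fold difference is identical
the t statistic is undefined: the comparison reports `p = 1` for a zero
shift and `p = 0` otherwise, flagged with `zero_variance = TRUE`.
`resource_profile()` wraps a call with wall-time and peak-heap accounting;
it is informational plumbing only, since absolute times and bytes are
hardware-dependent.

## The recommendation engine

`recommend()` encodes the decision workflow as ordered rules over a profile
(labelling depth, last-level V, resources, goal); every profile fires a
deterministic, non-empty trace.

1. `V > 1` at the last level → recommend semi-balancing as preprocessing.
2. PD labelling → a Local approach: per Level when `V <= 1`; per Level when
   `V > 1` but resources are limited; per Node when `V > 1` and resources
   are ample.
3. FD labelling → branch on the goal: Global for sensitivity; for
   specificity, a Local approach refined by the same V logic as rule 2.

With an FD dataset and an unspecified goal the engine cannot pick a branch
on the data alone, so it reports both: the Recommendation's `approach`
field carries the sensitivity branch (`"global"`), `alternative` carries
the V-refined Local branch, and the trace records both rules. This keeps
`approach` a single value from the fixed vocabulary while losing no
information — collapsing the two branches into one label would misstate
what the rules can conclude.

## The synthetic generator

`generate_hier_data()` emulates the statistical structure the evaluation
needs, with every challenge controllable:

* **Topology**: depth `L` (up to 4 in the intended regime) and per-level
  branching (scalars, vectors, or per-node ranges) set the class counts per
  level.
* **Imbalance**: per-leaf sample counts are equal, lognormal (`sigma`), or
  power-law (`alpha`). The lognormal mean is parameterised to `n0`
  (`meanlog = log(n0) - sigma^2/2`) so `n0` is the expected class size
  regardless of spread, and `calibrate_sigma(v) = sqrt(log(1 + v^2))`
  inverts the lognormal coefficient of variation, so a target last-level V
  can be dialled in directly. Counts are rounded up and floored at 1 —
  empty classes are not classes.
* **Feature geometry**: each child's mean is its parent's plus an
  isotropic offset of norm `separation * noise_sd`; features are
  `N(leaf mean, noise_sd^2 I)`. Spherical covariance and isotropic offsets
  are the simplest structure that makes the hierarchy learnable while
  sibling leaves (separated by 2 offsets at most) remain the hardest to
  tell apart, so deeper levels are progressively harder. At
  `separation = 4` sibling clusters barely overlap; at 0 there is no
  signal at all.
* **Partial depth**: each instance is independently truncated with
  probability `partial_depth_fraction` at a uniformly chosen internal
  level. Real PD mechanisms (annotation availability) are not generative,
  so uniform truncation is an explicit modelling choice.

Two presets bracket the intended regimes. `make_cath_like()` (4 levels,
branching 4·6·4·2 = 192 leaves, FD, lognormal counts with target V 11.07,
`n0 = 10`) emulates a structural hierarchy with an extremely dispersed last
level; `make_biolip_like()` (4 levels, 6·4·3·3 = 216 leaves, 30% PD,
target V 3.01, `n0 = 12`) emulates an EC-style functional hierarchy. Both
are scaled to a few thousand instances so they generate in seconds. One
honest caveat: the sample CV of a heavy-tailed lognormal under-estimates
its population value at a few hundred classes — a handful of giant classes
dominate the mean — so the cath-like preset's *measured* V lands well below
11 while remaining far above 1 and above the biolip-like preset's, which is
the property its consumers rely on. Calibration is verified quantitatively
at moderate targets (V ≈ 1.3, where the estimator is well behaved): across
20 seeds at 225 leaves the empirical last-level V recovers the target to
within a few percent.

What passing tests on this generator do **not** show: real protein features
are neither Gaussian nor spherical, real class counts are not lognormal,
and real PD annotations are informative rather than uniform. The generator
validates the machinery — constraint preservation, metric arithmetic,
approach mechanics, calibration — not biological performance.

## Numerical and engineering choices

* Deterministic ordering everywhere: node tables and class sets are sorted
  with radix (byte-wise) order, immune to locale.
* Per-scope seeds are derived as `seed + 7919 * scope_index` (a prime
  stride, kept under 2^31), so scopes get distinct but reproducible
  streams.
* Degenerate inputs are errors, not silent results: empty path sets,
  tokens containing the reserved delimiter, non-finite features, a
  filtering step that empties the dataset, a class smaller than `k` at CV
  time.
* Problem sizes in the tests and the acceptance script are chosen to make
  each property measurable in seconds on one CPU: the learnability
  experiment uses a 3-level, branching-3 tree with about 2000 instances
  and 10-fold CV over 50-tree forests; the constraint property runs 50
  small random datasets; metric equivalence uses 1000 random instances
  over depth-4 trees.

## Known limitations

* Trees only: no DAGs, no multi-parent nodes, no multi-label instances.
* Per-level training excludes PD-truncated instances from deeper levels;
  other inclusion policies are not implemented.
* NearMiss is the only under-sampler; over-sampling hybrids are out of
  scope.
* The guideline is a fixed rule set for hierarchies up to about 4 levels;
  it is a starting point for analysis, not a substitute for an empirical
  comparison on the data at hand — which is what `cross_validate()` is
  for.
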