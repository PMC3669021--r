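---
title: "Four-tiered graphs for binary phenotype profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-tiered graphs for binary phenotype profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotier)
```

## The model

The data are a binary relation between bacterial isolates ("strains") and
phenotypic measurements ("resources": enzymes produced, carbon substrates
assimilated). Two strains are phenotypically indistinguishable under the
assay exactly when their rows agree at every position, so the natural
reduction is into *equivalence classes* of identical rows, and dually of
identical columns. The reduced bipartite relation between classes is
all-or-none: because rows inside a strain class are identical and columns
inside a resource class are identical, either every strain of class $X$
uses every resource of class $Y$ or none does. `build_class_graph()`
asserts this rather than assuming it, so inconsistent partitions fail
loudly.

Distance between profiles is the normalized Hamming distance
$d(i,j) = \#\{p : M_{ip} \neq M_{jp}\}/m$ — the fraction of measured traits
on which two strains disagree. It is a metric on $\{0,1\}^m$ (symmetric,
zero iff identical, triangle inequality), which the test suite verifies
exhaustively on small instances rather than taking on faith.

### Ordination

The vertical axis of the graph comes from a PCA of the $n \times n$
similarity matrix $S = 1 - d$, treated as an observations × features data
matrix: columns are mean-centered and the SVD of the centered matrix gives
row scores $U\Sigma$ and variance fractions $\sigma_k^2/\sum\sigma^2$. This
is deliberately *not* classical principal coordinates analysis of $d$: the
method ordinates an explicit similarity rather than a double-centered
squared-distance Gram matrix. The two usually agree closely on this kind of
data; PCoA (`stats::cmdscale`) is available behind
`method = "pcoa"` for comparison, and the similarity-PCA is the default and
the mode the layout uses.

Two consequences matter for the layout. First, strains with identical
profiles have identical similarity rows and therefore identical scores, so
a class has a single well-defined coordinate. Second, PCA sign is
arbitrary; each component is oriented so the first entity in input order
has a non-negative coordinate (ties broken by the next non-zero entry),
making outputs reproducible across platforms. The covariance divisor is
$n-1$; this affects no variance fraction (they are ratios) and is stated
only so raw coordinates are reproducible.

Degenerate inputs are handled explicitly: a single entity has no ordination
(error); all-identical profiles give zero total variance, coordinates all 0,
variance fractions reported as 0 with a warning — the graph is still built
(one strain class, placement trivially valid).

## Binarization of optical densities

Continuous absorbance matrices are thresholded at
`fraction × max(whole matrix)`, default 10%, chosen to keep only
unequivocal growth signals. *Strictly above* the threshold codes 1:
"above" with "lower values" mapping to 0 leaves equality ambiguous, so the
package declares strictness and tests it (a value exactly at the threshold
is 0). The rule is scale-invariant (the threshold scales with the maximum)
and monotone in the fraction; both are property-tested. An all-zero matrix
binarizes to all zeros with a warning, not an error, because a plate with
no growth is a legitimate (if disappointing) observation. The threshold
actually applied is attached to the result and logged by the CLI.

## The layout

Tiers sit at $x = 0, 1, 2, 3$ in abstract units (consumers rescale; the
optional yFiles output multiplies by a pixel scale and flips the y-axis,
which grows downward in yEd). Larger PC1 coordinate means higher on the
page.

**Tier 2 (strain classes).** Classes are sorted by PC1 coordinate (ties by
class id). Maximal runs of consecutive classes closer than $\varepsilon$
are re-spaced exactly $\varepsilon$ apart, centered on the mean of the
run's raw coordinates; everything else keeps its raw coordinate. The naive
single pass is not enough: spreading a long run can push its ends to within
$\varepsilon$ of previously non-overlapping neighbours. Runs are therefore
merged transitively until every consecutive gap is at least $\varepsilon$.
Centering each final run on the mean of *all* its raw coordinates preserves
the coordinate sum globally and leaves singleton runs untouched, which is
the strongest distance-preservation guarantee compatible with the min-gap
requirement — a hard bound of $\varepsilon$ on the displacement of every
class is not achievable, since a run of $k$ coincident classes must span
$(k-1)\varepsilon$. The tests assert the exact post-conditions (singleton
runs unchanged, in-run spacing exactly $\varepsilon$, run means preserved)
rather than a bound that cannot hold.

Default $\varepsilon$ is 1% of the PC1 coordinate range of the classes
(0.01 when the range is degenerate), configurable. The choice is purely
cosmetic — any value small relative to the range gives the same reading —
and is logged.

**Tier 3 (resource classes).** Barycenter placement: the mean y of the
strain classes linking in. A resource class with in-degree 0 (resources no
strain uses) has no barycenter; it is placed at the midpoint of the
occupied range and flagged, so plots show it without pretending it carries
positional information.

**Outer tiers.** Members of each class are stacked at $\varepsilon$
spacing centered on their class, first member (input order) on top;
overlaps between neighbouring stacks are resolved by the same run-spreading
rule. Note resource-class barycenters can coincide exactly, in which case
members of different stacks interleave after spreading; order within each
stack is preserved.

The association matrix (`association_matrix()`) orders nodes by tier and
top-to-bottom within tier; its only non-zero blocks are between adjacent
tiers, and the tests check it cell-by-cell against the edge list.

## Statistics

**Distance correlation.** Pearson $r$ over the strict upper triangles
(row-major $i<j$ pairing — any fixed common order gives the same $r$; the
order is stated for reproducibility of intermediate vectors). The
parametric p treats the $n(n-1)/2$ pairs as independent, which they are
not; it is reported because it is the conventional figure, and a
Mantel-style permutation p (joint row/column relabelings of the second
matrix) is computed alongside as the defensible one. The permutation test's
type-I error at $\alpha = 0.05$ is verified at $0.05 \pm 0.02$ over 200
independent replicates in the acceptance suite. Externally computed
distance matrices (e.g. phylogenetic) are accepted as square CSV; the
package does not reimplement sequence-based distances.

**Group comparison.** Kolmogorov–Smirnov normality check per group (against
a normal with the group's estimated moments — a screening figure, not a
Lilliefors-corrected test), then a two-sided Wilcoxon rank-sum test. For
combined $n \le 12$ the p-value is exact by enumeration of all
$\binom{n}{n_1}$ assignments on midranks (valid under ties, conditional on
the observed ranks); beyond that, normal approximation with tie and
continuity correction. Both paths are cross-checked against
`stats::wilcox.test` in the tests.

## The synthetic generator

`simulate_binary()` emulates the structure the method assumes, at the scale
of a phenotype-microarray screen: defaults of 33 strains × 95 resources
with 6 planted strain classes, 13 universal (all-one) and 4 unused
(all-zero) columns, and 2% cell-flip noise. The planted canonical profiles
are drawn pairwise distinct in rows and columns, with all-one/all-zero free
columns excluded whenever universal/unused blocks exist so the planted
resource partition stays identifiable. Noise is applied after forcing the
universal/unused columns, which keeps those columns clean — they exist to
exercise the full-in-degree and zero-in-degree code paths. A consequence:
with a single planted strain class every free column would be constant, so
`n_strain_classes = 1` requires all columns to be in the forced blocks.

`simulate_continuous()` layers a bimodal absorbance model on the binary
truth: growth cells draw from N(1.5, 0.1), blank cells from N(0.05, 0.02)
(defaults; dimensionless OD, truncated at zero). With these separated modes
the 10% rule recovers the truth with error well under 1%, which the
acceptance suite checks over 10 seeds.

What the generator does *not* emulate: phylogenetic correlation between
profiles, plate-position or batch effects, kinetic (time-course) OD curves,
and the heavy-tailed, occasionally ambiguous signals of real Biolog wells.
A green recovery test therefore establishes that the pipeline is correct on
data satisfying its own assumptions, not that the binarization rule is
optimal for any particular instrument.

Reproducibility contract: the same seed yields byte-identical output; the
seed travels in the spec object and in the CLI's ground-truth sidecar JSON.

## Known limitations and open choices

- Whether the published variance-explained figures for this family of
  analyses come from similarity-matrix PCA exactly as implemented here or
  from a covariance PCA of the raw binary matrix cannot be settled without
  the original data; both interpretations are one flag apart
  (`method` argument), with the text-described similarity PCA as default.
- Edge-crossing minimization is out of scope; the layout accepts crossings
  for large variable sets (interactive highlighting in yEd is the intended
  remedy).
- The CLI mirrors all options as flags only; the configuration-file mirror
  was dropped for lack of a TOML parser in the supported dependency set.
- Outer-tier overlap correction is applied by default with the same
  $\varepsilon$; whether the original figures did so is unknown, and the
  parameter is exposed.

## A small end-to-end run

```{r example}
spec <- synth_spec(n_strains = 12, n_resources = 15, n_strain_classes = 4,
                   n_resource_classes = 4, noise_flip_prob = 0,
                   n_universal_resources = 2, n_unused_resources = 1,
                   seed = 7)
sim <- simulate_binary(spec)
g <- build_tiered_graph(sim$matrix)
g
summarize_profiles(sim$matrix)
```
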