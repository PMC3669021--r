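# phenotier

Four-tiered graphs for explaining phenotypic clustering of bacterial
isolates.

## The problem

Culture-based phenotyping assays — API ZYM enzyme strips (19 hydrolytic
enzymes), Biolog PM1 phenotype microarrays (95 carbon substrates) — yield a
binary strain × resource matrix: strain *i* produces enzyme *j* / grows on
substrate *j*, or not. Ordinations such as PCA show *that* isolates cluster,
but not *which* profile components drive the clustering. `phenotier`
implements a graph-based companion to the ordination that makes the "why"
readable at a glance, for microbiologists analysing isolate collections
strain by strain.

## The method

Given a binary matrix `M ∈ {0,1}^{n×m}`:

1. **Equivalence classes.** Strains with identical rows form one class;
   resources with identical columns form one class. This losslessly reduces
   the bipartite relation: a strain class `X` links to a resource class `Y`
   iff all strains in `X` use all resources in `Y` (all-or-none by
   construction).
2. **Ordination.** Pairwise normalized Hamming distance
   `d(i,j) = |{p : M_ip ≠ M_jp}| / m`, similarity `S = 1 − d`; a PCA of the
   column-centered `n×n` similarity matrix (via SVD) gives each strain a PC1
   coordinate and variance-explained fractions `σ_k² / Σσ²`.
3. **Layout.** Four vertical tiers, read left to right:
   strains → strain classes → resource classes → resources. Strain classes
   sit at their PC1 coordinate; classes closer than a small spacing ε are
   spread ε apart, centered on the run mean, leaving all other distances
   untouched. Resource classes sit at the barycenter (mean y) of the strain
   classes linking to them; outer tiers stack class members at ε spacing.
   Class nodes are annotated with their out-/in-degree.
4. **Export.** GraphML (optionally with yFiles extensions so yEd opens the
   file fully positioned), plus a profile table reordered to match the
   graph.

Supporting statistics: optical-density binarization at a strict 10%-of-max
threshold, profile summary counts (universal/unused resources, per-strain
counts, group means), Pearson correlation between distance matrices with
both the conventional parametric p and a Mantel permutation p, and a
Wilcoxon rank-sum comparison (exact enumeration for small samples) with a
Kolmogorov–Smirnov normality check.

## Worked example

```r
library(phenotier)

spec <- synth_spec(n_strains = 12, n_resources = 15, n_strain_classes = 4,
                   n_resource_classes = 4, noise_flip_prob = 0,
                   n_universal_resources = 2, n_unused_resources = 1, seed = 7)
sim <- simulate_binary(spec)

compute_strain_classes(sim$matrix)
#> partition of 12 strains into 4 equivalence classes
#>   B1 (n=5): S001, S006, S008, S011, S012
#>   B2 (n=2): S002, S005
#>   B3 (n=2): S003, S010
#>   B4 (n=3): S004, S007, S009

g <- build_tiered_graph(sim$matrix)
g
#> tiered_graph: 12 strains | 4 strain classes | 6 resource classes | 15 resources; 38 edges (epsilon 0.01895)
g$ordination
#> ordination (similarity-pca) of 12 entities; PC1 59.4%, PC2 39.8% of variance
summarize_profiles(sim$matrix)
#> profile summary: 12 strains, 15 resources; 2 universal, 1 unused
#> resources per strain: min 4 (S002), max 9 (S004)

write_graphml(g, "graph.graphml", yed_compat = TRUE)
write_profile_table(sim$matrix, g, "profile.tsv")
```

The four planted strain classes are recovered exactly (zero noise); the six
resource classes are the four planted free classes plus the universal and
the unused block. PC1 carries 59.4% of the similarity-matrix variance and
orders the strain classes vertically; `graph.graphml` opens in yEd with
every node positioned, class sizes in the `size` attribute and connection
counts in `degree`.

For real data, start from CSV instead:

```r
m <- read_binary_matrix("enzymes.csv")              # binary assay
od <- read_continuous_matrix("biolog_od.csv")       # OD readings
m2 <- binarize(od, fraction = 0.10)                 # strict > 10% of max
```

A command-line wrapper with `graph` / `classes` / `ordinate` / `simulate` /
`correlate` subcommands is installed at
`system.file("cli", "phenotier", package = "phenotier")`; see
`?phenotier_cli`.

## Vignette

`vignettes/four-tiered-graph.Rmd` documents the model, the numerical
choices (overlap-spreading rule, PCA sign convention, exact-vs-approximate
Wilcoxon switch), what the synthetic generator does and does not emulate,
and known limitations.
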