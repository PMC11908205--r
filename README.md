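# treegrm

Branch genetic relatedness matrices (GRMs) on succinct tree sequences:
exact dense constructions, a matrix-free `O(n)`-memory incremental
matrix–vector product, randomized PCA built on it, and pedigree /
coalescent generators for study data.

## What it computes

A succinct tree sequence (node table + edge table) encodes one genealogical
tree per recombination-free genome interval. The **centered branch
relatedness matrix** `B` is the genealogical covariance of an additive
trait: up to the factor `sigma2 * mu`, `Cov(g_i, g_j) = B[i, j]` when
mutations fall as a Poisson process on branch area and effects are i.i.d.

`treegrm` provides three provably equal constructions of `B` —

- shared branch area: `B = P C P` with `C[s, t]` the total area ancestral
  to both samples and `P = I - 11'/n`,
- pairwise divergence: `B = -P D P / 2`,
- span-weighted TMRCA matrices: `B = -sum_k s_k P T_k P`,

plus the eGRM normalization (`egrm()`), the genotype GRM and allele-match
covariance (`genotype_grm()`, `match_covariance()`, exactly equal on binary
genotypes), collapse to diploid individuals, and pedigree kinship.

The centerpiece is `branch_grm_vector_product()`: `y = C w` computed in a
single sweep over the edge table without ever forming `C`, in `O(n)` memory
and `O(log n)` expected work per tree transition. `ts_pca()` performs
randomized PCA of `B` through that product, so the top-`k` eigenpairs of a
GRM over thousands of samples never require an `n × n` allocation.

Simulators are included: an SMC-style coalescent-with-recombination
generator, Poisson mutation dropping, additive trait simulation, a balanced
multi-generation pedigree with gene-dropping and per-tree coalescent
recapitation.

## Worked example

```r
library(treegrm)

ts <- simulate_coalescent_ts(n_samples = 8, sequence_length = 1e5,
                             N_e = 1e4, recomb_rate = 2e-8, seed = 1)
ts
#> Tree sequence: 128 nodes (8 samples), 328 edges, 114 trees, length 100000

# Two of the three equal routes to B (units: generations x bases)
B <- branch_grm_centered(ts)                       # P C P
max(abs(as.matrix(B) - as.matrix(branch_grm_centered(ts, "divergence"))))
#> [1] 7.152557e-07        # identical to rounding, on entries of order 1e9

round(as.matrix(B)[1:4, 1:4] / 1e5, 1)             # per-base scale
#>         [,1]    [,2]    [,3]    [,4]
#> [1,] 11110.9   409.3 -3858.8   409.3
#> [2,]   409.3 11390.9 -6321.1 11304.5
#> [3,] -3858.8 -6321.1  9508.2 -6321.1
#> [4,]   409.3 11304.5 -6321.1 11390.9

# The same product without materializing any matrix
set.seed(2); w <- rnorm(8)
y <- centered_grm_vector_product(ts, w)
max(abs(y - as.numeric(as.matrix(B) %*% w)))
#> [1] 9.536743e-07

# Randomized PCA of B through the matrix-free product
p <- ts_pca(ts, k = 2, q = 5, seed = 42)
p
#> Branch-GRM PCA (rpca+6 oversampling): 2 components over 8 units
p$eigenvalues
#> [1] 3703510079 1344966981
```

A command-line interface covering simulation, validation, GRM export,
matrix-free products, PCA, and benchmarking is installed at
`system.file("cli", "treegrm", package = "treegrm")`; run it without
arguments for usage.

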