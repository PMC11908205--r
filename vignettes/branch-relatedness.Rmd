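---
title: "Branch genetic relatedness matrices on succinct tree sequences"
author: "treegrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch genetic relatedness matrices on succinct tree sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treegrm)
```

## The model

An ancestral recombination graph (ARG) records how a set of sampled genomes
is related along the genome.  Encoded as a *succinct tree sequence* — a node
table (birth times, in generations) and an edge table (`child` inherits
`[left, right)` from `parent`) — the ARG reduces, on each recombination-free
interval, to a *local tree* `T_k` with genome span `s_k`.  The area of an
edge is its branch length times its span; under the classical infinite-sites
model, mutations fall as a Poisson process on area.

For an additive trait whose mutation effects are i.i.d. with variance
`sigma2`, the covariance of the sample-centered genetic values is (up to the
factor `sigma2 * mu`) a purely genealogical quantity, the **centered branch
relatedness matrix** `B`.  The package exposes B through several provably
equal routes:

* **Shared area.** The uncentered matrix `C[s, t]` is the total area of
  branches ancestral to both `s` and `t`
  (`branch_grm_uncentered()`); with the centering projector
  `P = I - 11'/n`, `B = P C P` (`branch_grm_centered(method = "area")`).
* **Divergence.** `D[i, j]` is the span-weighted path length between `i` and
  `j` through their MRCAs (`divergence_matrix()`), and `B = -P D P / 2`
  (`method = "divergence"`).  The relation `R_i + R_j = 2 C[i, j] + D[i, j]`
  ties the two together, with `R` the diagonal of `C`.
* **TMRCA.** For samples at time 0, `B = -sum_k s_k P T_k P` with `T_k` the
  matrix of pairwise MRCA times in tree `k` (`method = "tmrca"`).

Centering is always with respect to two individuals `U, V` drawn uniformly
**with replacement** from the sample set; this convention is what produces
the `C[U, U]`-type diagonal terms and makes the three routes agree exactly.
Two relatives of B are also provided: the `egrm()` normalization, which
weights each edge by `1 / (Sbar (1 - Sbar))` (the variance of the edge's
descendant indicator, the branch analogue of `2p(1-p)`) and skips fixed
edges with `Sbar` equal to 0 or 1, since those carry no variance; and the
genotype-based pair `genotype_grm()` / `match_covariance()`, which coincide
exactly on binary genotypes.

The unit of `C`, `B` and `D` is generations times genome-length units;
divide by the sequence length for a per-unit-genome matrix.  The eGRM is
dimensionless.

## The incremental product (Algorithm V)

Materializing any of these matrices costs `O(n^2)` memory.  The package's
central algorithm, `branch_grm_vector_product()`, computes `y = C w` exactly
in one left-to-right sweep over the edge table with `O(n)` additional memory
and per-tree-transition work proportional to the depth of the rewired nodes
(`O(log n)` for balanced trees).  Per node it keeps a lazy subtree weight
`w(n)`, an accumulated value `v(n)`, and the position `x(n)` of the last
update; the pending contribution of the branch above `n` is
`z(n) = l(n) * (b - x(n)) * w(n)`.

One step of the published prose is ambiguous: when an edge `(c, p)` is
removed, the root-ward walk is described over the ancestors of `p`, which
never flushes the pending area of the removed branch itself.  Taken
literally this demonstrably loses the branch-above-sample contributions
(on a single 2-sample tree it returns `y = 0` instead of `y = w`).  The
package therefore fixes the update order as a design decision: **flush
`z(c)` into `v(c)` first**, then walk `p` to the root flushing each
ancestor, subtracting `w(c)`, and cascading each ancestor's accumulated
value into `v(c)`; insertion mirrors this with opposite signs.  The final
interval is closed by processing the edge removals at the right-hand end of
the genome.  Correctness is established empirically — the test suite
demands exact oracle equivalence (relative error below `1e-9`, observed at
machine precision) with the materialized `C` on 100 random tree sequences,
and cross-validates against an independent reference implementation of
tree-sequence relatedness.

Samples must be leaves in every local tree; the generalization to internal
samples is rejected loudly as unsupported.

## Randomized PCA

`ts_pca()` computes top-`k` principal components of `B` without forming it:
draw a Gaussian test matrix, orthonormalize `B * Omega`, run `q` power
iterations (default `q = 5`), and take the exact SVD of the small projected
factor.  Every product with `B` is a call to the incremental algorithm, so
the whole decomposition is `O(n)` in memory.  By default 10 oversampled
columns are drawn and truncated after the SVD — the standard accuracy
refinement — while `paper_mode = TRUE` draws exactly `k` columns.  A fixed
`seed` makes the output bit-identical across runs.  `exact_pca()` is the
dense comparator (guarded above `max_n` samples).

Whether one should center before or after collapsing genome copies to
(diploid) individuals is a genuine modelling choice that published accounts
leave unstated; both orders are exposed (`center = "samples"` collapses
`P C P`, `center = "individuals"` centers the collapsed matrix) and both are
tested against dense oracles.

## Synthetic data: what the generators do and do not claim

All study data are generated in-package; the defaults below are the study
conditions used by the test suite and by `scripts/acceptance.R`.

* `simulate_coalescent_ts()` draws the leftmost tree from the Kingman
  coalescent with pairwise rate `1/N_e` and moves rightward with
  prune-and-recoalesce edits at recombination breakpoints — a sequentially
  Markovian (SMC-style) approximation, not an exact coalescent with
  recombination.  This is adequate here because every downstream assertion
  is either an exact identity on whatever tree sequence is produced or a
  marginal-expectation check, neither of which depends on the exactness of
  the recombination process.  Defaults are human-scale: `N_e = 1e4`,
  per-base rates `1e-8`, 100 kb.
* `drop_mutations()` places Poisson(`mu * area`) mutations per edge,
  each founding its own biallelic site; `genotypes_from_mutations()`
  returns the binary descent matrix and `simulate_trait()` the additive
  trait.
* `make_pedigree()` builds a deterministic balanced design: one founder
  couple, `sibship` children per couple, each non-terminal child married to
  a new unrelated founder.  With `generations = 4, sibship = 2` the 16
  probands form 8 sibling, 16 first-, 32 second- and 64 third-cousin pairs
  with kinships 1/4, 1/16, 1/64, 1/256.  The balance is deliberate: every
  proband has an identical marginal relatedness profile, so centering
  shifts `B` uniformly and the regression of `B` on kinship is not
  attenuated by row effects.
* `gene_drop()` pushes two genome copies per individual through the
  pedigree with Poisson(`recomb_rate * L`) crossovers per meiosis, leaving
  founder lineages open; `recapitate()` closes them with a Kingman
  coalescent of size `N_e` run **independently per local tree**.  The
  per-tree marginals are exact, but linkage among founder lineages across
  trees is ignored — a deliberate simplification (stated here loudly) of
  pedigree-aware recapitation.  The pedigree demonstration below only uses
  per-tree marginal expectations, which this preserves.

## The pedigree demonstration

For individuals `i, j` with pedigree relatedness `r_ij` (twice the kinship
on the individual scale; equal to the kinship on the genome-copy-average
scale used here) one expects `B_ij ~ r_ij * T`, where `T` is the mean
pairwise TMRCA.  The package measures `T` with `mean_tmrca()` on the
simulated output rather than deriving it from the demographic model, since
published accounts leave the exact convention open.  The acceptance suite
regresses the across-replicate mean of the individual-collapsed `B`
(per unit genome) on kinship over 100 recapitated gene-drops and requires
the slope to lie within 15% of `T`.

A second claim concerns variability: the replicate-to-replicate spread of
`B_ij` is largest for sibling pairs and decreases with pedigree distance.
The package asserts this on the replicate-wise **standard deviation**, not
the coefficient of variation: because the mean of `B_ij` falls by a factor
of 4 per degree while the spread falls much more slowly, the CV actually
*increases* with distance, and a CV ordering would contradict the intended
"variability is highest for siblings" statement.

## Numerical choices and limitations

* Node ids are 0-based in all files and in the `mrca()` API (matching the
  tabular tree-sequence convention) and 1-based internally.
* MRCA queries use the simple ancestor-chain method, `O(height)` per query;
  constant-time LCA indexing is a possible optimization, not a correctness
  requirement.
* Scaling assertions use instrumented operation counts (nodes touched per
  tree transition), never wall-clock, so they are machine-independent.
  The dense routines are quadratic by construction and guarded in the CLI
  (`grm` refuses more than 5000 samples by default and points to
  `matvec`/`pca`).
* Two textbook-style equalities deserve a caveat: the allele-match
  covariance implemented here is the one consistent with the genotype GRM
  (a variant without the 1/2 factor circulates and differs by a factor of
  2 on 2-by-2 examples and is not implemented); and divergence between
  samples with no common root in some tree is an error, not infinity,
  while shared area for such pairs is 0.
* `trait_covariance_check()` and the duality test are Monte-Carlo
  computations; their tolerances (5 Monte-Carlo standard errors; 5%
  relative Frobenius error over 200 mutation replicates) are part of the
  test suite and are recomputed — not asserted from stored constants — by
  `scripts/acceptance.R`.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
ts <- simulate_coalescent_ts(n_samples = 8, sequence_length = 1e5,
                             N_e = 1e4, recomb_rate = 2e-8, seed = 1)
ts

# three equal routes to B
B <- branch_grm_centered(ts)
max(abs(as.matrix(B) - as.matrix(branch_grm_centered(ts, "divergence"))))

# the same product without materializing anything
w <- rnorm(8)
max(abs(centered_grm_vector_product(ts, w) - as.matrix(B) %*% w))

# randomized PCA
ts_pca(ts, k = 2, q = 5, seed = 42)
```

The chunks above are not evaluated during vignette building to keep
installation light; running them verbatim reproduces the object summaries
shown in the README, and `scripts/acceptance.R` reproduces every headline
number of the package.
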