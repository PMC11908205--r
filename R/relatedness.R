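#' @title Relatedness matrices on tree sequences
#' @description Dense (materialized) relatedness matrices: the divergence
#'   matrix D, the uncentered branch GRM C (total shared ancestral branch
#'   area), the centered branch GRM B, the eGRM, the genotype GRM and the
#'   allele-match covariance, plus the algebraic identities connecting them.
#'   All dense routines are quadratic in the number of samples and are meant
#'   for moderate n; use [branch_grm_vector_product()] and [ts_pca()] at
#'   scale.
#' @name relatedness
NULL

new_relatedness_matrix <- function(values, mode, unit) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(values, mode = mode, unit = unit,
            class = c("relatedness_matrix", class(values)))
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat(sprintf("%d x %d relatedness matrix, mode '%s' (%s)\n",
              nrow(x), ncol(x), attr(x, "mode"), attr(x, "unit")))
  print(as.matrix(x), ...)
  invisible(x)
}

#' @export
as.matrix.relatedness_matrix <- function(x, ...) {
  attr(x, "mode") <- NULL
  attr(x, "unit") <- NULL
  class(x) <- setdiff(class(x), "relatedness_matrix")
  unclass(x)
}

#' Relatedness-matrix mode
#' @param m a `relatedness_matrix`.
#' @return character tag, e.g. `"uncentered_C"` or `"egrm"`.
#' @export
grm_mode <- function(m) attr(m, "mode")

# n x n centering matrix P = I - 11'/n
centering_matrix <- function(n) diag(n) - matrix(1 / n, n, n)

# Per-tree descendant-sample indicator S (nodes x samples) and branch lengths.
# S[n, s] = 1 iff sample s inherits from node n in this tree.
tree_sample_indicator <- function(tree) {
  n_nodes <- length(tree$parent)
  samples <- which(tree$is_sample)
  S <- matrix(0, n_nodes, length(samples))
  S[cbind(samples, seq_along(samples))] <- 1
  attached <- which(tree$parent > 0L)
  for (c_node in attached[order(tree$time[attached])]) {
    p <- tree$parent[c_node]
    S[p, ] <- S[p, ] + S[c_node, ]
  }
  len <- numeric(n_nodes)
  len[attached] <- tree$time[tree$parent[attached]] - tree$time[attached]
  list(S = S, len = len)
}

# Per-tree MRCA-time matrix over samples (NA for pairs in different
# root-subtrees); diagonal is each sample's own time.  Each cross pair is
# assigned exactly once, when the subtrees containing its members merge.
tree_tmrca_matrix <- function(tree) {
  samples <- which(tree$is_sample)
  ns <- length(samples)
  tm <- matrix(NA_real_, ns, ns)
  diag(tm) <- tree$time[samples]
  idx <- integer(length(tree$parent))
  idx[samples] <- seq_len(ns)
  anc <- sample_ancestral(tree)
  ch <- split(which(tree$parent > 0L & anc),
              tree$parent[tree$parent > 0L & anc])
  desc <- vector("list", length(tree$parent))
  for (s in samples) desc[[s]] <- idx[s]
  nodes <- which(anc)
  for (n in nodes[order(tree$time[nodes])]) {
    kids <- ch[[as.character(n)]]
    if (is.null(kids)) next
    groups <- desc[kids]
    groups <- groups[!vapply(groups, is.null, logical(1L))]
    if (tree$is_sample[n]) groups <- c(groups, list(idx[n]))
    if (length(groups) > 1L) {
      for (a in seq_len(length(groups) - 1L)) {
        for (b in seq(a + 1L, length(groups))) {
          tm[groups[[a]], groups[[b]]] <- tree$time[n]
          tm[groups[[b]], groups[[a]]] <- tree$time[n]
        }
      }
    }
    desc[[n]] <- unlist(groups, use.names = FALSE)
  }
  tm
}

#' Branch genetic divergence matrix
#'
#' `D[i, j]` is the span-weighted total path length between samples i and j
#' through their MRCA in each local tree: per tree,
#' `s_k * (2 t_mrca - t_i - t_j)`.  Requires every sample pair to share a root
#' in every tree.
#'
#' @param ts a `tree_sequence`.
#' @return A `relatedness_matrix` of mode `divergence_D` with zero diagonal.
#' @export
divergence_matrix <- function(ts) {
  samples <- sample_nodes(ts)
  ns <- length(samples)
  if (ns < 1L) stop("tree sequence has no samples")
  st <- ts$nodes$time[samples]
  D <- matrix(0, ns, ns)
  for (tree in local_trees(ts)) {
    tm <- tree_tmrca_matrix(tree)
    if (anyNA(tm)) {
      stop(sprintf(
        "sample pair with no common root in tree on [%g, %g): divergence undefined",
        tree$interval[1L], tree$interval[2L]))
    }
    D <- D + tree$span * (2 * tm - outer(st, rep(1, ns)) -
                            outer(rep(1, ns), st))
  }
  diag(D) <- 0
  new_relatedness_matrix(D, "divergence_D", "generations x span")
}

#' Uncentered branch GRM
#'
#' `C[s, t]` is the total area (branch length times genome span) of branches
#' ancestral to both samples s and t, summed over local trees.  Samples in
#' different root-subtrees share no area and get 0.
#'
#' @param ts a `tree_sequence`.
#' @return A positive semi-definite `relatedness_matrix` of mode
#'   `uncentered_C`.
#' @export
branch_grm_uncentered <- function(ts) {
  ns <- n_samples(ts)
  if (ns < 1L) stop("tree sequence has no samples")
  C <- matrix(0, ns, ns)
  for (tree in local_trees(ts)) {
    si <- tree_sample_indicator(tree)
    C <- C + tree$span * crossprod(si$S, si$len * si$S)
  }
  new_relatedness_matrix(C, "uncentered_C", "generations x span")
}

#' Centered branch GRM
#'
#' The branch relatedness matrix B: the covariance of a centered additive
#' trait whose mutations fall as a Poisson process on branch area.  With the
#' centering matrix `P = I - 11'/n`, `B = P C P`, and equivalently
#' `B = -P D P / 2` (centering over uniform-with-replacement random samples U,
#' V).  A third route recomputes B from per-tree MRCA times,
#' `B = -sum_k s_k P T_k P` (all samples at time 0), and is exposed for
#' cross-validation.
#'
#' @param ts a `tree_sequence`.
#' @param method `"area"` (via C), `"divergence"` (via D) or `"tmrca"` (via
#'   per-tree MRCA times); all agree to numerical precision.
#' @return A `relatedness_matrix` of mode `centered_B` with zero row sums.
#' @export
branch_grm_centered <- function(ts, method = c("area", "divergence", "tmrca")) {
  method <- match.arg(method)
  ns <- n_samples(ts)
  P <- centering_matrix(ns)
  B <- switch(
    method,
    area = P %*% as.matrix(branch_grm_uncentered(ts)) %*% P,
    divergence = -P %*% as.matrix(divergence_matrix(ts)) %*% P / 2,
    tmrca = {
      acc <- matrix(0, ns, ns)
      for (tree in local_trees(ts)) {
        tm <- tree_tmrca_matrix(tree)
        if (anyNA(tm)) {
          stop(sprintf(
            "sample pair with no common root in tree on [%g, %g)",
            tree$interval[1L], tree$interval[2L]))
        }
        acc <- acc - tree$span * (P %*% tm %*% P)
      }
      acc
    })
  B <- (B + t(B)) / 2
  new_relatedness_matrix(B, "centered_B", "generations x span")
}

#' eGRM: frequency-normalized branch GRM
#'
#' Per edge e in tree k with descendant-sample proportion `Sbar`, the centered
#' indicator outer product is weighted by `b_e / (Sbar (1 - Sbar))`, summed
#' with spans and divided by the total branch area.  Edges with `Sbar` 0 or 1
#' carry no variance and are skipped; this is the branch analogue of the
#' `2p(1-p)` genotype standardization.
#'
#' @param ts a `tree_sequence`.
#' @return A `relatedness_matrix` of mode `egrm` (dimensionless) with zero row
#'   sums.
#' @export
egrm <- function(ts) {
  ns <- n_samples(ts)
  if (ns < 1L) stop("tree sequence has no samples")
  E <- matrix(0, ns, ns)
  area <- 0
  for (tree in local_trees(ts)) {
    si <- tree_sample_indicator(tree)
    nd <- rowSums(si$S)
    keep_area <- si$len > 0 & nd > 0
    area <- area + tree$span * sum(si$len[keep_area])
    sbar <- nd / ns
    keep <- keep_area & sbar < 1
    if (any(keep)) {
      Sc <- si$S[keep, , drop = FALSE] - sbar[keep]
      wts <- si$len[keep] / (sbar[keep] * (1 - sbar[keep]))
      E <- E + tree$span * crossprod(Sc, wts * Sc)
    }
  }
  if (area == 0) stop("total branch area is zero; eGRM undefined")
  new_relatedness_matrix(E / area, "egrm", "dimensionless")
}

#' Genotype GRM
#'
#' The kernel of most genotype-based GRMs: with the column-centered dosage
#' matrix `Gc` (entries minus the column mean over samples),
#' `C = Gc Gc' / n_loci`.  Entries of `G` are in `[0, 1]`: haploid 0/1 alleles,
#' or diploid dosages as the *proportion* of non-ancestral alleles.  Fixed
#' columns contribute nothing.
#'
#' @param G numeric matrix, samples in rows, loci in columns.
#' @return A `relatedness_matrix` of mode `genotype`.
#' @export
genotype_grm <- function(G) {
  G <- as.matrix(G)
  if (length(G) == 0L || ncol(G) < 1L) stop("genotype matrix is empty")
  if (any(G < 0 | G > 1)) stop("genotype entries must lie in [0, 1]")
  Gc <- sweep(G, 2L, colMeans(G))
  new_relatedness_matrix(tcrossprod(Gc) / ncol(G), "genotype", "dimensionless")
}

#' Allele-match covariance
#'
#' Defines relatedness through match probabilities: with a uniformly random
#' locus and individuals U, V drawn uniformly with replacement,
#' `C[i, j] = (P(Xi = Xj) - P(Xi = XU) - P(Xj = XV) + P(XU = XV)) / 2`.
#' For binary genotypes this equals [genotype_grm()] exactly, but the form
#' extends directly to multi-allelic data.
#'
#' @param G binary (0/1) genotype matrix, samples in rows.
#' @return A `relatedness_matrix` of mode `match_cov`.
#' @export
match_covariance <- function(G) {
  G <- as.matrix(G)
  if (length(G) == 0L || ncol(G) < 1L) stop("genotype matrix is empty")
  if (!all(G %in% c(0, 1))) stop("match_covariance requires binary entries")
  M <- (tcrossprod(G) + tcrossprod(1 - G)) / ncol(G)
  P <- centering_matrix(nrow(G))
  C <- P %*% M %*% P / 2
  new_relatedness_matrix((C + t(C)) / 2, "match_cov", "dimensionless")
}

#' Collapse a per-genome-copy matrix to individuals
#'
#' Entry (a, b) of the result is the mean of `M` over sample pairs (s in a,
#' t in b).  For diploids this equals the haploid 2x2 block sum divided by 4,
#' the usual dosage aggregation.
#'
#' @param m a `relatedness_matrix` (or plain matrix) over samples.
#' @param groups vector of individual labels, one per sample (row of `m`).
#' @return A `relatedness_matrix` over individuals, in `groups` label order of
#'   first appearance.
#' @export
collapse_to_individuals <- function(m, groups) {
  vals <- as.matrix(m)
  if (length(groups) != nrow(vals)) {
    stop("groups must have one entry per sample")
  }
  f <- factor(groups, levels = unique(groups))
  if (any(table(f) == 0L)) stop("empty individual group")
  H <- stats::model.matrix(~ f - 1)
  H <- sweep(H, 2L, colSums(H), "/")
  out <- crossprod(H, vals %*% H)
  dimnames(out) <- list(levels(f), levels(f))
  new_relatedness_matrix(out, attr(m, "mode") %||% "collapsed",
                         attr(m, "unit") %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Empirical trait covariance against its closed form
#'
#' Draws `n_reps` independent sets of additive effects (and, in branch mode,
#' fresh Poisson mutation placements) and returns the empirical covariance of
#' the sample-centered genetic values.  In site mode (mutations fixed) this
#' converges to `sigma2 * n_loci * C` with C the genotype GRM of the realized
#' genotypes; in branch mode it converges to `sigma2 * mu * B` with B the
#' centered branch GRM.
#'
#' @param ts a `tree_sequence`; must carry mutations in site mode.
#' @param sigma2 per-mutation effect variance.
#' @param n_reps number of independent replicates (>= 2).
#' @param seed RNG seed.
#' @param mode `"site"` or `"branch"`.
#' @param mu mutation rate per unit area (branch mode only).
#' @return Empirical covariance matrix with attribute `n_reps`.
#' @export
trait_covariance_check <- function(ts, sigma2 = 1, n_reps = 1000L, seed = 1L,
                                   mode = c("site", "branch"), mu = 1) {
  mode <- match.arg(mode)
  if (n_reps < 2L) stop("n_reps must be at least 2")
  ns <- n_samples(ts)
  with_seed(seed, {
    if (mode == "site") {
      if (is.null(ts$sites) || nrow(ts$sites) == 0L) {
        stop("site mode requires mutations on the tree sequence")
      }
      G <- genotypes_from_mutations(ts)
      if (sigma2 == 0) {
        acc <- matrix(0, ns, ns)
      } else {
        eff <- matrix(stats::rnorm(ncol(G) * n_reps, sd = sqrt(sigma2)),
                      ncol(G), n_reps)
        Z <- G %*% eff
        Zc <- sweep(Z, 2L, colMeans(Z))
        acc <- tcrossprod(Zc)
      }
    } else {
      acc <- matrix(0, ns, ns)
      for (r in seq_len(n_reps)) {
        tsm <- drop_mutations(ts, mu,
                              seed = stats::runif(1L, 0, .Machine$integer.max))
        if (is.null(tsm$sites) || nrow(tsm$sites) == 0L || sigma2 == 0) next
        G <- genotypes_from_mutations(tsm)
        z <- G %*% stats::rnorm(ncol(G), sd = sqrt(sigma2))
        zc <- z - mean(z)
        acc <- acc + tcrossprod(zc)
      }
    }
    out <- acc / n_reps
    attr(out, "n_reps") <- n_reps
    out
  })
}
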