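#' Randomized PCA of the branch GRM
#'
#' Principal components of the centered branch GRM B, computed without ever
#' materializing B.  Range estimation: draw a Gaussian test matrix Omega,
#' set `Q = qr(B Omega)`, then perform `q` power iterations `Q = qr(B Q)`.
#' Small factorization: `W = Q' B` (computed as `(B Q)'` since B is
#' symmetric), take the exact SVD of the small factor W; the components are
#' `Q U` truncated to `k` columns and the eigenvalues of B are the
#' corresponding singular values of W.  Every product with B is one call to
#' [centered_grm_vector_product()] per column.
#'
#' By default `oversample = 10` extra Gaussian columns are drawn and truncated
#' after the SVD, the standard accuracy refinement; `paper_mode = TRUE` uses
#' exactly `k` columns.
#'
#' @param ts a `tree_sequence` (samples must be leaves).
#' @param k number of principal components requested.
#' @param q number of power iterations (default 5).
#' @param seed RNG seed governing the Gaussian draw; fixed seed gives
#'   bit-identical results.
#' @param oversample extra random columns beyond `k` (ignored in paper mode).
#' @param paper_mode draw exactly `k` Gaussian columns, no oversampling.
#' @param groups optional per-sample individual labels; if given, PCA is done
#'   on the individual-collapsed GRM (see [pca_individuals()]).
#' @param center one of `"samples"`, `"individuals"`: whether centering is
#'   applied before or after collapsing genome copies to individuals (only
#'   relevant with `groups`).
#' @return An object of class `ts_pca` with fields `components` (n x k,
#'   orthonormal columns), `eigenvalues` (non-increasing, length k), `k`, `q`,
#'   `seed`, `method`.
#' @examples
#' ts <- tree_sequence(
#'   nodes = data.frame(time = c(0, 0, 1), is_sample = c(TRUE, TRUE, FALSE)),
#'   edges = data.frame(left = 0, right = 1, parent = 2, child = 0:1),
#'   sequence_length = 1
#' )
#' ts_pca(ts, k = 1, q = 2, seed = 1)
#' @export
ts_pca <- function(ts, k, q = 5L, seed = 1L, oversample = 10L,
                   paper_mode = FALSE, groups = NULL,
                   center = c("samples", "individuals")) {
  center <- match.arg(center)
  op <- grm_operator(ts, groups, center)
  n <- op$n
  if (k < 1L) stop("k must be at least 1")
  p <- if (paper_mode) k else k + oversample
  p <- min(p, n)
  if (k > n) stop("k exceeds the matrix dimension")
  with_seed(seed, {
    omega <- matrix(stats::rnorm(n * p), n, p)
    Y <- op$multiply(omega)
    Q <- qr.Q(qr(Y))
    for (i in seq_len(q)) {
      Q <- qr.Q(qr(op$multiply(Q)))
    }
    W <- t(op$multiply(Q))      # W = Q' B, p x n
    sv <- svd(W)
    comp <- Q %*% sv$u[, seq_len(k), drop = FALSE]
    structure(
      list(components = comp, eigenvalues = sv$d[seq_len(k)],
           k = as.integer(k), q = as.integer(q), seed = seed,
           method = if (paper_mode) "rpca" else
             sprintf("rpca+%d oversampling", p - k)),
      class = "ts_pca")
  })
}

# matrix-free operator for B, optionally collapsed to individuals.
# multiply() maps an n x m matrix column-wise through the operator.
grm_operator <- function(ts, groups = NULL, center = "samples") {
  ns <- n_samples(ts)
  if (is.null(groups)) {
    matvec1 <- function(w) centered_grm_vector_product(ts, w)
    n <- ns
  } else {
    if (length(groups) != ns) stop("groups must have one entry per sample")
    f <- factor(groups, levels = unique(groups))
    size <- as.numeric(table(f))
    idx <- as.integer(f)
    n <- nlevels(f)
    expand <- function(wi) wi[idx] / size[idx]      # H w
    reduce <- function(y) {                         # H' y
      as.numeric(rowsum(y / size[idx], idx, reorder = TRUE))
    }
    if (center == "samples") {
      # H' P C P H: center over genome copies, then collapse
      matvec1 <- function(wi) reduce(centered_grm_vector_product(ts, expand(wi)))
    } else {
      # P_I H' C H P_I: collapse, then center over individuals
      matvec1 <- function(wi) {
        y <- reduce(branch_grm_vector_product(ts, expand(wi - mean(wi))))
        y - mean(y)
      }
    }
  }
  list(n = n,
       multiply = function(X) {
         X <- as.matrix(X)
         out <- matrix(0, n, ncol(X))
         for (i in seq_len(ncol(X))) out[, i] <- matvec1(X[, i])
         out
       })
}

#' Exact PCA of the branch GRM
#'
#' Materializes the centered branch GRM (quadratic in n; guarded) and takes a
#' dense symmetric eigendecomposition.  The reference comparator for
#' [ts_pca()].
#'
#' @inheritParams ts_pca
#' @param max_n refuse to materialize above this many samples/individuals.
#' @return A `ts_pca` object with `method = "exact"`.
#' @export
exact_pca <- function(ts, k, groups = NULL, center = c("samples", "individuals"),
                      max_n = 5000L) {
  center <- match.arg(center)
  B <- as.matrix(branch_grm_centered(ts))
  if (!is.null(groups)) {
    if (center == "samples") {
      B <- as.matrix(collapse_to_individuals(B, groups))
    } else {
      C <- as.matrix(collapse_to_individuals(branch_grm_uncentered(ts), groups))
      P <- centering_matrix(nrow(C))
      B <- P %*% C %*% P
    }
  }
  n <- nrow(B)
  if (n > max_n) stop("n exceeds max_n; use ts_pca() for large samples")
  if (k > n) stop("k exceeds the matrix dimension")
  e <- eigen(B, symmetric = TRUE)
  structure(
    list(components = e$vectors[, seq_len(k), drop = FALSE],
         eigenvalues = e$values[seq_len(k)],
         k = as.integer(k), q = NA_integer_, seed = NA_integer_,
         method = "exact"),
    class = "ts_pca")
}

#' Randomized PCA on the individual scale
#'
#' Convenience wrapper for [ts_pca()] with `groups`: PCA of the
#' individual-collapsed centered branch GRM, still matrix-free (the averaging
#' operators are applied around the branch-GRM-vector product).
#'
#' @inheritParams ts_pca
#' @return A `ts_pca` object over individuals.
#' @export
pca_individuals <- function(ts, groups, k, q = 5L, seed = 1L,
                            center = c("samples", "individuals"), ...) {
  center <- match.arg(center)
  ts_pca(ts, k = k, q = q, seed = seed, groups = groups, center = center, ...)
}

#' @export
print.ts_pca <- function(x, ...) {
  cat(sprintf("Branch-GRM PCA (%s): %d components over %d units\n",
              x$method, x$k, nrow(x$components)))
  cat("eigenvalues:", format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.ts_pca <- function(object, ...) {
  print(object)
  tot <- sum(object$eigenvalues)
  if (tot > 0) {
    cat("proportion of captured variance per component:\n")
    print(round(object$eigenvalues / tot, 4))
  }
  invisible(object)
}
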