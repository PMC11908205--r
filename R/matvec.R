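#' Branch-GRM-vector product without materializing the matrix
#'
#' Computes `y = C w`, where C is the uncentered branch GRM (total shared
#' ancestral branch area between sample pairs), by a single left-to-right
#' sweep over the edge table.  The algorithm keeps, per node n, a lazy subtree
#' weight `w(n)` (sum of input weights over samples below n in the current
#' tree), an accumulated haplotype value `v(n)`, and the genome position
#' `x(n)` of its last update.  The pending, not-yet-propagated area
#' contribution of the branch above n is `z(n) = l(n) * (b - x(n))`.
#'
#' On removing edge (c, p) at breakpoint b, the pending contribution of the
#' removed branch itself is flushed into `v(c)`, then the walk from p to the
#' root flushes each ancestor, subtracts `w(c)` from its weight, and cascades
#' its accumulated value down into `v(c)`.  Insertion mirrors this with signs
#' reversed, so that a node only ever pays for contributions accrued while it
#' was attached.  After the final breakpoint every remaining edge is removed,
#' which flushes all pending area; the answer is read off the sample values.
#'
#' Work per tree transition is proportional to the depth of the affected
#' nodes — O(log n) for balanced trees — giving O(n + t log n) overall with
#' O(n) additional memory; no n x n object is ever allocated.
#'
#' @param ts a `tree_sequence` whose samples are leaves in every local tree.
#' @param w numeric weight vector, one entry per sample (node-id order).
#' @param instrument if `TRUE`, also return per-breakpoint operation counts.
#' @return The product vector `y` (length n_samples); with
#'   `instrument = TRUE`, a list with elements `y` and `counters`, where
#'   `counters` is a data.frame with one row per breakpoint (position, number
#'   of edges processed, nodes touched on root-ward walks).
#' @seealso [centered_grm_vector_product()], [quadratic_form()], [ts_pca()]
#' @examples
#' ts <- tree_sequence(
#'   nodes = data.frame(time = c(0, 0, 1), is_sample = c(TRUE, TRUE, FALSE)),
#'   edges = data.frame(left = 0, right = 1, parent = 2, child = 0:1),
#'   sequence_length = 1
#' )
#' branch_grm_vector_product(ts, c(1, 0))  # first column of C = identity
#' @export
branch_grm_vector_product <- function(ts, w, instrument = FALSE) {
  samples <- sample_nodes(ts)
  ns <- length(samples)
  if (length(w) != ns) stop("weight vector length must equal sample count")
  if (ns == 0L) stop("tree sequence has no samples")
  if (any(ts$nodes$is_sample[ts$edges$parent])) {
    stop("unsupported input: samples must be leaves in all trees")
  }
  n_nodes <- nrow(ts$nodes)
  time <- ts$nodes$time
  ed <- ts$edges
  M <- nrow(ed)
  ins <- edge_insertion_order(ts)
  rem <- edge_removal_order(ts)

  parent <- integer(n_nodes)
  wt <- numeric(n_nodes)
  wt[samples] <- w
  v <- numeric(n_nodes)
  x <- numeric(n_nodes)

  bp_pos <- numeric(0)
  bp_edges <- integer(0)
  bp_touched <- integer(0)

  # flush pending area of the branch above `n` into its value, using the
  # weight in force since x(n)
  flush <- function(n, b) {
    p <- parent[n]
    if (p != 0L) {
      v[n] <<- v[n] + (time[p] - time[n]) * (b - x[n]) * wt[n]
    }
    x[n] <<- b
  }

  j <- 1L; k <- 1L
  while (k <= M) {
    b <- if (j <= M) min(ed$right[rem[k]], ed$left[ins[j]]) else ed$right[rem[k]]
    n_edges <- 0L
    n_touch <- 0L
    while (k <= M && ed$right[rem[k]] == b) {
      e <- rem[k]
      cn <- ed$child[e]; p <- ed$parent[e]
      wc <- wt[cn]
      flush(cn, b)
      n <- p
      while (n != 0L) {
        flush(n, b)
        wt[n] <- wt[n] - wc
        v[cn] <- v[cn] + v[n]
        n_touch <- n_touch + 1L
        n <- parent[n]
      }
      parent[cn] <- 0L
      n_edges <- n_edges + 1L
      k <- k + 1L
    }
    while (j <= M && ed$left[ins[j]] == b) {
      e <- ins[j]
      cn <- ed$child[e]; p <- ed$parent[e]
      wc <- wt[cn]
      x[cn] <- b
      n <- p
      while (n != 0L) {
        flush(n, b)
        wt[n] <- wt[n] + wc
        v[cn] <- v[cn] - v[n]
        n_touch <- n_touch + 1L
        n <- parent[n]
      }
      parent[cn] <- p
      n_edges <- n_edges + 1L
      j <- j + 1L
    }
    if (instrument) {
      bp_pos <- c(bp_pos, b)
      bp_edges <- c(bp_edges, n_edges)
      bp_touched <- c(bp_touched, n_touch)
    }
  }
  y <- v[samples]
  if (instrument) {
    list(y = y, counters = data.frame(position = bp_pos, edges = bp_edges,
                                      nodes_touched = bp_touched))
  } else {
    y
  }
}

#' Centered branch-GRM-vector product
#'
#' Computes `B w = P C (P w)` with `P = I - 11'/n` applied as subtraction of
#' the mean, using a single uncentered product.
#'
#' @inheritParams branch_grm_vector_product
#' @return numeric vector `B w`.
#' @export
centered_grm_vector_product <- function(ts, w) {
  y <- branch_grm_vector_product(ts, w - mean(w))
  y - mean(y)
}

#' Quadratic form with the branch GRM
#'
#' `u' C w` (or `u' B w` with `centered = TRUE`) via one matrix-free product
#' and a dot product.
#'
#' @inheritParams branch_grm_vector_product
#' @param u,w numeric vectors over samples.
#' @param centered use the centered GRM B instead of C.
#' @return a single number.
#' @export
quadratic_form <- function(ts, u, w, centered = FALSE) {
  if (length(u) != n_samples(ts)) stop("weight vector length must equal sample count")
  y <- if (centered) centered_grm_vector_product(ts, w)
  else branch_grm_vector_product(ts, w)
  sum(u * y)
}

#' Instrumented branch-GRM-vector product
#'
#' Same result as [branch_grm_vector_product()], plus operation counters
#' recording the root-ward path lengths traversed at each breakpoint.  The
#' mean nodes-touched per tree transition (excluding the initial edge
#' insertions that build the first tree) is the machine-independent measure of
#' the O(log n) per-transition cost.
#'
#' @inheritParams branch_grm_vector_product
#' @return list with `y`, `counters` (per-breakpoint data.frame) and
#'   `mean_nodes_per_transition`.
#' @export
instrument_matvec <- function(ts, w) {
  res <- branch_grm_vector_product(ts, w, instrument = TRUE)
  ctr <- res$counters
  # first row builds tree 1, last row tears everything down; transitions are
  # the interior breakpoints
  trans <- ctr[-c(1L, nrow(ctr)), , drop = FALSE]
  list(y = res$y, counters = ctr,
       mean_nodes_per_transition = if (nrow(trans) > 0L)
         mean(trans$nodes_touched) else NA_real_)
}
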