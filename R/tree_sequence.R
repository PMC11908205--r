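#' Construct a succinct tree sequence
#'
#' A tree sequence encodes an ancestral recombination graph (ARG) as a node
#' table and an edge table.  Each node is a (haploid) genome with a birth time
#' in generations; each edge records that a `child` node inherited the genome
#' interval `[left, right)` from a `parent` node.  Sweeping edge insertions and
#' removals along the genome recovers the sequence of local trees, one per
#' recombination-free interval.
#'
#' Node ids in the tables are 0-based (the convention of the tabular
#' tree-sequence format); internally nodes are addressed 1-based in table row
#' order.  Coordinates are half-open `[left, right)` on `[0, sequence_length]`.
#'
#' @param nodes data.frame with columns `time` (>= 0, generations),
#'   `is_sample` (logical or 0/1) and optionally `individual` (0-based
#'   individual index, -1 or NA for none).
#' @param edges data.frame with columns `left`, `right` (genome coordinates)
#'   and `parent`, `child` (0-based node ids).
#' @param sequence_length positive total genome length.
#' @param sites optional data.frame with column `position`.
#' @param mutations optional data.frame with columns `site` (0-based row index
#'   into `sites`) and `node` (0-based node id carrying the derived allele).
#' @return An object of class `tree_sequence`.
#' @examples
#' ts <- tree_sequence(
#'   nodes = data.frame(time = c(0, 0, 1), is_sample = c(TRUE, TRUE, FALSE)),
#'   edges = data.frame(left = 0, right = 1, parent = 2, child = 0:1),
#'   sequence_length = 1
#' )
#' ts
#' @export
tree_sequence <- function(nodes, edges, sequence_length,
                          sites = NULL, mutations = NULL) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!is.numeric(sequence_length) || length(sequence_length) != 1L ||
      !is.finite(sequence_length) || sequence_length <= 0) {
    stop("sequence_length must be a single positive number")
  }
  nodes <- data.frame(
    time = as.numeric(nodes$time),
    is_sample = as.logical(nodes$is_sample),
    individual = if (!is.null(nodes$individual)) {
      ind <- as.integer(nodes$individual)
      ind[!is.na(ind) & ind < 0L] <- NA_integer_
      ind
    } else rep(NA_integer_, nrow(nodes))
  )
  if (nrow(edges) > 0L) {
    edges <- data.frame(
      left = as.numeric(edges$left),
      right = as.numeric(edges$right),
      parent = as.integer(edges$parent) + 1L,
      child = as.integer(edges$child) + 1L
    )
  } else {
    edges <- data.frame(left = numeric(0), right = numeric(0),
                        parent = integer(0), child = integer(0))
  }
  if (!is.null(sites)) {
    sites <- data.frame(position = as.numeric(sites$position))
  }
  if (!is.null(mutations)) {
    mutations <- data.frame(site = as.integer(mutations$site) + 1L,
                            node = as.integer(mutations$node) + 1L)
  }
  ts <- structure(
    list(sequence_length = sequence_length, nodes = nodes, edges = edges,
         sites = sites, mutations = mutations),
    class = "tree_sequence"
  )
  validate_tree_sequence(ts)
  ts
}

#' Validate the invariants of a tree sequence
#'
#' Checks node times, edge interval bounds and orientation, the
#' parent-older-than-child requirement, and per-child interval disjointness
#' (which, together with time ordering, guarantees that each genome interval
#' carries a forest).  Errors identify the offending table row (0-based, as in
#' the files).
#'
#' @param ts a `tree_sequence`.
#' @return `ts`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_tree_sequence <- function(ts) {
  nd <- ts$nodes
  ed <- ts$edges
  L <- ts$sequence_length
  if (nrow(nd) == 0L) stop("node table is empty")
  bad <- which(!is.finite(nd$time) | nd$time < 0)
  if (length(bad) > 0L) {
    stop(sprintf("node row %d: time must be finite and >= 0", bad[1L] - 1L))
  }
  n_nodes <- nrow(nd)
  if (nrow(ed) > 0L) {
    bad <- which(ed$parent < 1L | ed$parent > n_nodes |
                   ed$child < 1L | ed$child > n_nodes)
    if (length(bad) > 0L) {
      stop(sprintf("edge row %d: node id out of range", bad[1L] - 1L))
    }
    bad <- which(!(ed$left < ed$right) | ed$left < 0 | ed$right > L)
    if (length(bad) > 0L) {
      stop(sprintf(
        "edge row %d: must have 0 <= left < right <= sequence_length",
        bad[1L] - 1L))
    }
    bad <- which(nd$time[ed$parent] <= nd$time[ed$child])
    if (length(bad) > 0L) {
      stop(sprintf("edge row %d: time(parent) must exceed time(child)",
                   bad[1L] - 1L))
    }
    # per-child disjoint intervals: a position has at most one parent
    o <- order(ed$child, ed$left)
    same_child <- ed$child[o][-1L] == ed$child[o][-length(o)]
    overlap <- ed$left[o][-1L] < ed$right[o][-length(o)]
    bad <- which(same_child & overlap)
    if (length(bad) > 0L) {
      stop(sprintf(
        "edge row %d: overlapping intervals for child %d (one parent per position)",
        o[bad[1L] + 1L] - 1L, ed$child[o[bad[1L] + 1L]] - 1L))
    }
  }
  if (!is.null(ts$mutations) && nrow(ts$mutations) > 0L) {
    if (is.null(ts$sites)) stop("mutations present without a site table")
    bad <- which(ts$mutations$site < 1L | ts$mutations$site > nrow(ts$sites) |
                   ts$mutations$node < 1L | ts$mutations$node > n_nodes)
    if (length(bad) > 0L) {
      stop(sprintf("mutation row %d: site or node out of range", bad[1L] - 1L))
    }
  }
  if (!is.null(ts$sites) && nrow(ts$sites) > 0L) {
    bad <- which(ts$sites$position < 0 | ts$sites$position >= L)
    if (length(bad) > 0L) {
      stop(sprintf("site row %d: position outside [0, sequence_length)",
                   bad[1L] - 1L))
    }
  }
  invisible(ts)
}

#' @export
print.tree_sequence <- function(x, ...) {
  cat(sprintf(
    "Tree sequence: %d nodes (%d samples), %d edges, %d trees, length %g\n",
    nrow(x$nodes), sum(x$nodes$is_sample), nrow(x$edges),
    num_trees(x), x$sequence_length))
  if (!is.null(x$sites)) cat(sprintf("  %d sites, %d mutations\n",
                                     nrow(x$sites),
                                     if (is.null(x$mutations)) 0L else nrow(x$mutations)))
  invisible(x)
}

#' @export
summary.tree_sequence <- function(object, ...) {
  lt <- local_trees(object)
  cat(sprintf("Tree sequence of length %g with %d local trees\n",
              object$sequence_length, length(lt)))
  cat(sprintf("  nodes: %d (%d samples), edges: %d\n",
              nrow(object$nodes), sum(object$nodes$is_sample),
              nrow(object$edges)))
  cat(sprintf("  total branch area (sample-ancestral): %g\n",
              total_area(object)))
  invisible(object)
}

# 1-based node ids of sample nodes, in node-table order
sample_nodes <- function(ts) which(ts$nodes$is_sample)

n_samples <- function(ts) sum(ts$nodes$is_sample)

# edge processing orders of the genome sweep: insertions by
# (left, parent time ascending), removals by (right, parent time descending),
# so parents are valid before children attach and subtrees detach top-down.
edge_insertion_order <- function(ts) {
  with(ts$edges, order(left, ts$nodes$time[parent], parent, child))
}

edge_removal_order <- function(ts) {
  with(ts$edges, order(right, -ts$nodes$time[parent], parent, child))
}

#' Number of local trees
#' @param ts a `tree_sequence`.
#' @return integer count of distinct genome intervals.
#' @export
num_trees <- function(ts) {
  if (nrow(ts$edges) == 0L) return(1L)
  bp <- sort(unique(c(0, ts$sequence_length, ts$edges$left, ts$edges$right)))
  length(bp) - 1L
}

#' Extract the sequence of local trees
#'
#' Sweeps the edge table left-to-right, applying removals before insertions at
#' each breakpoint, and returns one `local_tree` per genome interval together
#' with the edge ids removed (`R_k`) and added (`A_k`) at its left breakpoint.
#'
#' @param ts a `tree_sequence`.
#' @return A list of `local_tree` objects.  Each has fields `interval`
#'   (c(left, right)), `span`, `parent` (1-based parent id per node, 0 = none),
#'   `removed` and `added` (edge table row indices), and carries the node times
#'   and sample flags needed for downstream traversal.
#' @export
local_trees <- function(ts) {
  n_nodes <- nrow(ts$nodes)
  time <- ts$nodes$time
  ed <- ts$edges
  M <- nrow(ed)
  ins <- edge_insertion_order(ts)
  rem <- edge_removal_order(ts)
  par <- integer(n_nodes)
  out <- list()
  j <- 1L; k <- 1L
  pos <- 0
  repeat {
    removed <- integer(0)
    while (k <= M && ed$right[rem[k]] == pos) {
      e <- rem[k]
      par[ed$child[e]] <- 0L
      removed <- c(removed, e)
      k <- k + 1L
    }
    added <- integer(0)
    while (j <= M && ed$left[ins[j]] == pos) {
      e <- ins[j]
      if (par[ed$child[e]] != 0L) {
        stop("internal consistency error: child gains second parent mid-sweep")
      }
      par[ed$child[e]] <- ed$parent[e]
      added <- c(added, e)
      j <- j + 1L
    }
    nxt <- ts$sequence_length
    if (j <= M) nxt <- min(nxt, ed$left[ins[j]])
    if (k <= M) nxt <- min(nxt, ed$right[rem[k]])
    out[[length(out) + 1L]] <- structure(
      list(interval = c(pos, nxt), span = nxt - pos, parent = par,
           removed = removed, added = added,
           time = time, is_sample = ts$nodes$is_sample),
      class = "local_tree")
    pos <- nxt
    if (pos >= ts$sequence_length) break
  }
  out
}

#' @export
print.local_tree <- function(x, ...) {
  cat(sprintf("Local tree on [%g, %g), %d attached nodes\n",
              x$interval[1L], x$interval[2L], sum(x$parent > 0L)))
  invisible(x)
}

#' Most recent common ancestor of two nodes in a local tree
#'
#' Uses the simple ancestor-chain method: climb from `u` recording ancestors,
#' then climb from `v` until the chain is hit.  Node ids are 0-based as in the
#' tables.
#'
#' @param tree a `local_tree` from [local_trees()].
#' @param u,v 0-based node ids.
#' @return The 0-based id of the MRCA, or `NA` when `u` and `v` lie in
#'   different root-subtrees of the interval's forest.
#' @export
mrca <- function(tree, u, v) {
  n <- length(tree$parent)
  u <- as.integer(u) + 1L
  v <- as.integer(v) + 1L
  if (is.na(u) || is.na(v) || u < 1L || u > n || v < 1L || v > n) {
    stop("unknown node id")
  }
  anc <- logical(n)
  w <- u
  while (w != 0L) {
    anc[w] <- TRUE
    w <- tree$parent[w]
  }
  w <- v
  while (w != 0L) {
    if (anc[w]) return(w - 1L)
    w <- tree$parent[w]
  }
  NA_integer_
}

# logical vector: node is ancestral to (or is) at least one sample, per tree
sample_ancestral <- function(tree) {
  n <- length(tree$parent)
  anc <- logical(n)
  for (s in which(tree$is_sample)) {
    w <- s
    while (w != 0L && !anc[w]) {
      anc[w] <- TRUE
      w <- tree$parent[w]
    }
  }
  anc
}

#' Total branch area of a tree sequence
#'
#' The area of a branch is its length (generations) times its genome span.
#' Only branches ancestral to at least one sample are counted; this is the
#' normalizing constant of the eGRM.
#'
#' @param ts a `tree_sequence`.
#' @return Total area, in generations times genome-length units.
#' @export
total_area <- function(ts) {
  if (n_samples(ts) == 0L) stop("tree sequence has no samples")
  area <- 0
  for (tree in local_trees(ts)) {
    anc <- sample_ancestral(tree)
    has_par <- tree$parent > 0L & anc
    if (any(has_par)) {
      len <- tree$time[tree$parent[has_par]] - tree$time[has_par]
      area <- area + tree$span * sum(len)
    }
  }
  area
}

#' Remap genome coordinates through a genetic map
#'
#' Applies piecewise-linear interpolation (physical -> genetic position) to all
#' edge endpoints and site positions, e.g. to convert base pairs to genetic
#' distance before relatedness computations.  Node times are unchanged.
#'
#' @param ts a `tree_sequence`.
#' @param map data.frame or 2-column matrix of (physical, genetic) positions,
#'   strictly increasing in both columns and covering `[0, sequence_length]`.
#' @return A valid `tree_sequence` in genetic-map units.
#' @export
remap_coordinates <- function(ts, map) {
  map <- as.data.frame(map)
  phys <- as.numeric(map[[1L]])
  gen <- as.numeric(map[[2L]])
  if (length(phys) < 2L || any(diff(phys) <= 0) || any(diff(gen) <= 0)) {
    stop("genetic map must be strictly increasing in both columns")
  }
  if (phys[1L] > 0 || phys[length(phys)] < ts$sequence_length) {
    stop("genetic map must cover [0, sequence_length]")
  }
  f <- function(x) stats::approx(phys, gen, xout = x, rule = 1)$y
  out <- ts
  out$sequence_length <- f(ts$sequence_length)
  if (nrow(ts$edges) > 0L) {
    out$edges$left <- f(ts$edges$left)
    out$edges$right <- f(ts$edges$right)
  }
  if (!is.null(ts$sites)) out$sites$position <- f(ts$sites$position)
  validate_tree_sequence(out)
  out
}
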