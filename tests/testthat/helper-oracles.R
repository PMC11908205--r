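# Fixtures and independent brute-force oracles.  The oracles deliberately use
# different algorithms from the package (per-position forest reconstruction
# from the raw edge table, ancestor-chain climbing) so that agreement is
# evidence of correctness rather than shared bugs.

# 2 samples at time 0, one root at time 1, genome length 1:
# C = I, D = [[0,2],[2,0]], B = [[.5,-.5],[-.5,.5]], eGRM = [[1,-1],[-1,1]].
two_sample_ts <- function() {
  tree_sequence(
    nodes = data.frame(time = c(0, 0, 1), is_sample = c(TRUE, TRUE, FALSE)),
    edges = data.frame(left = 0, right = 1, parent = 2, child = 0:1),
    sequence_length = 1)
}

# caterpillar: (a,b) coalesce at t=1 (node 3), +c at t=2 (node 4), span 1.
# C = [[2,1,0],[1,2,0],[0,0,2]].
caterpillar_ts <- function() {
  tree_sequence(
    nodes = data.frame(time = c(0, 0, 0, 1, 2),
                       is_sample = c(TRUE, TRUE, TRUE, FALSE, FALSE)),
    edges = data.frame(left = 0, right = 1,
                       parent = c(3, 3, 4, 4), child = c(0, 1, 3, 2)),
    sequence_length = 1)
}

# small random tree sequences for oracle pools: n in [4, 16], few dozen trees
small_random_ts <- function(seed) {
  n <- 4L + (seed %% 13L)
  simulate_coalescent_ts(n_samples = n, sequence_length = 2e4, N_e = 1e4,
                         recomb_rate = 2e-8, seed = seed)
}

# lazily built, cached pool of 50 small random tree sequences
.oracle_pool <- new.env(parent = emptyenv())
ts_pool <- function(m = 50L) {
  key <- paste0("pool", m)
  if (is.null(.oracle_pool[[key]])) {
    .oracle_pool[[key]] <- lapply(seq_len(m), function(i) small_random_ts(i))
  }
  .oracle_pool[[key]]
}

# brute-force parent map (1-based, 0 = none) at position x from the raw edges
oracle_parents_at <- function(ts, x) {
  par <- integer(nrow(ts$nodes))
  ed <- ts$edges
  hit <- ed$left <= x & x < ed$right
  par[ed$child[hit]] <- ed$parent[hit]
  par
}

# ancestor chain of 1-based node u (including u) under a parent map
oracle_chain <- function(par, u) {
  out <- integer(0)
  while (u != 0L) {
    out <- c(out, u)
    u <- par[u]
  }
  out
}

# naive mrca via chain intersection; NA if disconnected (1-based ids)
oracle_mrca <- function(par, u, v) {
  cu <- oracle_chain(par, u)
  cv <- oracle_chain(par, v)
  hit <- cv[cv %in% cu]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

# per-tree interval midpoints, from the raw edge table only
oracle_breaks <- function(ts) {
  sort(unique(c(0, ts$sequence_length, ts$edges$left, ts$edges$right)))
}

# node x sample descent indicator by climbing each sample's ancestor chain
oracle_indicator <- function(ts, par) {
  samples <- which(ts$nodes$is_sample)
  S <- matrix(0, nrow(ts$nodes), length(samples))
  for (j in seq_along(samples)) S[oracle_chain(par, samples[j]), j] <- 1
  S
}

# uncentered branch GRM by per-interval chain climbing
oracle_uncentered_C <- function(ts) {
  bp <- oracle_breaks(ts)
  ns <- sum(ts$nodes$is_sample)
  C <- matrix(0, ns, ns)
  for (k in seq_len(length(bp) - 1L)) {
    par <- oracle_parents_at(ts, (bp[k] + bp[k + 1L]) / 2)
    S <- oracle_indicator(ts, par)
    len <- numeric(nrow(ts$nodes))
    att <- which(par > 0L)
    len[att] <- ts$nodes$time[par[att]] - ts$nodes$time[att]
    C <- C + (bp[k + 1L] - bp[k]) * crossprod(S, len * S)
  }
  C
}

# divergence matrix by per-interval naive mrca
oracle_divergence <- function(ts) {
  bp <- oracle_breaks(ts)
  samples <- which(ts$nodes$is_sample)
  ns <- length(samples)
  st <- ts$nodes$time[samples]
  D <- matrix(0, ns, ns)
  for (k in seq_len(length(bp) - 1L)) {
    par <- oracle_parents_at(ts, (bp[k] + bp[k + 1L]) / 2)
    span <- bp[k + 1L] - bp[k]
    for (i in seq_len(ns - 1L)) {
      for (j in seq(i + 1L, ns)) {
        m <- oracle_mrca(par, samples[i], samples[j])
        stopifnot(!is.na(m))
        d <- span * (2 * ts$nodes$time[m] - st[i] - st[j])
        D[i, j] <- D[i, j] + d
        D[j, i] <- D[j, i] + d
      }
    }
  }
  D
}

# eGRM by an explicit per-edge (per-node-per-interval) loop
oracle_egrm <- function(ts) {
  bp <- oracle_breaks(ts)
  ns <- sum(ts$nodes$is_sample)
  E <- matrix(0, ns, ns)
  area <- 0
  for (k in seq_len(length(bp) - 1L)) {
    par <- oracle_parents_at(ts, (bp[k] + bp[k + 1L]) / 2)
    S <- oracle_indicator(ts, par)
    span <- bp[k + 1L] - bp[k]
    for (n in which(par > 0L)) {
      nd <- sum(S[n, ])
      if (nd == 0L) next
      b <- ts$nodes$time[par[n]] - ts$nodes$time[n]
      area <- area + span * b
      if (nd == ns) next
      sbar <- nd / ns
      x <- S[n, ] - sbar
      E <- E + span * b * outer(x, x) / (sbar * (1 - sbar))
    }
  }
  E / area
}

# total sample-ancestral branch area by per-interval chain climbing
oracle_total_area <- function(ts) {
  bp <- oracle_breaks(ts)
  area <- 0
  for (k in seq_len(length(bp) - 1L)) {
    par <- oracle_parents_at(ts, (bp[k] + bp[k + 1L]) / 2)
    anc <- rowSums(oracle_indicator(ts, par)) > 0
    att <- which(par > 0L & anc)
    area <- area + (bp[k + 1L] - bp[k]) *
      sum(ts$nodes$time[par[att]] - ts$nodes$time[att])
  }
  area
}

# principal angles (radians) between the column spaces of U and V
principal_angles <- function(U, V) {
  qu <- qr.Q(qr(U))
  qv <- qr.Q(qr(V))
  s <- svd(crossprod(qu, qv))$d
  acos(pmin(pmax(s, -1), 1))
}
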