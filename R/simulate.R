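# internal constructor for simulators: tables already use 1-based node ids
make_ts_internal <- function(nodes, edges, sequence_length,
                             sites = NULL, mutations = NULL) {
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges$left, nodes$time[edges$parent],
                         edges$parent, edges$child), , drop = FALSE]
    rownames(edges) <- NULL
  }
  ts <- structure(
    list(sequence_length = sequence_length,
         nodes = data.frame(time = as.numeric(nodes$time),
                            is_sample = as.logical(nodes$is_sample),
                            individual = if (!is.null(nodes$individual))
                              as.integer(nodes$individual)
                            else rep(NA_integer_, nrow(nodes))),
         edges = edges, sites = sites, mutations = mutations),
    class = "tree_sequence")
  validate_tree_sequence(ts)
  ts
}

#' Simulate a coalescent-with-recombination tree sequence
#'
#' The leftmost local tree is drawn from the Kingman coalescent with pairwise
#' coalescence rate `1 / N_e` (expected pairwise TMRCA `N_e` generations).
#' Moving rightwards, recombination breakpoints arrive at rate
#' `recomb_rate * total branch length` per unit of genome; at each breakpoint
#' a uniformly chosen point on the current tree's branches is pruned and the
#' detached lineage re-coalesces into the remaining tree (sequentially
#' Markovian approximation).  Edge tables are emitted by merging identical
#' parent assignments over adjacent intervals, so edges are maximal.
#'
#' Defaults are human-scale: `N_e = 1e4` (haploid), per-base-pair rates of
#' `1e-8`, a 100 kb genome and 10 samples, which yields on the order of tens
#' of local trees.
#'
#' @param n_samples number of sampled (leaf) genomes at time 0.
#' @param sequence_length genome length.
#' @param N_e haploid effective population size, in generations.
#' @param recomb_rate recombination rate per unit length per generation.
#' @param seed RNG seed.
#' @return A fully coalesced `tree_sequence`.
#' @export
simulate_coalescent_ts <- function(n_samples = 10L, sequence_length = 1e5,
                                   N_e = 1e4, recomb_rate = 1e-8, seed = 1L) {
  if (n_samples < 2L) stop("need at least 2 samples")
  L <- sequence_length
  with_seed(derive_seed(seed, "trees"), {
    times <- rep(0, n_samples)
    par <- integer(n_samples)
    active <- seq_len(n_samples)
    t <- 0
    while (length(active) > 1L) {
      k <- length(active)
      t <- t + stats::rexp(1L, k * (k - 1L) / 2 / N_e)
      pair <- sample(k, 2L)
      new_id <- length(times) + 1L
      times <- c(times, t)
      par <- c(par, 0L)
      par[active[pair]] <- new_id
      active <- c(active[-pair], new_id)
    }
    root <- active
    in_tree <- c(rep(TRUE, length(times)))

    snapshots <- list()
    positions <- numeric(0)
    pos <- 0
    repeat {
      attached <- which(in_tree & par > 0L)
      lens <- times[par[attached]] - times[attached]
      Ltot <- sum(lens)
      dist <- if (recomb_rate > 0 && Ltot > 0)
        stats::rexp(1L, recomb_rate * Ltot) else Inf
      nxt <- pos + dist
      snapshots[[length(snapshots) + 1L]] <- par
      positions <- c(positions, pos)
      if (nxt >= L) break

      # prune: uniform point on the branches
      ci <- sample.int(length(attached), 1L, prob = lens)
      cnode <- attached[ci]
      u <- stats::runif(1L, times[cnode], times[par[cnode]])
      p <- par[cnode]
      par[cnode] <- 0L
      # splice out p (binary nodes: one remaining child)
      d <- which(in_tree & par == p)
      stopifnot(length(d) == 1L)
      gp <- par[p]
      par[d] <- gp
      par[p] <- 0L
      in_tree[p] <- FALSE
      if (p == root) root <- d

      # re-coalesce the floating lineage from time u upward; lineages of the
      # remaining tree are branches crossing t, plus the root lineage
      rem <- which(in_tree & !subtree_member(par, cnode))
      starts <- times[rem]
      ends <- rep(Inf, length(rem))   # the root lineage extends to infinity
      has_p <- par[rem] > 0L
      ends[has_p] <- times[par[rem][has_p]]
      tt <- u
      repeat {
        m <- sum(starts <= tt & ends > tt)
        t_next <- suppressWarnings(min(starts[starts > tt]))
        dt <- stats::rexp(1L, m / N_e)
        if (tt + dt < t_next) {
          tstar <- tt + dt
          break
        }
        tt <- t_next
      }
      cross <- rem[starts <= tstar & ends > tstar]
      target <- if (length(cross) == 1L) cross else
        cross[sample.int(length(cross), 1L)]
      g <- length(times) + 1L
      times <- c(times, tstar)
      par <- c(par, 0L)
      in_tree <- c(in_tree, TRUE)
      if (target == root) {
        # re-coalesce onto the lineage above the old root
        par[root] <- g
        par[cnode] <- g
        root <- g
      } else {
        q <- par[target]
        par[target] <- g
        par[cnode] <- g
        par[g] <- q
      }
      pos <- nxt
    }

    # emit maximal edges from the per-interval parent snapshots
    K <- length(snapshots)
    n_total <- length(times)
    bounds <- c(positions, L)
    pm <- matrix(0L, n_total, K)
    for (k in seq_len(K)) {
      sp <- snapshots[[k]]
      pm[seq_along(sp), k] <- sp
    }
    el <- er <- ep <- ec <- list()
    for (nd in seq_len(n_total)) {
      r <- rle(pm[nd, ])
      stop_at <- cumsum(r$lengths)
      start_at <- c(0L, stop_at[-length(stop_at)]) + 1L
      keep <- r$values != 0L
      if (any(keep)) {
        i <- length(el) + 1L
        el[[i]] <- bounds[start_at[keep]]
        er[[i]] <- bounds[stop_at[keep] + 1L]
        ep[[i]] <- r$values[keep]
        ec[[i]] <- rep(nd, sum(keep))
      }
    }
    make_ts_internal(
      nodes = data.frame(time = times,
                         is_sample = seq_len(n_total) <= n_samples,
                         individual = NA_integer_),
      edges = data.frame(left = unlist(el), right = unlist(er),
                         parent = unlist(ep), child = unlist(ec)),
      sequence_length = L)
  })
}

# logical vector: node is in the subtree rooted at `root_node` under `par`
subtree_member <- function(par, root_node) {
  n <- length(par)
  memb <- logical(n)
  memb[root_node] <- TRUE
  # children point to parents; propagate by repeated passes (one per level
  # of the subtree)
  repeat {
    add <- which(!memb & par > 0L)
    add <- add[memb[par[add]]]
    if (length(add) == 0L) break
    memb[add] <- TRUE
  }
  memb
}

#' Drop Poisson mutations on a tree sequence
#'
#' The number of mutations on an edge is Poisson with mean `mu` times the
#' edge's area (length in generations times genome span); positions are
#' uniform on the edge's interval.  Every mutation founds its own biallelic
#' site (infinite-sites style), with the edge's child as the mutation node.
#'
#' @param ts a `tree_sequence`.
#' @param mu mutation rate per unit area.
#' @param seed RNG seed.
#' @return A `tree_sequence` with site and mutation tables (positions sorted).
#' @export
drop_mutations <- function(ts, mu, seed = 1L) {
  if (mu < 0) stop("mu must be non-negative")
  with_seed(derive_seed(seed, "mutations"), {
    ed <- ts$edges
    out <- ts
    if (mu == 0 || nrow(ed) == 0L) {
      out$sites <- data.frame(position = numeric(0))
      out$mutations <- data.frame(site = integer(0), node = integer(0))
      return(out)
    }
    areas <- (ed$right - ed$left) *
      (ts$nodes$time[ed$parent] - ts$nodes$time[ed$child])
    counts <- stats::rpois(nrow(ed), mu * areas)
    tot <- sum(counts)
    if (tot == 0L) {
      out$sites <- data.frame(position = numeric(0))
      out$mutations <- data.frame(site = integer(0), node = integer(0))
      return(out)
    }
    eidx <- rep(seq_len(nrow(ed)), counts)
    posn <- stats::runif(tot, ed$left[eidx], ed$right[eidx])
    o <- order(posn)
    out$sites <- data.frame(position = posn[o])
    out$mutations <- data.frame(site = seq_len(tot), node = ed$child[eidx][o])
    out
  })
}

#' Genotype matrix from mutations
#'
#' Binary matrix with one row per sample and one column per site; entry 1
#' means the sample inherits the derived allele, i.e. descends from the
#' mutation's node in the local tree covering the site's position.
#'
#' @param ts a `tree_sequence` with site and mutation tables.
#' @return numeric 0/1 matrix, `n_samples` x `n_sites`.
#' @export
genotypes_from_mutations <- function(ts) {
  if (is.null(ts$sites)) stop("tree sequence has no site table")
  ns <- n_samples(ts)
  n_sites <- nrow(ts$sites)
  G <- matrix(0, ns, n_sites)
  if (n_sites == 0L) return(G)
  mut_by_site <- split(ts$mutations$node, ts$mutations$site)
  for (tree in local_trees(ts)) {
    in_tree <- which(ts$sites$position >= tree$interval[1L] &
                       ts$sites$position < tree$interval[2L])
    if (length(in_tree) == 0L) next
    si <- tree_sample_indicator(tree)
    for (s in in_tree) {
      nodes <- mut_by_site[[as.character(s)]]
      if (is.null(nodes)) next
      # parity handles the (unused here) stacked-mutation case; with one
      # mutation per site this is just the descent indicator of its node
      G[, s] <- as.numeric(colSums(si$S[nodes, , drop = FALSE]) %% 2 == 1)
    }
  }
  G
}

#' Simulate an additive trait on a genotype matrix
#'
#' Each site receives an i.i.d. normal effect with mean zero and variance
#' `sigma2`; the genetic value of a sample is the sum of effects over the
#' derived alleles it carries.
#'
#' @param G binary genotype matrix (samples x sites).
#' @param sigma2 per-site effect variance.
#' @param seed RNG seed.
#' @return An object of class `trait_model` with fields `effects`, `values`
#'   (per-sample genetic values), `mean_value` and `sigma2`.
#' @export
simulate_trait <- function(G, sigma2 = 1, seed = 1L) {
  G <- as.matrix(G)
  with_seed(derive_seed(seed, "effects"), {
    eff <- stats::rnorm(ncol(G), sd = sqrt(sigma2))
    z <- as.numeric(G %*% eff)
    structure(list(effects = eff, values = z, mean_value = mean(z),
                   sigma2 = sigma2),
              class = "trait_model")
  })
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf(
    "Additive trait: %d loci, effect variance %g, %d samples, mean value %g\n",
    length(x$effects), x$sigma2, length(x$values), x$mean_value))
  invisible(x)
}

#' Mean pairwise TMRCA of a tree sequence
#'
#' One half of the mean branch genetic divergence per unit of genome:
#' `mean over pairs of D[i, j] / (2 * sequence_length)`.  Requires a fully
#' coalesced tree sequence.
#'
#' @param ts a `tree_sequence`.
#' @return Mean TMRCA in generations.
#' @export
mean_tmrca <- function(ts) {
  D <- as.matrix(divergence_matrix(ts))
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 samples")
  mean(D[upper.tri(D)]) / (2 * ts$sequence_length)
}
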