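#' Construct a pedigree
#'
#' A pedigree stores, per individual, its two parents (or none: founders) and
#' a generation index.  Individuals must be ordered (or orderable) so that
#' parents precede children; unknown parents are treated as founders.
#'
#' @param id vector of unique individual identifiers.
#' @param father,mother identifiers of the parents; `NA` or an id not present
#'   marks an unknown parent.
#' @param probands optional ids of focal (sampled, contemporary) individuals.
#' @return An object of class `pedigree` with fields `id`, `father`, `mother`
#'   (integer indices into `id`, `NA` for unknown), `generation` (0 =
#'   founders) and `proband` (logical).
#' @export
pedigree <- function(id, father, mother, probands = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate individual ids")
  fi <- match(as.character(father), id)
  mi <- match(as.character(mother), id)
  n <- length(id)
  # topological generation index; cycles leave nodes unresolvable
  gen <- rep(NA_integer_, n)
  gen[is.na(fi) & is.na(mi)] <- 0L
  repeat {
    progress <- FALSE
    for (i in which(is.na(gen))) {
      gf <- if (is.na(fi[i])) -1L else gen[fi[i]]
      gm <- if (is.na(mi[i])) -1L else gen[mi[i]]
      if (!is.na(gf) && !is.na(gm)) {
        gen[i] <- max(gf, gm) + 1L
        progress <- TRUE
      }
    }
    if (!any(is.na(gen))) break
    if (!progress) stop("pedigree contains a cycle")
  }
  pr <- if (is.null(probands)) rep(FALSE, n) else id %in% as.character(probands)
  structure(list(id = id, father = fi, mother = mi, generation = gen,
                 proband = pr),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals, %d founders, %d probands, depth %d\n",
              length(x$id), sum(is.na(x$father) & is.na(x$mother)),
              sum(x$proband), max(x$generation)))
  invisible(x)
}

#' Pedigree kinship matrix
#'
#' The kinship theta(i, j) is the probability that two genome copies, one
#' drawn at random from each individual, are identical by descent within the
#' pedigree.  Computed by the standard tabular recursion: founders are
#' non-inbred and unrelated (`theta(i,i) = 1/2`, `theta(i,j) = 0`);
#' `theta(i,j) = (theta(father(i),j) + theta(mother(i),j)) / 2` for j not a
#' descendant of i; `theta(i,i) = (1 + theta(father(i),mother(i))) / 2`.
#'
#' @param ped a `pedigree`.
#' @param ids optional subset of individual ids (e.g. probands) for the
#'   returned matrix; the recursion always runs over the whole pedigree.
#' @return A `relatedness_matrix` of mode `pedigree_kinship`.
#' @export
pedigree_kinship <- function(ped, ids = NULL) {
  n <- length(ped$id)
  ord <- order(ped$generation)
  theta <- matrix(0, n, n)
  for (i in ord) {
    f <- ped$father[i]; m <- ped$mother[i]
    tf <- if (is.na(f)) 0 else theta[f, ]
    tm <- if (is.na(m)) 0 else theta[m, ]
    row <- (tf + tm) / 2
    theta[i, ] <- row
    theta[, i] <- row
    theta[i, i] <- 0.5 * (1 + if (is.na(f) || is.na(m)) 0 else theta[f, m])
  }
  dimnames(theta) <- list(ped$id, ped$id)
  if (!is.null(ids)) {
    ids <- as.character(ids)
    theta <- theta[ids, ids, drop = FALSE]
  }
  new_relatedness_matrix(theta, "pedigree_kinship", "dimensionless")
}

#' Build a balanced synthetic pedigree
#'
#' One founder couple at generation 0; every couple has `sibship` children;
#' each non-terminal child marries a newly introduced, unrelated founder
#' spouse, keeping mating monogamous and the design non-inbred.  The
#' final-generation individuals are the probands.  With `sibship = 2` and
#' `generations = 4` the 16 probands form 8 sibling, 16 first-cousin, 32
#' second-cousin and 64 third-cousin pairs, each with identical marginal
#' relatedness profiles — convenient for comparing branch and pedigree
#' relatedness.
#'
#' @param generations number of descent steps from the founder couple (>= 2
#'   gives sibling pairs, 4 gives up to third cousins).
#' @param sibship children per couple.
#' @return A `pedigree` with probands flagged.
#' @export
make_pedigree <- function(generations, sibship = 2L) {
  if (generations < 1L) stop("need at least 1 generation of offspring")
  id <- c("F0a", "F0b")
  father <- c(NA, NA)
  mother <- c(NA, NA)
  couples <- list(c("F0a", "F0b"))
  for (g in seq_len(generations)) {
    nxt <- list()
    for (ci in seq_along(couples)) {
      cp <- couples[[ci]]
      for (s in seq_len(sibship)) {
        kid <- sprintf("G%d_%d_%d", g, ci, s)
        id <- c(id, kid); father <- c(father, cp[1L]); mother <- c(mother, cp[2L])
        if (g < generations) {
          sp <- paste0(kid, "sp")
          id <- c(id, sp); father <- c(father, NA); mother <- c(mother, NA)
          nxt[[length(nxt) + 1L]] <- c(kid, sp)
        }
      }
    }
    couples <- nxt
  }
  probands <- grep(sprintf("^G%d_", generations), id, value = TRUE)
  pedigree(id, father, mother, probands = probands)
}

#' Gene-drop a pedigree into a within-pedigree tree sequence
#'
#' Simulates Mendelian inheritance with recombination through the fixed
#' pedigree: each individual carries two genome-copy nodes; every non-founder
#' copy is a recombination mosaic of the corresponding parent's two copies,
#' with a Poisson(`recomb_rate * sequence_length`) number of crossover
#' breakpoints per meiosis.  Local-tree roots are founder genome copies
#' (founder lineages are left open for [recapitate()]); proband copies are
#' flagged as samples.  Node times equal generations before the probands.
#'
#' @param ped a `pedigree`; every non-founder must have both parents known.
#' @param sequence_length genome length.
#' @param recomb_rate crossover rate per unit length per meiosis.
#' @param seed RNG seed.
#' @return A `tree_sequence` whose samples are the proband genome copies; the
#'   `individual` column maps copies to pedigree rows (0-based).
#' @export
gene_drop <- function(ped, sequence_length, recomb_rate, seed = 1L) {
  n <- length(ped$id)
  known <- !is.na(ped$father) & !is.na(ped$mother)
  if (any(xor(is.na(ped$father), is.na(ped$mother)))) {
    stop("gene_drop requires both parents known or both unknown")
  }
  L <- sequence_length
  maxgen <- max(ped$generation)
  copy1 <- 2L * seq_len(n) - 1L
  copy2 <- 2L * seq_len(n)
  node_time <- numeric(2L * n)
  node_time[copy1] <- maxgen - ped$generation
  node_time[copy2] <- maxgen - ped$generation
  is_sample <- logical(2L * n)
  is_sample[copy1[ped$proband]] <- TRUE
  is_sample[copy2[ped$proband]] <- TRUE
  individual <- rep(seq_len(n) - 1L, each = 2L)
  with_seed(derive_seed(seed, "meiosis"), {
    el <- er <- ep <- ec <- list()
    add_meiosis <- function(child_copy, par_ind) {
      # segments alternate between the parent's two copies
      nbrk <- stats::rpois(1L, recomb_rate * L)
      brk <- sort(stats::runif(nbrk, 0, L))
      brk <- unique(brk)
      bounds <- c(0, brk, L)
      start <- sample(c(copy1[par_ind], copy2[par_ind]), 1L)
      other <- if (start == copy1[par_ind]) copy2[par_ind] else copy1[par_ind]
      src <- rep(c(start, other), length.out = length(bounds) - 1L)
      i <- length(el) + 1L
      el[[i]] <<- bounds[-length(bounds)]
      er[[i]] <<- bounds[-1L]
      ep[[i]] <<- src
      ec[[i]] <<- rep(child_copy, length(src))
    }
    for (i in which(known)) {
      add_meiosis(copy1[i], ped$father[i])
      add_meiosis(copy2[i], ped$mother[i])
    }
    edges <- data.frame(left = unlist(el), right = unlist(er),
                        parent = unlist(ep), child = unlist(ec))
    make_ts_internal(
      nodes = data.frame(time = node_time, is_sample = is_sample,
                         individual = individual),
      edges = edges, sequence_length = L)
  })
}

#' Proband genome-copy grouping of a gene-dropped tree sequence
#'
#' Returns the per-sample individual labels needed by
#' [collapse_to_individuals()] and [pca_individuals()].
#'
#' @param ts a `tree_sequence` with an `individual` column.
#' @return character vector of individual labels, one per sample.
#' @export
sample_individuals <- function(ts) {
  s <- sample_nodes(ts)
  ind <- ts$nodes$individual[s]
  if (anyNA(ind)) stop("tree sequence has samples without individual labels")
  as.character(ind)
}

#' Recapitate open founder lineages
#'
#' Completes a within-pedigree tree sequence by coalescing, for each local
#' tree independently, the remaining sample-ancestral roots under a Kingman
#' coalescent with haploid size `N_e` (pairwise coalescence rate 1/N_e),
#' starting each lineage at its root's time.  Per-tree independence ignores
#' linkage among founder lineages across trees; marginal per-tree
#' distributions are exact.
#'
#' @param ts a `tree_sequence` with (possibly) multiple roots per tree.
#' @param N_e haploid effective population size, in generations.
#' @param seed RNG seed.
#' @return A fully coalesced `tree_sequence`.
#' @export
recapitate <- function(ts, N_e, seed = 1L) {
  with_seed(derive_seed(seed, "recapitation"), {
    nd_time <- ts$nodes$time
    nd_sample <- ts$nodes$is_sample
    nd_ind <- ts$nodes$individual
    el <- er <- ep <- ec <- list()
    for (tree in local_trees(ts)) {
      anc <- sample_ancestral(tree)
      roots <- which(anc & tree$parent == 0L)
      if (length(roots) < 2L) next
      lin_node <- roots
      lin_time <- nd_time[roots]
      t <- min(lin_time)
      active <- which(lin_time <= t)
      pending <- setdiff(seq_along(lin_node), active)
      while (length(active) > 1L || length(pending) > 0L) {
        k <- length(active)
        t_next <- if (length(pending) > 0L) min(lin_time[pending]) else Inf
        if (k < 2L) {
          t <- t_next
        } else {
          dt <- stats::rexp(1L, k * (k - 1L) / 2 / N_e)
          if (t + dt >= t_next) {
            t <- t_next
          } else {
            t <- t + dt
            pair <- sample(active, 2L)
            new_id <- length(nd_time) + 1L
            nd_time <- c(nd_time, t)
            nd_sample <- c(nd_sample, FALSE)
            nd_ind <- c(nd_ind, NA_integer_)
            i <- length(el) + 1L
            el[[i]] <- rep(tree$interval[1L], 2L)
            er[[i]] <- rep(tree$interval[2L], 2L)
            ep[[i]] <- rep(new_id, 2L)
            ec[[i]] <- lin_node[pair]
            lin_node <- c(lin_node[-pair], new_id)
            lin_time <- c(lin_time[-pair], t)
            active <- which(lin_time <= t)
            pending <- setdiff(seq_along(lin_node), active)
            next
          }
        }
        active <- which(lin_time <= t)
        pending <- setdiff(seq_along(lin_node), active)
      }
    }
    if (length(el) == 0L) return(ts)
    edges <- rbind(ts$edges,
                   data.frame(left = unlist(el), right = unlist(er),
                              parent = unlist(ep), child = unlist(ec)))
    make_ts_internal(
      nodes = data.frame(time = nd_time, is_sample = nd_sample,
                         individual = nd_ind),
      edges = edges, sequence_length = ts$sequence_length,
      sites = ts$sites, mutations = ts$mutations)
  })
}
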