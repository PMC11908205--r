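test_that("minimal 2-sample tree sequence constructs and prints", {
  ts <- two_sample_ts()
  expect_s3_class(ts, "tree_sequence")
  expect_equal(num_trees(ts), 1L)
  expect_equal(length(local_trees(ts)), 1L)
  expect_output(print(ts), "3 nodes \\(2 samples\\), 2 edges, 1 trees")
  expect_output(summary(ts), "total branch area")
})

test_that("validation rejects invariant violations with row numbers", {
  nodes <- data.frame(time = c(0, 0, 1), is_sample = c(TRUE, TRUE, FALSE))
  # parent not older than child
  expect_error(
    tree_sequence(nodes,
                  data.frame(left = 0, right = 1, parent = c(2, 0), child = c(0, 1)),
                  1),
    "edge row 1: time\\(parent\\) must exceed time\\(child\\)")
  # overlapping intervals for one child
  expect_error(
    tree_sequence(nodes,
                  data.frame(left = c(0, 0.5), right = c(0.8, 1),
                             parent = 2, child = 0),
                  1),
    "overlapping intervals for child 0")
  # left >= right
  expect_error(
    tree_sequence(nodes,
                  data.frame(left = 0.5, right = 0.5, parent = 2, child = 0), 1),
    "edge row 0: must have 0 <= left < right")
  # node id out of range
  expect_error(
    tree_sequence(nodes,
                  data.frame(left = 0, right = 1, parent = 7, child = 0), 1),
    "edge row 0: node id out of range")
  # negative time
  expect_error(
    tree_sequence(data.frame(time = c(-1, 0, 1),
                             is_sample = c(TRUE, TRUE, FALSE)),
                  data.frame(left = 0, right = 1, parent = 2, child = 0:1), 1),
    "node row 0: time must be finite")
  # bad sequence length
  expect_error(tree_sequence(nodes, data.frame(), 0), "positive")
  # site position out of range
  expect_error(
    tree_sequence(nodes,
                  data.frame(left = 0, right = 1, parent = 2, child = 0:1), 1,
                  sites = data.frame(position = 1.5),
                  mutations = data.frame(site = 0, node = 0)),
    "site row 0: position outside")
  # mutation referencing a missing site
  expect_error(
    tree_sequence(nodes,
                  data.frame(left = 0, right = 1, parent = 2, child = 0:1), 1,
                  sites = data.frame(position = 0.5),
                  mutations = data.frame(site = 3, node = 0)),
    "mutation row 0: site or node out of range")
})

test_that("single-tree sequence yields one element with all edges added", {
  lt <- local_trees(two_sample_ts())
  expect_length(lt, 1L)
  expect_equal(lt[[1L]]$removed, integer(0))
  expect_setequal(lt[[1L]]$added, 1:2)
  expect_equal(lt[[1L]]$interval, c(0, 1))
})

test_that("tree transitions swap a bounded edge set and match brute force", {
  found_transition <- FALSE
  ok <- TRUE
  for (ts in ts_pool()) {
    lt <- local_trees(ts)
    if (length(lt) < 2L) next
    for (k in 2:length(lt)) {
      found_transition <- TRUE
      # an SMC prune-regraft edit rewires at least one and at most a
      # handful of edges
      ok <- ok && length(lt[[k]]$removed) >= 1L &&
        length(lt[[k]]$added) >= 1L && length(lt[[k]]$removed) <= 4L
    }
  }
  expect_true(found_transition)
  expect_true(ok)
})

test_that("sweep parent maps equal brute-force forest reconstruction", {
  for (ts in ts_pool()) {
    lt <- local_trees(ts)
    expect_true(all(vapply(lt, function(tree) {
      identical(tree$parent, oracle_parents_at(ts, mean(tree$interval)))
    }, logical(1))))
    # span conservation
    expect_equal(sum(vapply(lt, function(t) t$span, numeric(1))),
                 ts$sequence_length)
    expect_equal(length(lt), num_trees(ts))
  }
})

test_that("tree sequences round-trip through the TSV tables", {
  ts <- drop_mutations(ts_pool()[[3L]], mu = 2e-7, seed = 9L)
  expect_gt(nrow(ts$sites), 0L)
  prefix <- file.path(withr::local_tempdir(), "ts")
  write_tree_sequence(ts, prefix)
  ts2 <- read_tree_sequence(prefix, sequence_length = ts$sequence_length)
  expect_equal(ts2$nodes, ts$nodes)
  expect_equal(ts2$edges, ts$edges, ignore_attr = TRUE)
  expect_equal(ts2$sites, ts$sites)
  expect_equal(ts2$mutations, ts$mutations)
  expect_equal(ts2$sequence_length, ts$sequence_length)
})

test_that("mrca handles identity, caterpillar, and disconnection", {
  tr <- local_trees(caterpillar_ts())[[1L]]
  expect_equal(mrca(tr, 0, 0), 0L)
  expect_equal(mrca(tr, 0, 1), 3L)  # inner node
  expect_equal(mrca(tr, 0, 2), 4L)  # root
  expect_error(mrca(tr, 0, 99), "unknown node id")
  # two root-subtrees: no common ancestor
  ts2 <- tree_sequence(
    nodes = data.frame(time = c(0, 0, 1, 1),
                       is_sample = c(TRUE, TRUE, FALSE, FALSE)),
    edges = data.frame(left = 0, right = 1, parent = c(2, 3), child = c(0, 1)),
    sequence_length = 1)
  tr2 <- local_trees(ts2)[[1L]]
  expect_true(is.na(mrca(tr2, 0, 1)))
})

test_that("mrca agrees with naive chain intersection on random trees", {
  for (ts in ts_pool()) {
    samples <- which(ts$nodes$is_sample)
    pairs <- utils::combn(samples, 2L)
    expect_true(all(vapply(local_trees(ts), function(tree) {
      par <- oracle_parents_at(ts, mean(tree$interval))
      all(vapply(seq_len(ncol(pairs)), function(p) {
        u <- pairs[1L, p]; v <- pairs[2L, p]
        m <- oracle_mrca(par, u, v)
        identical(mrca(tree, u - 1L, v - 1L),
                  if (is.na(m)) NA_integer_ else m - 1L)
      }, logical(1)))
    }, logical(1))))
  }
})

test_that("total_area matches hand values, linearity, and the oracle", {
  expect_equal(total_area(two_sample_ts()), 2)
  # doubling the span doubles the area
  ts2 <- tree_sequence(
    nodes = data.frame(time = c(0, 0, 1), is_sample = c(TRUE, TRUE, FALSE)),
    edges = data.frame(left = 0, right = 2, parent = 2, child = 0:1),
    sequence_length = 2)
  expect_equal(total_area(ts2), 4)
  for (ts in ts_pool()[1:10]) {
    expect_equal(total_area(ts), oracle_total_area(ts))
  }
})

test_that("remap_coordinates applies piecewise-linear interpolation", {
  ts <- ts_pool()[[1L]]
  L <- ts$sequence_length
  # identity map: unchanged
  same <- remap_coordinates(ts, data.frame(phys = c(0, L), gen = c(0, L)))
  expect_equal(same$edges, ts$edges)
  expect_equal(same$sequence_length, L)
  # uniform halving: spans and total area halve
  half <- remap_coordinates(ts, data.frame(phys = c(0, L), gen = c(0, L / 2)))
  expect_equal(half$sequence_length, L / 2)
  expect_equal(total_area(half), total_area(ts) / 2)
  # 3-segment map equals an independent interpolation oracle
  map <- data.frame(phys = c(0, L / 3, L), gen = c(0, L / 2, L))
  out <- remap_coordinates(ts, map)
  interp <- function(x) {
    ifelse(x <= L / 3, x * (L / 2) / (L / 3),
           L / 2 + (x - L / 3) * (L / 2) / (2 * L / 3))
  }
  expect_equal(out$edges$left, interp(ts$edges$left))
  expect_equal(out$edges$right, interp(ts$edges$right))
  expect_equal(out$nodes$time, ts$nodes$time)
  # invalid maps
  expect_error(remap_coordinates(ts, data.frame(p = c(0, L), g = c(1, 0))),
               "strictly increasing")
  expect_error(remap_coordinates(ts, data.frame(p = c(0, L / 2), g = c(0, 1))),
               "must cover")
})
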