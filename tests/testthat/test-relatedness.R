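test_that("divergence matrix matches hand values and the naive mrca oracle", {
  D <- divergence_matrix(two_sample_ts())
  expect_equal(as.matrix(D), matrix(c(0, 2, 2, 0), 2), ignore_attr = TRUE)
  expect_equal(grm_mode(D), "divergence_D")
  for (ts in ts_pool()[1:15]) {
    expect_equal(as.matrix(divergence_matrix(ts)), oracle_divergence(ts),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(diag(as.matrix(divergence_matrix(ts))),
                 rep(0, n_samples(ts)))
  }
  # pair with no common root: error names the interval
  ts2 <- tree_sequence(
    nodes = data.frame(time = c(0, 0, 1, 1),
                       is_sample = c(TRUE, TRUE, FALSE, FALSE)),
    edges = data.frame(left = 0, right = 1, parent = c(2, 3), child = c(0, 1)),
    sequence_length = 1)
  expect_error(divergence_matrix(ts2), "no common root in tree on \\[0, 1\\)")
})

test_that("uncentered C matches hand values and is PSD", {
  expect_equal(as.matrix(branch_grm_uncentered(two_sample_ts())), diag(2),
               ignore_attr = TRUE)
  C3 <- as.matrix(branch_grm_uncentered(caterpillar_ts()))
  expect_equal(C3, matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3),
               ignore_attr = TRUE)
  for (ts in ts_pool()) {
    C <- as.matrix(branch_grm_uncentered(ts))
    expect_equal(C, oracle_uncentered_C(ts), tolerance = 1e-12,
                 ignore_attr = TRUE)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9 * max(ev))
  }
})

test_that("centered B: hand value, equal methods, zero row sums, PSD", {
  B <- as.matrix(branch_grm_centered(two_sample_ts()))
  expect_equal(B, matrix(c(0.5, -0.5, -0.5, 0.5), 2), ignore_attr = TRUE)
  for (ts in ts_pool()[1:10]) {
    Ba <- as.matrix(branch_grm_centered(ts, method = "area"))
    Bd <- as.matrix(branch_grm_centered(ts, method = "divergence"))
    Bt <- as.matrix(branch_grm_centered(ts, method = "tmrca"))
    scale <- max(abs(Ba))
    expect_lt(max(abs(Ba - Bd)), 1e-9 * scale)
    expect_lt(max(abs(Ba - Bt)), 1e-9 * scale)
    expect_lt(max(abs(rowSums(Ba))), 1e-9 * scale)
    ev <- eigen(Ba, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9 * max(ev))
  }
})

test_that("eGRM matches the hand value and the per-edge oracle", {
  E <- as.matrix(egrm(two_sample_ts()))
  expect_equal(E, matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  for (ts in ts_pool()[1:10]) {
    E <- as.matrix(egrm(ts))
    expect_equal(E, oracle_egrm(ts), tolerance = 1e-10, ignore_attr = TRUE)
    expect_lt(max(abs(rowSums(E))), 1e-9 * max(abs(E)))
  }
})

test_that("genotype GRM evaluates Eq.-style hand example and edge cases", {
  G <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(as.matrix(genotype_grm(G)),
               matrix(c(0.125, -0.125, -0.125, 0.125), 2), ignore_attr = TRUE)
  # fixed columns contribute nothing
  expect_equal(as.matrix(genotype_grm(cbind(G, 1, 0))),
               as.matrix(genotype_grm(G)) * 2 / 4)
  expect_error(genotype_grm(matrix(2, 1, 1)), "must lie in")
  expect_error(genotype_grm(matrix(numeric(0), 0, 0)), "empty")
})

test_that("match covariance equals genotype GRM exactly on binary data", {
  G <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(as.matrix(match_covariance(G)),
               matrix(c(0.125, -0.125, -0.125, 0.125), 2), ignore_attr = TRUE)
  set.seed(101)
  for (r in 1:20) {
    n <- sample(2:12, 1L)
    m <- sample(1:30, 1L)
    G <- matrix(rbinom(n * m, 1L, runif(1L, 0.1, 0.9)), n, m)
    expect_equal(as.matrix(match_covariance(G)), as.matrix(genotype_grm(G)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(match_covariance(matrix(0.5, 2, 2)), "binary")
})

test_that("collapse_to_individuals averages blocks correctly", {
  m <- diag(4)
  # 2 diploids from 4 haploids with M = I: diag 0.5, off-diag 0
  out <- collapse_to_individuals(m, c("a", "a", "b", "b"))
  expect_equal(as.matrix(out), matrix(c(0.5, 0, 0, 0.5), 2),
               ignore_attr = TRUE)
  # singleton groups: identity
  out1 <- collapse_to_individuals(m, c("w", "x", "y", "z"))
  expect_equal(as.matrix(out1), m, ignore_attr = TRUE)
  # collapse of a centered matrix keeps zero row sums
  B <- as.matrix(branch_grm_centered(ts_pool()[[2L]]))
  g <- rep(seq_len(nrow(B) / 2), each = 2L)[seq_len(nrow(B))]
  Bc <- as.matrix(collapse_to_individuals(B, g))
  expect_lt(max(abs(rowSums(Bc))), 1e-9 * max(abs(Bc)))
  expect_error(collapse_to_individuals(m, c("a", "a")), "one entry per sample")
})

test_that("pedigree kinship: founders, siblings, parent-offspring", {
  ped <- pedigree(id = c("f", "m", "c1", "c2"),
                  father = c(NA, NA, "f", "f"),
                  mother = c(NA, NA, "m", "m"))
  th <- as.matrix(pedigree_kinship(ped))
  expect_equal(th["f", "m"], 0)
  expect_equal(diag(th), rep(0.5, 4), ignore_attr = TRUE)
  expect_equal(th["c1", "c2"], 0.25)
  expect_equal(th["f", "c1"], 0.25)
  # founders only: theta = I/2
  ped0 <- pedigree(id = c("a", "b"), father = c(NA, NA), mother = c(NA, NA))
  expect_equal(as.matrix(pedigree_kinship(ped0)), diag(2) / 2,
               ignore_attr = TRUE)
  # cycles are rejected
  expect_error(pedigree(id = c("a", "b"), father = c("b", "a"),
                        mother = c("b", "a")),
               "cycle")
})

test_that("first-cousin kinship matches a single-locus gene-dropping oracle", {
  ped <- make_pedigree(generations = 2L, sibship = 2L)
  th <- as.matrix(pedigree_kinship(ped, ids = ped$id[ped$proband]))
  # children of different generation-1 siblings are first cousins
  cousins <- c("G2_1_1", "G2_2_1")
  expect_equal(th[cousins[1L], cousins[2L]], 0.0625)
  # independent Monte-Carlo oracle: drop distinct founder alleles through the
  # pedigree 1e5 times and estimate P(IBD) for a random allele pair
  R <- 1e5L
  set.seed(2024)
  n <- length(ped$id)
  a1 <- matrix(0L, n, R)
  a2 <- matrix(0L, n, R)
  nxt <- 1L
  for (i in order(ped$generation)) {
    f <- ped$father[i]; m <- ped$mother[i]
    if (is.na(f)) {
      a1[i, ] <- nxt; a2[i, ] <- nxt + 1L
      nxt <- nxt + 2L
    } else {
      pick1 <- runif(R) < 0.5
      pick2 <- runif(R) < 0.5
      a1[i, ] <- ifelse(pick1, a1[f, ], a2[f, ])
      a2[i, ] <- ifelse(pick2, a1[m, ], a2[m, ])
    }
  }
  i <- match(cousins[1L], ped$id); j <- match(cousins[2L], ped$id)
  ibd <- ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
            (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4
  se <- stats::sd(ibd) / sqrt(R)
  expect_lt(abs(mean(ibd) - 0.0625), 5 * se)
})

test_that("trait covariance check: zero variance and site-mode closed form", {
  ts <- drop_mutations(ts_pool()[[5L]], mu = 2e-7, seed = 4L)
  expect_gt(nrow(ts$sites), 1L)
  z0 <- trait_covariance_check(ts, sigma2 = 0, n_reps = 10L, seed = 1L,
                               mode = "site")
  expect_equal(max(abs(z0)), 0)
  expect_error(trait_covariance_check(ts, n_reps = 1L), "at least 2")
  # site mode: empirical covariance ~ sigma2 * n_L * C within 5 MC SEs,
  # using the Gaussian closed form Var(hat Sigma_ij) = (S_ii S_jj + S_ij^2)/R
  sigma2 <- 0.7
  R <- 10000L
  G <- genotypes_from_mutations(ts)
  Sig <- sigma2 * ncol(G) * as.matrix(genotype_grm(G))
  emp <- trait_covariance_check(ts, sigma2 = sigma2, n_reps = R, seed = 7L,
                                mode = "site")
  se <- sqrt((outer(diag(Sig), diag(Sig)) + Sig^2) / R)
  expect_lt(max(abs(emp - Sig) / pmax(se, 1e-300)), 5)
})

test_that("trait covariance check: branch mode converges to sigma2 * mu * B", {
  # small dense tree sequence so that mu = 1 gives many mutations per draw
  ts <- simulate_coalescent_ts(n_samples = 12L, sequence_length = 20,
                               N_e = 1, recomb_rate = 5e-2, seed = 11L)
  B <- as.matrix(branch_grm_centered(ts))
  K <- 20L
  batches <- lapply(seq_len(K), function(k) {
    trait_covariance_check(ts, sigma2 = 1, n_reps = 50L, seed = 100L + k,
                           mode = "branch", mu = 1)
  })
  m <- Reduce(`+`, batches) / K
  se <- sqrt(Reduce(`+`, lapply(batches, function(b) (b - m)^2)) /
               (K * (K - 1L)))
  expect_lt(max(abs(m - B) / pmax(se, 1e-300)), 5)
})
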