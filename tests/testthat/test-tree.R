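# small fixed topology used in several tests: ((A,B),C) with root T
.p_abc <- c(4L, 4L, 5L, 5L, NA)

test_that("additive edges satisfy the recursion and invert exactly", {
  # root child: delta equals its total inbreeding
  t1 <- subpop_tree(c(2L, NA), labels = c("A", "T"), f_edge = c(0.3, NA))
  expect_equal(t1$delta[1], 0.3)
  expect_equal(t1$f_total[1], 0.3)
  # chain T -> A -> B with f_A^T = 0.2, f_B^A = 0.1
  t2 <- subpop_tree(c(2L, 3L, NA), labels = c("B", "A", "T"),
                    f_edge = c(0.1, 0.2, NA))
  expect_equal(t2$delta[1], 0.1 * (1 - 0.2))
  expect_equal(t2$f_total[1], 0.28)
  # random tree: f -> delta -> f round trip
  set.seed(401)
  for (rep_i in 1:5) {
    K <- 6
    dat <- make_random_tree(K)
    back <- subpop_tree(dat$parent, f_edge = NULL, delta = dat$tree$delta)
    expect_equal(back$f_edge, dat$tree$f_edge, tolerance = 1e-12)
    expect_equal(back$f_total, dat$tree$f_total, tolerance = 1e-12)
    # f_total non-decreasing along root-to-leaf paths
    nonroot <- setdiff(seq_along(dat$parent), dat$tree$root)
    expect_true(all(dat$tree$f_total[nonroot] >=
                    dat$tree$f_total[dat$parent[nonroot]] - 1e-12))
  }
  expect_error(subpop_tree(c(2L, NA), f_edge = c(1.5, NA)), "\\[0,1\\]")
})

test_that("tree coancestry: star, caterpillar, and brute-force oracle", {
  # star tree: MRCA of any two distinct leaves is the root
  F_leaf <- c(0.1, 0.2, 0.3, 0.4)
  st <- subpop_tree(c(5L, 5L, 5L, 5L, NA), f_edge = c(F_leaf, NA))
  Th <- tree_coancestry(st)
  expect_equal(unname(diag(Th)), F_leaf)
  expect_true(all(Th[upper.tri(Th)] == 0))
  # caterpillar ((A,B),C) with given deltas
  ct <- subpop_tree(.p_abc, labels = c("A", "B", "C", "AB", "T"),
                    delta = c(0.05, 0.05, 0.05, 0.1, NA))
  Th2 <- tree_coancestry(ct)
  expect_equal(Th2["A", "B"], 0.1)
  expect_equal(Th2["A", "C"], 0)
  expect_equal(Th2["A", "A"], 0.15)
  # random trees against enumeration, and PSD
  set.seed(402)
  for (rep_i in 1:5) {
    dat <- make_random_tree(8)
    Th3 <- tree_coancestry(dat$tree)
    expect_equal(unname(Th3),
                 oracle_tree_coancestry(dat$parent, dat$tree$delta,
                                        dat$tree$leaves),
                 tolerance = 1e-12)
    expect_gte(min(eigen(Th3, symmetric = TRUE)$values), -1e-12)
  }
})

test_that("tree genotype draws: zero drift, MAF filter, two-leaf FST", {
  set.seed(403)
  # zero-drift tree: all leaf frequencies equal the ancestral one
  z <- subpop_tree(.p_abc, f_edge = c(0, 0, 0, 0, NA))
  gz <- draw_tree_genotypes(z, 10, 200, maf_min = 0)
  expect_equal(gz$p_leaves, matrix(gz$p_anc, 200, 3), tolerance = 1e-12)
  # sample MAF floor is enforced
  tt <- subpop_tree(.p_abc, f_edge = c(0.3, 0.2, 0.25, 0.15, NA))
  g <- draw_tree_genotypes(tt, 15, 800, maf_min = 0.01)
  p_hat <- rowMeans(g$X) / 2
  expect_gte(min(pmin(p_hat, 1 - p_hat)), 0.01)
  # two leaves at total inbreeding 0.2 each: Hudson FST ~ 0.2
  tw <- subpop_tree(c(3L, 3L, NA), labels = c("A", "B", "T"),
                    f_edge = c(0.2, 0.2, NA))
  gw <- draw_tree_genotypes(tw, 50, 5000, maf_min = 0)
  fst <- oracle_hudson_fst(gw$X[, gw$labels == "A"], gw$X[, gw$labels == "B"])
  expect_equal(fst, 0.2, tolerance = 0.02)
})

test_that("subpopulation coancestry averaging matches brute force", {
  set.seed(404)
  Th <- crossprod(matrix(stats::rnorm(100), 5, 20)) / 5
  labels <- rep(c("a", "b", "c", "d"), each = 5)
  got <- subpop_coancestry(Th, labels)
  for (u in 1:4) for (v in 1:4) {
    ju <- which(labels == letters[u]); jv <- which(labels == letters[v])
    s <- 0
    for (j in ju) for (k in jv) s <- s + Th[j, k]
    expect_equal(got[u, v], s / (length(ju) * length(jv)))
  }
  # one individual per subpopulation: identity; block-constant: exact blocks
  expect_equal(unname(subpop_coancestry(Th, as.character(1:20))),
               unname(Th[order(as.character(1:20)), order(as.character(1:20))]))
  expect_error(subpop_coancestry(Th, labels[1:3]), "match")
})

test_that("fit_tree recovers topology and edges from exact coancestry", {
  set.seed(405)
  for (rep_i in 1:10) {
    dat <- make_random_tree(8)
    Th <- tree_coancestry(dat$tree)
    fit <- fit_tree(Th)
    Th_fit <- tree_coancestry(fit)[rownames(Th), colnames(Th)]
    expect_lt(max(abs(Th_fit - Th)), 1e-6)
    expect_lt(fit$delta0, 1e-6)
    # delta values agree node-by-node when matched on leaf sets
    expect_equal(sort(round(fit$delta[-fit$root], 9)),
                 sort(round(dat$tree$delta[-dat$tree$root], 9)),
                 tolerance = 1e-6)
  }
  # star input: internal deltas ~ 0, leaf deltas = diagonal
  F_leaf <- c(0.1, 0.2, 0.3, 0.4)
  st <- subpop_tree(c(5L, 5L, 5L, 5L, NA),
                    labels = c(paste0("L", 1:4), "T"), f_edge = c(F_leaf, NA))
  fs <- fit_tree(tree_coancestry(st))
  leaf_delta <- fs$delta[fs$leaves][match(paste0("L", 1:4), fs$labels[fs$leaves])]
  expect_equal(unname(leaf_delta), F_leaf, tolerance = 1e-8)
  internal <- setdiff(seq_along(fs$parent), c(fs$leaves, fs$root))
  expect_lt(max(fs$delta[internal]), 1e-8)
})

test_that("fit_tree recovers the truth from genotype-estimated coancestry", {
  set.seed(406)
  dat <- make_random_tree(8, f_range = c(0.05, 0.25))
  Th_true <- tree_coancestry(dat$tree)
  hits <- 0; rmse <- numeric(0)
  for (rep_i in 1:5) {
    g <- draw_tree_genotypes(dat$tree, 30, 15000)
    est <- coancestry_from_kinship(corrected_kinship(g$X))
    Th_hat <- subpop_coancestry(est, g$labels)
    fit <- fit_tree(Th_hat[rownames(Th_true), colnames(Th_true)])
    same_topology <- as.numeric(ape::dist.topo(
      ape::unroot(as_phylo(fit)), ape::unroot(as_phylo(dat$tree)))) == 0
    if (same_topology) hits <- hits + 1
    rmse <- c(rmse, sqrt(mean((sort(fit$delta[-fit$root]) -
                               sort(dat$tree$delta[-dat$tree$root]))^2)))
  }
  expect_gte(hits, 4)
  expect_lt(mean(rmse), 0.01)
})

test_that("newick export/import round trips topology and edge values", {
  set.seed(407)
  dat <- make_random_tree(6)
  path <- file.path(tempdir(), "t.nwk")
  write_tree_newick(dat$tree, path)
  back <- read_tree_newick(path)
  Th1 <- tree_coancestry(dat$tree)
  Th2 <- tree_coancestry(back)[rownames(Th1), colnames(Th1)]
  expect_equal(Th2, Th1, tolerance = 1e-8)
})
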