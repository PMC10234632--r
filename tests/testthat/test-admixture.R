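test_that("admixture proportions: limits, symmetry, and kernel oracle", {
  # infinite-spread limit is uniform
  Q <- admixture_proportions_1d(7, 4, 1e6)
  expect_lt(max(abs(Q - 1 / 4)), 1e-3)
  # K = 2, individual exactly midway between the subpopulations
  Q2 <- admixture_proportions_1d(1, 2, 0.7, coords = 1.5)
  expect_equal(unname(Q2[1, ]), c(0.5, 0.5))
  # brute-force normalized-kernel evaluation
  Q3 <- admixture_proportions_1d(9, 3, 1)
  expect_equal(rowSums(Q3), rep(1, 9))
  expect_equal(Q3, oracle_admix_props(admixture_coords(9, 3), 3, 1),
               tolerance = 1e-12)
  # sigma = 0 assigns everyone to the nearest subpopulation
  Q0 <- admixture_proportions_1d(6, 3, 0)
  expect_true(all(rowSums(Q0 == 1) == 1))
  expect_error(admixture_proportions_1d(5, 3, -1), "non-negative")
})

test_that("admixture coancestry matches brute force and limit cases", {
  set.seed(201)
  Q <- matrix(stats::runif(12), 4, 3)
  Q <- Q / rowSums(Q)
  F_subpops <- c(0.1, 0.25, 0.4)
  expect_equal(admixture_coancestry(Q, F_subpops),
               oracle_admix_coancestry(Q, F_subpops), tolerance = 1e-12)
  # unadmixed individuals: theta_jj = f of own subpopulation, 0 across
  Qid <- diag(3)
  Th <- admixture_coancestry(Qid, F_subpops)
  expect_equal(diag(Th), F_subpops)
  expect_equal(Th[upper.tri(Th)], rep(0, 3))
  # zero inbreeding gives the zero matrix
  expect_equal(admixture_coancestry(Q, c(0, 0, 0)), matrix(0, 4, 4))
  expect_error(admixture_coancestry(Q, c(0.1, 0.2)), "length")
})

test_that("model fit hits FST and kinship-ratio targets deterministically", {
  for (n in c(100, 1000)) {
    model <- fit_admixture_model(n, 10, fst_target = 0.1, kinship_ratio = 0.5)
    Th <- admixture_coancestry(model$Q, model$F_subpops)
    fst <- mean(diag(Th))
    ratio <- (sum(Th) - sum(diag(Th))) / (n * (n - 1)) / fst
    expect_equal(fst, 0.1, tolerance = 1e-4)
    expect_equal(ratio, 0.5, tolerance = 1e-4)
    expect_equal(model$F_subpops, (1:10) * model$tau)
  }
  # determinism
  m1 <- fit_admixture_model(200, 10, 0.1, 0.5)
  m2 <- fit_admixture_model(200, 10, 0.1, 0.5)
  expect_identical(m1$sigma, m2$sigma)
  expect_identical(m1$tau, m2$tau)
  # infeasible ratio errors with the attainable range
  expect_error(fit_admixture_model(50, 10, 0.1, 0.01), "attainable")
})

test_that("kinship ratio is monotone in the kernel spread", {
  n <- 100; K <- 10
  ratios <- vapply(c(0.2, 0.5, 1, 2, 5), function(sigma) {
    Q <- admixture_proportions_1d(n, K, sigma)
    Th <- admixture_coancestry(Q, 1:K)
    (sum(Th) - sum(diag(Th))) / (n * (n - 1)) / mean(diag(Th))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("Balding-Nichols draws: moments and degenerate limits", {
  p <- rep(0.3, 5)
  expect_identical(rbalding_nichols(p, 0), p)
  set.seed(202)
  x1 <- rbalding_nichols(rep(0.3, 2000), 1)
  expect_true(all(x1 %in% c(0, 1)))
  expect_equal(mean(x1), 0.3, tolerance = 0.05)
  x <- rbalding_nichols(rep(0.3, 20000), 0.2)
  expect_lt(abs(mean(x) - 0.3), 0.01)
  expect_lt(abs(stats::var(x) - 0.3 * 0.7 * 0.2), 0.002)
  expect_error(rbalding_nichols(p, -0.1), "\\[0,1\\]")
})

test_that("genotype draws obey the model moments and exclude fixed loci", {
  set.seed(203)
  model <- fit_admixture_model(500, 10, 0.1, 0.5)
  g <- draw_admixture_genotypes(model, 2000)
  expect_equal(dim(g$X), c(2000, 500))
  rs <- rowSums(g$X)
  expect_true(all(rs > 0 & rs < 2 * 500))
  # per-locus mean dosage within 4 binomial SEs of mean pi for >= 95% of loci
  pbar <- rowMeans(g$p_ind)
  se <- sqrt(rowMeans(g$p_ind * (1 - g$p_ind)) / (2 * 500))
  frac_ok <- mean(abs(rowMeans(g$X) / 2 - pbar) <= 4 * se)
  expect_gte(frac_ok, 0.95)
  # zero-drift model: subpopulation frequencies collapse to the ancestral ones
  model0 <- model
  model0$F_subpops <- rep(0, 10)
  g0 <- draw_admixture_genotypes(model0, 50)
  expect_equal(g0$p_subpops, matrix(g0$p_anc, 50, 10), tolerance = 1e-12)
  expect_equal(g0$p_ind, matrix(g0$p_anc, 50, 500), tolerance = 1e-12)
})

test_that("replicate draws at fixed ancestral frequency recover the coancestry", {
  set.seed(204)
  # n and p_anc chosen so fixation (and hence the redraw rule) is negligible,
  # leaving the unconditional covariance identity testable
  n <- 10; K <- 3
  Q <- matrix(stats::runif(n * K), n, K); Q <- Q / rowSums(Q)
  model <- list(Q = Q, F_subpops = c(0.1, 0.2, 0.3))
  p0 <- 0.5
  g <- draw_admixture_genotypes(model, 50000,
                                p_anc_sampler = function(m) rep(p0, m),
                                want_p_ind = FALSE)
  emp <- crossprod(sweep(g$X, 2, 2 * p0)) / nrow(g$X) / (4 * p0 * (1 - p0))
  truth <- kinship_from_coancestry(admixture_coancestry(Q, model$F_subpops))
  expect_lt(mean(abs(emp - truth)), 0.01)
  expect_lt(max(abs(emp - truth)), 0.02)
})

test_that("top K-1 PCs plus intercept span the admixture proportions", {
  set.seed(205)
  model <- fit_admixture_model(300, 10, 0.1, 0.5)
  g <- draw_admixture_genotypes(model, 20000, want_p_ind = FALSE)
  U <- compute_pcs(g$X, 9, maf_min = 0)
  for (u in seq_len(10)) {
    r2 <- summary(stats::lm(model$Q[, u] ~ U))$r.squared
    expect_gt(r2, 0.95)
  }
})
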