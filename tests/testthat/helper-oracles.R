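# Independent brute-force oracles used across the test files.  These are
# deliberately naive (loops, dense inverses, enumeration) and share no code
# with the package internals they check.

# coancestry by triple loop: theta_jk = sum_u Q[j,u] Q[k,u] F[u]
oracle_admix_coancestry <- function(Q, F_subpops) {
  n <- nrow(Q)
  out <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) for (u in seq_along(F_subpops))
    out[j, k] <- out[j, k] + Q[j, u] * Q[k, u] * F_subpops[u]
  out
}

# normalized Gaussian kernel row by row
oracle_admix_props <- function(coords, K, sigma) {
  t(vapply(coords, function(cj) {
    w <- exp(-(cj - seq_len(K))^2 / (2 * sigma^2))
    w / sum(w)
  }, numeric(K)))
}

# per-locus standardized cross-product, double loop
oracle_standard_kinship <- function(X) {
  m <- nrow(X); n <- ncol(X)
  p <- rowMeans(X) / 2
  out <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (i in seq_len(m))
      s <- s + (X[i, j] - 2 * p[i]) * (X[i, k] - 2 * p[i]) / (4 * p[i] * (1 - p[i]))
    out[j, k] <- s / m
  }
  out
}

# OLS fit via explicit normal equations for one locus
oracle_ols <- function(y, x, W) {
  D <- cbind(W, x)
  b <- solve(t(D) %*% D, t(D) %*% y)
  res <- y - D %*% b
  df <- length(y) - ncol(D)
  s2 <- sum(res^2) / df
  V <- s2 * solve(t(D) %*% D)
  beta <- b[ncol(D)]
  se <- sqrt(V[ncol(D), ncol(D)])
  list(beta = beta, t = beta / se, p = 2 * stats::pt(-abs(beta / se), df))
}

# GLS score statistic with an explicit dense inverse of a known covariance
oracle_gls_score <- function(y, x, W, V) {
  Vi <- solve(V)
  P <- Vi - Vi %*% W %*% solve(t(W) %*% Vi %*% W) %*% t(W) %*% Vi
  drop((t(x) %*% P %*% y)^2 / (t(x) %*% P %*% x))
}

# pedigree kinship by gene dropping: founders carry unique allele labels,
# each replicate drops alleles independently; kinship = P(IBD of random
# alleles), averaged over n_reps drops
oracle_gene_drop_kinship <- function(ped, n_reps = 1e5) {
  n <- attr(ped, "n")
  G <- max(ped$generation)
  rows_of <- split(seq_len(nrow(ped)), ped$generation)
  a1 <- matrix(rep(seq_len(n) * 2L - 1L, n_reps), n, n_reps)
  a2 <- a1 + 1L
  for (g in seq_len(G)[-1]) {
    rows <- rows_of[[g]]
    prev <- rows_of[[g - 1]]
    pa <- match(ped$father[rows], prev)
    ma <- match(ped$mother[rows], prev)
    pick1 <- matrix(stats::runif(n * n_reps) < 0.5, n, n_reps)
    pick2 <- matrix(stats::runif(n * n_reps) < 0.5, n, n_reps)
    na1 <- ifelse(pick1, a1[pa, , drop = FALSE], a2[pa, , drop = FALSE])
    na2 <- ifelse(pick2, a1[ma, , drop = FALSE], a2[ma, , drop = FALSE])
    a1 <- matrix(na1, n, n_reps)
    a2 <- matrix(na2, n, n_reps)
  }
  K <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in j:n) {
    ibd <- (a1[j, ] == a1[k, ]) + (a1[j, ] == a2[k, ]) +
           (a2[j, ] == a1[k, ]) + (a2[j, ] == a2[k, ])
    K[j, k] <- K[k, j] <- mean(ibd) / 4
  }
  K
}

# tree coancestry by explicit enumeration of common ancestors per leaf pair
oracle_tree_coancestry <- function(parent, delta, leaves, delta0 = 0) {
  anc_of <- function(w) {
    out <- integer(0)
    while (!is.na(w)) { out <- c(out, w); w <- parent[w] }
    out
  }
  L <- length(leaves)
  out <- matrix(delta0, L, L)
  for (a in seq_len(L)) for (b in seq_len(L)) {
    common <- intersect(anc_of(leaves[a]), anc_of(leaves[b]))
    out[a, b] <- out[a, b] + sum(delta[common], na.rm = TRUE)
  }
  out
}

# Hudson-style FST estimator between two samples of allele counts
oracle_hudson_fst <- function(XA, XB) {
  nA <- ncol(XA); nB <- ncol(XB)
  pA <- rowMeans(XA) / 2; pB <- rowMeans(XB) / 2
  num <- (pA - pB)^2 -
    pA * (1 - pA) / (2 * nA - 1) - pB * (1 - pB) / (2 * nB - 1)
  den <- pA * (1 - pB) + pB * (1 - pA)
  sum(num) / sum(den)
}

# precision-recall area by dense numeric integration of the linearly
# interpolated (TP, FP) path over a fine TP grid
oracle_auc_pr <- function(scores, causal, grid = 1e5) {
  ord <- order(scores, decreasing = TRUE)
  cs <- causal[ord]
  ends <- cumsum(rle(scores[ord])$lengths)
  tp <- c(0, cumsum(cs)[ends])
  fp <- c(0, ends - cumsum(cs)[ends])
  P <- sum(causal)
  area <- 0
  for (k in seq_len(length(tp) - 1L)) {
    if (tp[k + 1] == tp[k]) next
    ts <- seq(tp[k], tp[k + 1], length.out = grid)
    fs <- fp[k] + (fp[k + 1] - fp[k]) * (ts - tp[k]) / (tp[k + 1] - tp[k])
    prec <- ts / (ts + fs)
    prec[ts + fs == 0] <- 1
    rec <- ts / P
    area <- area + sum((prec[-1] + prec[-grid]) / 2 * diff(rec))
  }
  area
}

# random admixture dataset used by several test files
make_admix_data <- function(n, K, m, seed, fst = 0.1, ratio = 0.5) {
  set.seed(seed)
  model <- fit_admixture_model(n, K, fst, ratio)
  g <- draw_admixture_genotypes(model, m, want_p_ind = FALSE)
  list(model = model, X = g$X, p_anc = g$p_anc,
       theta = admixture_coancestry(model$Q, model$F_subpops))
}

# random rooted binary tree with K leaves and random edge inbreeding values
make_random_tree <- function(K, f_range = c(0.02, 0.35)) {
  phy <- ape::rtree(K, rooted = TRUE,
                    br = function(n) stats::runif(n, f_range[1], f_range[2]))
  tr <- from_phylo(phy, lengths = "f")
  list(tree = tr, parent = tr$parent)
}
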