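# Quantitative trait simulation with exact narrow-sense heritability:
# y = 1 alpha + X' beta + Z' eta + epsilon.  Causal coefficients follow
# either the fixed effect sizes (FES) model, beta proportional to the
# inverse square root of the allele variance so every causal locus
# contributes the same variance, or the random coefficients (RC) model,
# beta ~ Normal(0,1); both are rescaled so the genetic variance equals h2.

#' Number of causal loci heuristic
#'
#' `m1 = round(n h2 / 8)` (round half to even, as in base R), with a minimum
#' of one causal locus.  The heuristic balances per-locus power across sample
#' sizes and heritabilities.
#'
#' @param n Number of individuals.
#' @param h2 Narrow-sense heritability in (0,1).
#' @return Integer count of causal loci.
#' @export
num_causal <- function(n, h2) {
  if (n < 1) stop("n must be >= 1")
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0,1)")
  max(1L, as.integer(round(n * h2 / 8)))
}

#' Construct causal coefficients calibrated to a heritability
#'
#' Initial coefficients are `1 / sqrt(v_i)` with a random sign (FES; all
#' per-locus effect sizes `2 v_i beta_i^2` equal) or `Normal(0,1)` draws
#' (RC), where `v_i = p_i (1 - p_i)` is the ancestral allele variance of
#' causal locus i.  All coefficients are then multiplied by `h / sigma_0`
#' with `sigma_0^2 = sum_i 2 v_i beta_i^2`, making the genetic variance
#' exactly `h2` under known ancestral frequencies.  The intercept is
#' `alpha = -sum_i 2 p_i beta_i` for known frequencies; with estimated
#' frequencies the bias-avoiding product-of-sums form
#' `alpha = -(2/m1) (sum_i p_i)(sum_i beta_i)` is used and `v` is replaced by
#' the unbiased `p (1-p) / (1 - mean_kinship)`.
#'
#' @param p_causal Ancestral allele frequencies of the causal loci (known
#'   truth), or sample frequencies if `mean_kinship` is supplied.
#' @param h2 Narrow-sense heritability in (0,1).
#' @param model "fes" or "rc".
#' @param mean_kinship Mean kinship estimate; NULL (default) means `p_causal`
#'   are known ancestral frequencies.
#' @return List with `beta`, `alpha`, `h2`, `model`, `sigma_0` (pre-scale
#'   genetic standard deviation).
#' @export
construct_coefficients <- function(p_causal, h2, model = c("fes", "rc"),
                                   mean_kinship = NULL) {
  model <- match.arg(model)
  m1 <- length(p_causal)
  if (m1 < 1) stop("need at least one causal locus")
  v <- p_causal * (1 - p_causal)
  if (any(v <= 0)) stop("causal loci must be polymorphic")
  if (!is.null(mean_kinship)) v <- v / (1 - mean_kinship)
  beta <- switch(model,
    fes = sample(c(-1, 1), m1, replace = TRUE) / sqrt(v),
    rc = stats::rnorm(m1))
  sigma_0 <- sqrt(sum(2 * v * beta^2))
  beta <- beta * sqrt(h2) / sigma_0
  alpha <- if (is.null(mean_kinship)) -sum(2 * p_causal * beta)
           else -(2 / m1) * sum(p_causal) * sum(beta)
  list(beta = beta, alpha = alpha, h2 = h2, model = model, sigma_0 = sigma_0)
}

#' Contiguous environment groups
#'
#' Individual j (in coordinate order) belongs to group `ceiling(j k / n)`,
#' giving k contiguous groups whose sizes differ by at most one.
#'
#' @param n Number of individuals.
#' @param k Number of groups, `1 <= k <= n`.
#' @return List with `groups` (length-n integer vector) and `Z` (k x n 0/1
#'   indicator matrix, groups along rows).
#' @export
make_env_groups <- function(n, k) {
  if (k < 1 || k > n) stop("need 1 <= k <= n")
  groups <- ceiling(seq_len(n) * k / n)
  Z <- matrix(0L, k, n)
  Z[cbind(groups, seq_len(n))] <- 1L
  list(groups = groups, Z = Z)
}

#' Simulate one trait replicate
#'
#' Assembles `y = 1 alpha + X_C' beta + sum_i Z_i' eta_i + epsilon` with
#' `eta_gi ~ Normal(0, env_vars[i])` per environment group and
#' `epsilon_j ~ Normal(0, sigma_eps^2)`, where
#' `sigma_eps^2 = 1 - h2 - sum(env_vars)` must be non-negative.
#'
#' @param X Genotype matrix (loci x individuals).
#' @param causal Integer indices of causal loci (rows of X).
#' @param coeffs Coefficient list from [construct_coefficients()].
#' @param env_vars Vector of per-environment variance proportions (possibly
#'   empty/NULL).
#' @param env_k Number of groups per environment (same length as `env_vars`).
#' @return List with `y`, `genetic`, `env` (matrix of per-environment
#'   contributions or NULL), `resid`, `sigma_eps_sq`, `causal`, `coeffs`.
#' @export
simulate_trait <- function(X, causal, coeffs, env_vars = NULL, env_k = NULL) {
  n <- ncol(X)
  if (length(causal) != length(coeffs$beta))
    stop("causal set and beta lengths differ")
  env_vars <- if (is.null(env_vars)) numeric(0) else env_vars
  sigma_eps_sq <- 1 - coeffs$h2 - sum(env_vars)
  if (sigma_eps_sq < 0)
    stop("infeasible variance partition: h2 + sum(env_vars) > 1")
  genetic <- drop(crossprod(X[causal, , drop = FALSE], coeffs$beta))
  env <- NULL
  if (length(env_vars)) {
    if (length(env_k) != length(env_vars))
      stop("env_k must match env_vars in length")
    env <- sapply(seq_along(env_vars), function(i) {
      eg <- make_env_groups(n, env_k[i])
      eta <- stats::rnorm(env_k[i], 0, sqrt(env_vars[i]))
      eta[eg$groups]
    })
    env <- matrix(env, nrow = n)
  }
  resid <- stats::rnorm(n, 0, sqrt(sigma_eps_sq))
  y <- coeffs$alpha + genetic + (if (is.null(env)) 0 else rowSums(env)) + resid
  list(y = y, genetic = genetic, env = env, resid = resid,
       sigma_eps_sq = sigma_eps_sq, causal = causal, coeffs = coeffs)
}

#' Draw a causal set and simulate a trait in one call
#'
#' Draws `m1` causal loci uniformly from loci with sample MAF at least
#' `maf_min`, builds coefficients (using true ancestral frequencies if
#' `p_anc` is given, else sample frequencies with the mean-kinship
#' correction) and simulates the trait.
#'
#' @param X Genotype matrix (loci x individuals).
#' @param h2 Heritability.
#' @param model "fes" or "rc".
#' @param p_anc Optional true ancestral frequencies (length = nrow(X)).
#' @param mean_kinship Required when `p_anc` is NULL.
#' @param m1 Number of causal loci; default `num_causal(ncol(X), h2)`.
#' @param maf_min Causal loci must have sample MAF >= this (default 0.01).
#' @param env_vars,env_k Passed to [simulate_trait()].
#' @return As [simulate_trait()].
#' @export
simulate_trait_replicate <- function(X, h2, model = c("fes", "rc"),
                                     p_anc = NULL, mean_kinship = NULL,
                                     m1 = num_causal(ncol(X), h2),
                                     maf_min = 0.01,
                                     env_vars = NULL, env_k = NULL) {
  model <- match.arg(model)
  p_hat <- rowMeans(X) / 2
  eligible <- which(pmin(p_hat, 1 - p_hat) >= maf_min)
  if (length(eligible) < m1) stop("not enough loci with MAF >= ", maf_min)
  causal <- sort(eligible[sample.int(length(eligible), m1)])
  if (!is.null(p_anc)) {
    coeffs <- construct_coefficients(p_anc[causal], h2, model)
  } else {
    if (is.null(mean_kinship))
      stop("mean_kinship required when ancestral frequencies are unknown")
    coeffs <- construct_coefficients(p_hat[causal], h2, model, mean_kinship)
  }
  simulate_trait(X, causal, coeffs, env_vars = env_vars, env_k = env_k)
}
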