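# 1D-geography admixture model: K intermediate subpopulations at coordinates
# 1..K, each with total inbreeding f_u = u * tau (linear in position), and
# admixture proportions from a Gaussian kernel of spread sigma around each
# individual's coordinate.  tau and sigma are fit so that the generalized FST
# (mean individual inbreeding) and the ratio of mean kinship to FST hit given
# targets.

#' Individual coordinates on the 1D geography
#'
#' Individuals are evenly spread over `[0.5, K + 0.5]`, the span of the K
#' subpopulation coordinates `1..K`.
#'
#' @param n Number of individuals.
#' @param K Number of intermediate subpopulations.
#' @return Length-n numeric vector of coordinates, increasing.
#' @export
admixture_coords <- function(n, K) {
  0.5 + K * (seq_len(n) - 0.5) / n
}

#' Admixture proportions from a 1D random-walk kernel
#'
#' Computes the n x K admixture proportion matrix Q: individual j at
#' coordinate `c_j` has `q_ju` proportional to `exp(-(c_j - u)^2 / (2 sigma^2))`
#' over subpopulations u = 1..K, normalized to sum to one per individual.
#' As `sigma` grows the rows tend to the uniform 1/K; `sigma = 0` assigns each
#' individual fully to its nearest subpopulation.
#'
#' @param n Number of individuals (>= 1).
#' @param K Number of subpopulations (>= 2).
#' @param sigma Non-negative spread of the kernel.
#' @param coords Optional individual coordinates (default [admixture_coords()]).
#' @return n x K matrix Q with non-negative rows summing to 1.
#' @export
admixture_proportions_1d <- function(n, K, sigma, coords = admixture_coords(n, K)) {
  if (n < 1 || K < 2) stop("need n >= 1 and K >= 2")
  if (sigma < 0) stop("sigma must be non-negative")
  u <- seq_len(K)
  if (sigma == 0) {
    Q <- matrix(0, n, K)
    nearest <- pmin(pmax(round(coords), 1L), K)
    Q[cbind(seq_len(n), nearest)] <- 1
    return(Q)
  }
  D2 <- outer(coords, u, function(a, b) (a - b)^2)
  Q <- exp(-D2 / (2 * sigma^2))
  # guard against underflow at tiny sigma: fall back to nearest assignment
  zero <- rowSums(Q) == 0
  if (any(zero)) {
    nearest <- pmin(pmax(round(coords[zero]), 1L), K)
    Q[zero, ] <- 0
    Q[cbind(which(zero), nearest)] <- 1
  }
  Q / rowSums(Q)
}

#' Coancestry induced by an admixture model
#'
#' For independent intermediate subpopulations with total inbreeding `F[u]`,
#' the coancestry of individuals j and k is
#' `theta_jk = sum_u Q[j,u] Q[k,u] F[u]`.  The diagonal holds the individual
#' inbreeding coefficients.
#'
#' @param Q n x K admixture proportions (rows sum to 1).
#' @param F_subpops Length-K vector of subpopulation inbreeding in `[0,1]`.
#' @return Symmetric n x n coancestry matrix.
#' @export
admixture_coancestry <- function(Q, F_subpops) {
  if (ncol(Q) != length(F_subpops))
    stop("ncol(Q) must equal length(F_subpops)")
  Theta <- Q %*% (F_subpops * t(Q))
  (Theta + t(Theta)) / 2
}

#' Fit the 1D admixture model to FST and mean-kinship targets
#'
#' Calibrates the kernel spread `sigma` and the inbreeding scale `tau`
#' (subpopulation u has total inbreeding `u * tau`) so that the model's
#' generalized FST (mean diagonal of the coancestry matrix, i.e. mean
#' individual inbreeding with uniform weights) equals `fst_target` and the
#' mean off-diagonal coancestry equals `kinship_ratio * fst_target`.
#'
#' The kinship ratio is free of `tau` (both moments are linear in `tau`), so
#' `sigma` is found by one-dimensional root finding on the ratio and `tau` is
#' then set in closed form.  The fit is deterministic.
#'
#' @param n Number of individuals.
#' @param K Number of subpopulations.
#' @param fst_target Target generalized FST in (0,1).
#' @param kinship_ratio Target mean-coancestry / FST ratio in (0,1).
#' @param sigma_range Bracket searched for sigma.
#' @return An object of class `admixture_model`: list with `Q`, `F_subpops`,
#'   `tau`, `sigma`, `coords`, `subpop_coords`, `n`, `K`, `fst`, `kinship_ratio`.
#' @export
fit_admixture_model <- function(n, K, fst_target = 0.1, kinship_ratio = 0.5,
                                sigma_range = c(1e-3, 1e3)) {
  if (fst_target <= 0 || fst_target >= 1) stop("fst_target must be in (0,1)")
  if (kinship_ratio <= 0 || kinship_ratio >= 1) stop("kinship_ratio must be in (0,1)")
  coords <- admixture_coords(n, K)
  w <- seq_len(K)  # F = tau * w; tau cancels in the ratio
  ratio_at <- function(sigma) {
    Q <- admixture_proportions_1d(n, K, sigma, coords)
    Theta <- admixture_coancestry(Q, w)
    fst <- mean(diag(Theta))
    (sum(Theta) - sum(diag(Theta))) / (n * (n - 1)) / fst
  }
  lo <- ratio_at(sigma_range[1])
  hi <- ratio_at(sigma_range[2])
  if (kinship_ratio < min(lo, hi) || kinship_ratio > max(lo, hi))
    stop(sprintf(
      "kinship_ratio %.4g not attainable for n=%d, K=%d: attainable range [%.4g, %.4g]",
      kinship_ratio, n, K, min(lo, hi), max(lo, hi)))
  sigma <- stats::uniroot(function(s) ratio_at(s) - kinship_ratio,
                          interval = sigma_range, tol = 1e-10)$root
  Q <- admixture_proportions_1d(n, K, sigma, coords)
  mean_diag_w <- mean(diag(Q %*% (w * t(Q))))
  tau <- fst_target / mean_diag_w
  F_subpops <- tau * w
  if (max(F_subpops) > 1)
    stop("fitted inbreeding exceeds 1; fst_target too large for this K")
  structure(list(Q = Q, F_subpops = F_subpops, tau = tau, sigma = sigma,
                 coords = coords, subpop_coords = w, n = n, K = K,
                 fst = fst_target, kinship_ratio = kinship_ratio),
            class = "admixture_model")
}

#' @export
print.admixture_model <- function(x, ...) {
  cat(sprintf("1D admixture model: n = %d, K = %d\n", x$n, x$K))
  cat(sprintf("  fitted sigma = %.6g, tau = %.6g\n", x$sigma, x$tau))
  cat(sprintf("  targets: FST = %.4g, mean kinship / FST = %.4g\n",
              x$fst, x$kinship_ratio))
  invisible(x)
}

#' Balding-Nichols allele-frequency draw
#'
#' Draws frequencies with mean `p` and variance `p (1-p) f`
#' (Beta with shape parameters `p (1/f - 1)` and `(1-p)(1/f - 1)`).
#' The limits are handled as the continuous limits of the Beta:
#' `f = 0` returns `p` exactly; `f = 1` returns Bernoulli(`p`) values in \{0,1\}.
#'
#' @param p Vector of mean allele frequencies in (0,1).
#' @param f Single inbreeding coefficient in `[0,1]`.
#' @return Vector of drawn frequencies, same length as `p`.
#' @export
rbalding_nichols <- function(p, f) {
  if (f < 0 || f > 1) stop("f must be in [0,1]")
  if (f == 0) return(p)
  if (f == 1) return(as.numeric(stats::rbinom(length(p), 1L, p)))
  nu <- 1 / f - 1
  stats::rbeta(length(p), p * nu, (1 - p) * nu)
}

#' Draw genotypes from a fitted admixture model
#'
#' Hierarchical draw: ancestral frequencies `p_T` from `p_anc_sampler`
#' (default Uniform(0.01, 0.5)); subpopulation frequencies by
#' Balding-Nichols drift with the model's per-subpopulation inbreeding;
#' individual-specific frequencies `pi = p_S Q'`; genotypes
#' `x ~ Binomial(2, pi)`.  Loci fixed across all individuals (all dosages 0 or
#' all 2) are redrawn from the model starting at `p_T` until none remain.
#'
#' @param model An `admixture_model` (or a list with `Q` and `F_subpops`).
#' @param m Number of loci.
#' @param p_anc_sampler Function of one argument (count) returning ancestral
#'   frequencies in (0,1).
#' @param want_p_ind Keep the m x n individual frequency matrix in the result.
#' @param max_redraws Cap on fixed-locus redraw rounds.
#' @return List with `X` (m x n dosage matrix), `p_anc`, `p_subpops` (m x K),
#'   and `p_ind` (m x n, if requested).
#' @export
draw_admixture_genotypes <- function(model, m,
                                     p_anc_sampler = function(m) stats::runif(m, 0.01, 0.5),
                                     want_p_ind = TRUE, max_redraws = 1000) {
  Q <- model$Q
  F_subpops <- model$F_subpops
  n <- nrow(Q)
  K <- ncol(Q)
  if (m < 1) stop("m must be >= 1")

  draw_block <- function(mm) {
    p_anc <- p_anc_sampler(mm)
    if (any(!is.finite(p_anc)) || any(p_anc <= 0) || any(p_anc >= 1))
      stop("p_anc_sampler must return values in (0,1)")
    p_sub <- vapply(seq_len(K),
                    function(u) rbalding_nichols(p_anc, F_subpops[u]),
                    numeric(mm))
    p_sub <- matrix(p_sub, nrow = mm, ncol = K)
    p_ind <- p_sub %*% t(Q)
    X <- matrix(stats::rbinom(mm * n, 2L, p_ind), nrow = mm, ncol = n)
    list(p_anc = p_anc, p_sub = p_sub, p_ind = p_ind, X = X)
  }

  blk <- draw_block(m)
  for (round in seq_len(max_redraws)) {
    rs <- rowSums(blk$X)
    fixed <- which(rs == 0L | rs == 2L * n)
    if (!length(fixed)) break
    if (round == max_redraws)
      stop("fixed-locus redraw cap exceeded (", max_redraws, " rounds)")
    sub <- draw_block(length(fixed))
    blk$p_anc[fixed] <- sub$p_anc
    blk$p_sub[fixed, ] <- sub$p_sub
    blk$p_ind[fixed, ] <- sub$p_ind
    blk$X[fixed, ] <- sub$X
  }
  rownames(blk$X) <- paste0("snp", seq_len(m))
  colnames(blk$X) <- paste0("ind", seq_len(n))
  out <- list(X = blk$X, p_anc = blk$p_anc, p_subpops = blk$p_sub)
  if (want_p_ind) out$p_ind <- blk$p_ind
  out
}
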