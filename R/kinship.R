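# Kinship and coancestry estimation from genotypes: the standard
# (method-of-moments, mean-centered) estimator, a bias-corrected
# ratio-of-means estimator calibrated so the most-unrelated pairs map to
# coancestry zero, the KING-robust local (pedigree) kinship estimator, and
# greedy relative filtering.

#' Standard kinship estimator
#'
#' Method-of-moments estimator on standardized genotypes:
#' `X_S = (x_ij - 2 p_i) / sqrt(4 p_i (1 - p_i))` with
#' `p_i = mean(x_i) / 2`, and `Phi = X_S' X_S / m`.  Because the
#' standardized rows have zero mean, every row of the estimate sums to zero
#' exactly; the estimator is therefore biased for the true kinship but is the
#' one used by the standard PCA/LMM pipelines.
#'
#' @param X Genotype matrix, loci x individuals, no missing values
#'   (loci with any missing entry are dropped with a warning).
#' @return Symmetric n x n kinship matrix with attribute `flag = "standard"`.
#' @export
standard_kinship <- function(X) {
  if (anyNA(X)) {
    keep <- rowSums(is.na(X)) == 0L
    warning("dropping ", sum(!keep), " loci with missing genotypes")
    X <- X[keep, , drop = FALSE]
  }
  p <- rowMeans(X) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic loci present; filter by MAF before kinship estimation")
  Xs <- (X - 2 * p) / sqrt(4 * p * (1 - p))
  K <- crossprod(Xs) / nrow(X)
  dimnames(K) <- list(colnames(X), colnames(X))
  attr(K, "flag") <- "standard"
  K
}

#' Bias-corrected kinship estimator
#'
#' Ratio-of-means estimator: `A_jk = mean_i (x_ij - 1)(x_ik - 1) - 1` has
#' expectation `-vbar (1 - phi_jk)` where `vbar` is the mean heterozygosity
#' scale, so `Phi = 1 - A / A_min` is unbiased once `A_min` estimates the
#' value of A at kinship zero.  `A_min` is the mean of A over the
#' most-unrelated pairs (the off-diagonal pairs in the lowest
#' `min_pair_quantile` of A).  Selecting extreme pairs on the same noisy A
#' that is then averaged would bias `A_min` downward, so the loci are split
#' in two interleaved halves: each half's unrelated-pair set is chosen on the
#' other half's A, the two half estimates are calibrated separately and then
#' averaged.
#'
#' @param X Genotype matrix, loci x individuals, no missing values.
#' @param min_pair_quantile Fraction of off-diagonal pairs treated as
#'   unrelated for the calibration (default 0.01, at least one pair).
#' @return Symmetric n x n kinship matrix with attribute `flag = "corrected"`.
#' @export
corrected_kinship <- function(X, min_pair_quantile = 0.01) {
  if (anyNA(X)) stop("corrected_kinship requires complete genotypes")
  n <- ncol(X)
  if (n < 3) stop("need at least 3 individuals")
  if (nrow(X) < 2) stop("need at least 2 loci")
  Z <- X - 1
  half <- seq_len(nrow(X)) %% 2 == 0
  A1 <- crossprod(Z[half, , drop = FALSE]) / sum(half) - 1
  A2 <- crossprod(Z[!half, , drop = FALSE]) / sum(!half) - 1
  ut <- upper.tri(A1)
  calibrate <- function(A, A_select) {
    off <- A_select[ut]
    qcut <- stats::quantile(off, min_pair_quantile, names = FALSE)
    A_min <- mean(A[ut][off <= qcut])
    if (A_min >= 0)
      stop("calibration failed: most-unrelated pairs have non-negative A")
    1 - A / A_min
  }
  K <- (calibrate(A1, A2) + calibrate(A2, A1)) / 2
  K <- (K + t(K)) / 2
  dimnames(K) <- list(colnames(X), colnames(X))
  attr(K, "flag") <- "corrected"
  K
}

#' Convert kinship to coancestry
#'
#' Off-diagonal entries are copied; the diagonal is transformed from
#' self-kinship `(1 + f) / 2` to inbreeding `f = 2 phi_jj - 1`.
#'
#' @param K Square symmetric kinship matrix.
#' @return Coancestry matrix of the same shape.
#' @export
coancestry_from_kinship <- function(K) {
  Theta <- K
  diag(Theta) <- 2 * diag(K) - 1
  Theta
}

#' Convert coancestry to kinship (inverse of [coancestry_from_kinship()])
#' @param Theta Coancestry matrix (diagonal = inbreeding).
#' @return Kinship matrix (diagonal = self-kinship `(1+f)/2`).
#' @export
kinship_from_coancestry <- function(Theta) {
  K <- Theta
  diag(K) <- (1 + diag(Theta)) / 2
  K
}

#' KING-robust local kinship estimator
#'
#' Within-pair estimator of recent (pedigree) relatedness, robust to
#' population structure:
#' `phi_jk = (N_Aa,Aa - 2 N_AA,aa) / (N_Aa(j) + N_Aa(k))`, where counts are
#' over loci complete for the pair: both heterozygous, opposite homozygous,
#' and heterozygous in each individual.  Estimates for structured unrelated
#' pairs are negative by design; pairs with no heterozygous loci are NA.
#'
#' @param X Genotype matrix, loci x individuals; NA allowed (pairwise complete).
#' @return Symmetric n x n matrix with attribute `flag = "king"`; the diagonal
#'   equals 1/2 wherever defined.
#' @export
king_robust <- function(X) {
  het <- X == 1L
  hom0 <- X == 0L
  hom2 <- X == 2L
  if (anyNA(X)) {
    ok <- !is.na(X)
    het[is.na(het)] <- FALSE
    hom0[is.na(hom0)] <- FALSE
    hom2[is.na(hom2)] <- FALSE
    mode(ok) <- "numeric"
  } else {
    ok <- NULL
  }
  mode(het) <- "numeric"; mode(hom0) <- "numeric"; mode(hom2) <- "numeric"
  N11 <- crossprod(het)
  Nopp <- crossprod(hom0, hom2)
  Nopp <- Nopp + t(Nopp)
  if (is.null(ok)) {
    nh <- diag(N11)
    denom <- outer(nh, nh, "+")
  } else {
    D <- crossprod(het, ok)  # D[j,k] = het loci of j complete for k
    denom <- D + t(D)
  }
  K <- (N11 - 2 * Nopp) / denom
  if (any(denom == 0)) {
    warning("pairs with no heterozygous loci: estimate undefined, set to NA")
    K[denom == 0] <- NA_real_
  }
  dimnames(K) <- list(colnames(X), colnames(X))
  attr(K, "flag") <- "king"
  K
}

#' Default KING cutoff excluding up to 4th-degree relatives
#'
#' `2^(-11/2) = 0.02209709`, the midpoint (on the log scale) between the
#' expected kinship of 4th- and 5th-degree relatives.
#' @export
king_cutoff_4th_degree <- function() 2^(-11 / 2)

#' Greedy filtering of close relatives
#'
#' While any pair has local kinship at or above the cutoff, removes the
#' individual participating in the most such pairs (ties broken by lowest
#' index), then returns the indices of the kept individuals.
#'
#' @param K Symmetric local kinship matrix (e.g. from [king_robust()]).
#' @param cutoff Kinship threshold; default [king_cutoff_4th_degree()].
#' @return Integer vector of kept individual indices (named if K has dimnames).
#' @export
filter_relatives <- function(K, cutoff = king_cutoff_4th_degree()) {
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(K)
  adj <- !is.na(K) & K >= cutoff
  diag(adj) <- FALSE
  keep <- rep(TRUE, n)
  repeat {
    deg <- rowSums(adj[, keep, drop = FALSE]) * keep
    if (all(deg == 0)) break
    drop <- which.max(deg)  # ties: lowest index
    keep[drop] <- FALSE
  }
  kept <- which(keep)
  if (!is.null(rownames(K))) names(kept) <- rownames(K)[kept]
  kept
}
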