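# Native association scans.  PCA: per-locus ordinary least squares with an
# intercept, r principal components and optional covariates, tested with the
# two-sided t-test.  LMM: variance components fitted once per trait by REML
# under y ~ Normal(W a, 2 sigma_g^2 Phi + sigma_e^2 I), then each locus is
# evaluated with the score test (no per-locus refit).

#' Principal components from genotypes or a kinship matrix
#'
#' Top-r eigenvectors of the standard kinship estimate.  When genotypes are
#' given, loci with minor allele frequency below `maf_min` (default 0.1,
#' matching the usual PC pipeline) are removed first.  The standard estimate
#' has zero row sums, so the returned PCs are orthogonal to the all-ones
#' vector as well as orthonormal.
#'
#' @param X Genotype matrix (loci x individuals), or NULL if `kinship` given.
#' @param r Number of components, `0 <= r < n` (r = 0 returns an n x 0 matrix).
#' @param kinship Optional precomputed kinship matrix (used instead of X).
#' @param maf_min MAF filter applied to X before kinship estimation.
#' @return n x r matrix with orthonormal columns.
#' @export
compute_pcs <- function(X = NULL, r, kinship = NULL, maf_min = 0.1) {
  if (is.null(kinship)) {
    if (is.null(X)) stop("supply genotypes or a kinship matrix")
    p <- rowMeans(X) / 2
    keep <- pmin(p, 1 - p) >= maf_min
    if (!any(keep)) stop("no loci pass the MAF filter")
    kinship <- standard_kinship(X[keep, , drop = FALSE])
  }
  n <- nrow(kinship)
  if (r < 0 || r >= n) stop("need 0 <= r < n")
  if (r == 0) return(matrix(numeric(0), n, 0))
  ev <- eigen(kinship, symmetric = TRUE)
  ev$vectors[, seq_len(r), drop = FALSE]
}

# full-rank check + orthonormal basis of the fixed-effect design
.design_basis <- function(n, U = NULL, covar = NULL) {
  W <- cbind(rep(1, n), U, covar)
  qrW <- qr(W)
  if (qrW$rank < ncol(W))
    stop("fixed-effect design is rank deficient (collinear PCs/covariates)")
  list(W = W, Q = qr.Q(qrW))
}

#' PCA association scan (OLS + t-test)
#'
#' Per locus i fits `y = 1 alpha + x_i beta_i + U gamma + Z' eta + e` by
#' least squares and reports the two-sided t-test of `beta_i = 0` with
#' `n - ncol([1, U, Z]) - 1` degrees of freedom.  Loci whose genotype is
#' collinear with the covariates get NA with a warning.
#'
#' @param X Genotype matrix (loci x individuals).
#' @param y Length-n trait vector.
#' @param U n x r matrix of PCs (may have 0 columns).
#' @param covar Optional additional covariate columns (n x c).
#' @return Data frame: `locus`, `beta`, `stat` (t), `p`; attributes `df`,
#'   `method = "pca"`, `r`.
#' @export
pca_assoc <- function(X, y, U = NULL, covar = NULL) {
  n <- length(y)
  if (ncol(X) != n) stop("X and y dimensions differ")
  d <- .design_basis(n, U, covar)
  Qw <- d$Q
  df <- n - ncol(d$W) - 1L
  if (df < 1) stop("not enough residual degrees of freedom")
  yr <- y - Qw %*% crossprod(Qw, y)
  XQ <- X %*% Qw
  sxx <- rowSums(X^2) - rowSums(XQ^2)
  sxy <- drop(X %*% yr)
  syy <- sum(yr^2)
  tol <- max(rowSums(X^2), 1) * 1e-12
  ok <- sxx > tol
  beta <- stat <- p <- rep(NA_real_, nrow(X))
  beta[ok] <- sxy[ok] / sxx[ok]
  rss <- syy - beta[ok] * sxy[ok]
  rss[rss < 0] <- 0
  se <- sqrt(rss / df / sxx[ok])
  stat[ok] <- beta[ok] / se
  p[ok] <- 2 * stats::pt(-abs(stat[ok]), df)
  if (any(!ok))
    warning(sum(!ok), " loci collinear with covariates: NA results")
  out <- data.frame(locus = if (!is.null(rownames(X))) rownames(X)
                            else seq_len(nrow(X)),
                    beta = beta, stat = stat, p = p)
  attr(out, "df") <- df
  attr(out, "method") <- "pca"
  attr(out, "r") <- if (is.null(U)) 0L else ncol(U)
  out
}

#' REML fit of the LMM null model
#'
#' Fits `y ~ Normal(W a, V)` with `V = 2 sigma_g^2 Phi + sigma_e^2 I` by
#' restricted maximum likelihood.  The generalized eigenstructure reduces the
#' problem to a one-dimensional search over the variance ratio
#' `lambda = sigma_g^2 / sigma_e^2`, optimized by Brent's method on the log
#' scale over `[1e-6, 1e6]` with the residual scale profiled out analytically;
#' the boundary `sigma_g^2 = 0` is also evaluated and kept if better.
#'
#' @param y Length-n trait vector.
#' @param kinship Symmetric n x n kinship matrix Phi.
#' @param U,covar Fixed-effect columns besides the intercept.
#' @param eigen_K Optional precomputed `eigen(2 * kinship, symmetric = TRUE)`.
#' @return Object of class `lmm_null`: `sigma_g_sq`, `sigma_e_sq`, `lambda`,
#'   `logLik_reml`, plus the rotated quantities used by [lmm_assoc()].
#' @export
lmm_null_reml <- function(y, kinship, U = NULL, covar = NULL, eigen_K = NULL) {
  n <- length(y)
  if (is.null(eigen_K)) {
    if (!isSymmetric(unname(kinship), tol = 1e-8))
      stop("kinship matrix must be symmetric")
    eigen_K <- eigen(2 * kinship, symmetric = TRUE)
  }
  d <- pmax(eigen_K$values, 0)
  Uev <- eigen_K$vectors
  des <- .design_basis(n, U, covar)
  p <- ncol(des$W)
  if (n <= p) stop("more fixed effects than observations")
  yt <- drop(crossprod(Uev, y))
  Wt <- crossprod(Uev, des$W)

  # restricted log-likelihood at variance ratio lambda, scale profiled out
  reml_ll <- function(lambda) {
    v <- lambda * d + 1
    wi <- 1 / v
    C <- crossprod(Wt, wi * Wt)
    cf <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(cf)) return(-Inf)
    b <- backsolve(cf, forwardsolve(t(cf), crossprod(Wt, wi * yt)))
    r <- yt - Wt %*% b
    rss <- sum(r^2 * wi)
    -0.5 * ((n - p) * log(rss) + sum(log(v)) + 2 * sum(log(diag(cf))))
  }
  opt <- stats::optimize(function(ll) reml_ll(exp(ll)),
                         interval = log(c(1e-6, 1e6)),
                         maximum = TRUE, tol = 1e-8)
  ll0 <- reml_ll(0)
  if (ll0 >= opt$objective) {
    lambda <- 0
    llbest <- ll0
  } else {
    lambda <- exp(opt$maximum)
    llbest <- opt$objective
  }
  v <- lambda * d + 1
  wi <- 1 / v
  C <- crossprod(Wt, wi * Wt)
  b <- solve(C, crossprod(Wt, wi * yt))
  rss <- sum((yt - Wt %*% b)^2 * wi)
  sigma_e_sq <- rss / (n - p)
  sigma_g_sq <- lambda * sigma_e_sq
  structure(list(sigma_g_sq = sigma_g_sq, sigma_e_sq = sigma_e_sq,
                 lambda = lambda,
                 logLik_reml = llbest - 0.5 * (n - p) * (1 + log(2 * pi) - log(n - p)),
                 eigen_vectors = Uev, eigen_values = d,
                 yt = yt, Wt = Wt, W = des$W, n = n, p = p),
            class = "lmm_null")
}

#' @export
print.lmm_null <- function(x, ...) {
  cat(sprintf("LMM null model (REML): sigma_g^2 = %.4g, sigma_e^2 = %.4g\n",
              x$sigma_g_sq, x$sigma_e_sq))
  cat(sprintf("  variance ratio = %.4g, restricted logLik = %.4f\n",
              x$lambda, x$logLik_reml))
  invisible(x)
}

#' LMM association scan (score test)
#'
#' Fits the null model once per trait with [lmm_null_reml()], then evaluates
#' each locus with the score statistic `(x' P y)^2 / (x' P x)` where P is the
#' projection onto the orthocomplement of the fixed effects under the null
#' covariance; p-values from the chi-square distribution with 1 df.
#'
#' @param X Genotype matrix (loci x individuals).
#' @param y Length-n trait vector.
#' @param kinship Kinship matrix for the random effect (standard estimator by
#'   default in the pipelines; any symmetric matrix accepted).
#' @param U,covar Fixed-effect columns besides the intercept.
#' @param null_fit Optional precomputed `lmm_null` (must match U/covar).
#' @return Data frame: `locus`, `beta`, `stat` (chi-square, 1 df), `p`;
#'   attributes `method = "lmm"`, `r`, `varcomp`.
#' @export
lmm_assoc <- function(X, y, kinship, U = NULL, covar = NULL, null_fit = NULL) {
  if (is.null(null_fit))
    null_fit <- lmm_null_reml(y, kinship, U = U, covar = covar)
  n <- null_fit$n
  if (ncol(X) != n) stop("X and y dimensions differ")
  wi <- 1 / (null_fit$sigma_g_sq * null_fit$eigen_values + null_fit$sigma_e_sq)
  Wt <- null_fit$Wt
  yt <- null_fit$yt
  C <- crossprod(Wt, wi * Wt)
  b <- solve(C, crossprod(Wt, wi * yt))
  Py_rot <- wi * (yt - drop(Wt %*% b))       # rotated P y
  Xt <- X %*% null_fit$eigen_vectors          # m x n rotated genotypes
  num <- drop(Xt %*% Py_rot)
  B <- Xt %*% (wi * Wt)                       # m x p
  xPx <- drop(Xt^2 %*% wi) - rowSums((B %*% solve(C)) * B)
  tol <- 1e-10 * max(xPx, 1)
  ok <- xPx > tol
  stat <- p <- beta <- rep(NA_real_, nrow(X))
  stat[ok] <- num[ok]^2 / xPx[ok]
  beta[ok] <- num[ok] / xPx[ok]
  p[ok] <- stats::pchisq(stat[ok], df = 1, lower.tail = FALSE)
  if (any(!ok))
    warning(sum(!ok), " loci collinear with covariates: NA results")
  out <- data.frame(locus = if (!is.null(rownames(X))) rownames(X)
                            else seq_len(nrow(X)),
                    beta = beta, stat = stat, p = p)
  attr(out, "method") <- "lmm"
  attr(out, "r") <- if (is.null(U)) 0L else ncol(U)
  attr(out, "varcomp") <- null_fit[c("sigma_g_sq", "sigma_e_sq", "lambda",
                                     "logLik_reml")]
  out
}
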