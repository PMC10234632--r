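# Scoring of association scans: SRMSDp measures departure of the null
# p-value distribution from uniform (signed: positive = anti-conservative),
# AUCPR measures causal-locus classification with the nonlinear
# precision-recall interpolation, and the genomic inflation factor lambda is
# kept as an auxiliary diagnostic.

#' Signed root-mean-square deviation of null p-values from uniform
#'
#' Sorted null p-values `p_(i)` are compared with the expected uniform
#' quantiles `u_i = (i - 0.5) / m0`; the root-mean-square deviation is signed
#' by `sgn(1/2 - median(p))` (sign of zero taken as +1), so positive values
#' flag anti-conservative p-values and negative values conservative ones.
#' The statistic is bounded by +/- 1/sqrt(3) = 0.577, the all-zero (or
#' all-one) p-value limit.
#'
#' @param pvals Vector of null-locus p-values in `[0,1]`.
#' @return Signed real in `[-1/sqrt(3), 1/sqrt(3)]`.
#' @export
srmsd_p <- function(pvals) {
  if (!length(pvals)) stop("empty p-value vector")
  if (anyNA(pvals)) pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) stop("all p-values missing")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must be in [0,1]")
  m0 <- length(pvals)
  ps <- sort(pvals)
  u <- (seq_len(m0) - 0.5) / m0
  rmsd <- sqrt(mean((u - ps)^2))
  s <- if (0.5 - stats::median(ps) >= 0) 1 else -1
  s * rmsd
}

#' Area under the precision-recall curve
#'
#' Ranks loci by `scores` (larger = more significant; ties enter together)
#' and integrates precision over recall using the nonlinear interpolation
#' between operating points: between consecutive points the false-positive
#' count is a linear function of the true-positive count, so the precision
#' segment integrates in closed form.  A random ranking has expected AUCPR
#' equal to the causal fraction; perfect separation gives 1.
#'
#' @param scores Numeric vector (e.g. -log10 p-values).
#' @param causal_mask Logical vector, TRUE at causal loci.
#' @return Area in `[0, 1]`.
#' @export
auc_pr <- function(scores, causal_mask) {
  if (length(scores) != length(causal_mask))
    stop("scores and causal_mask lengths differ")
  ok <- !is.na(scores)
  scores <- scores[ok]
  causal_mask <- as.logical(causal_mask)[ok]
  P <- sum(causal_mask)
  if (P == 0 || P == length(scores))
    stop("need at least one causal and one non-causal locus")
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]
  cs <- causal_mask[ord]
  ends <- cumsum(rle(sc)$lengths)  # last index of each tied score group
  tp <- cumsum(cs)[ends]
  fp <- ends - tp
  tp <- c(0, tp)
  fp <- c(0, fp)
  area <- 0
  for (k in seq_len(length(tp) - 1L)) {
    dtp <- tp[k + 1L] - tp[k]
    if (dtp == 0) next  # vertical segment: recall unchanged
    s <- (fp[k + 1L] - fp[k]) / dtp
    a <- fp[k] - s * tp[k]
    # integral of t / ((1+s) t + a) dt over [tp_k, tp_{k+1}]
    seg <- function(t) t / (1 + s) -
      if (a != 0) a / (1 + s)^2 * log((1 + s) * t + a) else 0
    area <- area + (seg(tp[k + 1L]) - seg(tp[k]))
  }
  area / P
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(p, 1, lower = FALSE)) / qchisq(0.5, 1)`; equals 1
#' for calibrated p-values, above 1 for inflated (anti-conservative) ones.
#' Zero p-values are clipped to the smallest positive double.
#'
#' @param pvals Vector of p-values in `[0,1]`.
#' @return Positive real.
#' @export
inflation_lambda <- function(pvals) {
  if (!length(pvals)) stop("empty p-value vector")
  pvals <- pvals[!is.na(pvals)]
  pvals[pvals == 0] <- .Machine$double.xmin
  chi <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}
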