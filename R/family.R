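# Random admixed pedigrees: iterative generation construction with random
# sex, geographically assortative pairing subject to a local-kinship cutoff,
# Poisson family sizes rebalanced to a fixed generation size, kinship
# recursion through the pedigree, and genotype dropping.

#' Simulate a random multi-generation pedigree
#'
#' Generation 1 is the `n` founders (locally unrelated and outbred), ordered
#' by coordinate.  Each later generation is built by: random sex assignment
#' (done at creation); drawing males in random order and pairing each with the
#' nearest available female whose local kinship is below `cutoff` (the male
#' stays unpaired if none qualifies); drawing the number of children per
#' family as `n_min + Poisson(n / n_f - n_min)` where `n_f` is the number of
#' families; rebalancing family sizes by incrementing or decrementing random
#' families until the generation size is exactly `n`; and ordering children by
#' the mean coordinate of their parents.
#'
#' @param founder_coords Length-n vector of founder coordinates, sorted
#'   increasing (e.g. `admixture_coords(n, K)`).
#' @param n_generations Number of generations G (G = 1 returns founders only).
#' @param cutoff Local-kinship pairing cutoff; default `1/4^3` excludes
#'   second cousins and closer.
#' @param n_min Minimum number of children per family.
#' @return Object of class `pedigree`: data frame with columns `id`,
#'   `generation`, `father`, `mother` (row ids, NA for founders), `sex`
#'   (1 = male, 2 = female), `coord`; attribute `n` = generation size.
#' @export
draw_pedigree <- function(founder_coords, n_generations, cutoff = 1 / 4^3,
                          n_min = 1L) {
  n <- length(founder_coords)
  if (n < 2) stop("need at least 2 founders")
  if (is.unsorted(founder_coords)) stop("founders must be ordered by coordinate")
  if (cutoff <= 0 || cutoff > 0.5) stop("cutoff must be in (0, 1/2]")
  if (n_generations < 1) stop("need n_generations >= 1")

  ped <- data.frame(id = seq_len(n), generation = 1L,
                    father = NA_integer_, mother = NA_integer_,
                    sex = sample(c(1L, 2L), n, replace = TRUE),
                    coord = founder_coords)
  kin_prev <- diag(n) / 2  # local kinship of current generation
  prev_rows <- seq_len(n)

  for (g in seq_len(n_generations)[-1]) {
    sex <- ped$sex[prev_rows]
    coord <- ped$coord[prev_rows]
    males <- which(sex == 1L)
    avail_f <- which(sex == 2L)
    if (!length(males) || !length(avail_f))
      stop("population collapse at generation ", g, ": missing one sex")
    pairs_f <- integer(0)
    pairs_m <- integer(0)
    male_order <- if (length(males) == 1L) males else sample(males)
    for (mi in male_order) {
      if (!length(avail_f)) break
      okf <- avail_f[kin_prev[mi, avail_f] < cutoff]
      if (!length(okf)) next  # male stays unpaired
      d <- abs(coord[okf] - coord[mi])
      fi <- okf[which.min(d)]  # ties: lowest index (which.min is first-min)
      pairs_m <- c(pairs_m, mi)
      pairs_f <- c(pairs_f, fi)
      avail_f <- setdiff(avail_f, fi)
    }
    n_f <- length(pairs_m)
    if (n_f == 0L) stop("population collapse at generation ", g, ": no valid pairs")

    kids <- n_min + stats::rpois(n_f, max(n / n_f - n_min, 0))
    repeat {
      delta <- n - sum(kids)
      if (delta == 0L) break
      if (delta > 0L) {
        inc <- if (delta >= n_f) seq_len(n_f) else sample(n_f, delta)
        kids[inc] <- kids[inc] + 1L
      } else {
        elig <- which(kids >= n_min + 1L)
        if (!length(elig))
          stop("cannot rebalance generation ", g, " down to size ", n)
        dec <- if (-delta >= length(elig)) elig
               else elig[sample.int(length(elig), -delta)]
        kids[dec] <- kids[dec] - 1L
      }
    }

    fam <- rep.int(seq_len(n_f), kids)
    child_coord <- (coord[pairs_m[fam]] + coord[pairs_f[fam]]) / 2
    ord <- order(child_coord)
    fam <- fam[ord]
    child_coord <- child_coord[ord]
    new_rows <- nrow(ped) + seq_len(n)
    ped <- rbind(ped, data.frame(
      id = new_rows, generation = g,
      father = prev_rows[pairs_m[fam]], mother = prev_rows[pairs_f[fam]],
      sex = sample(c(1L, 2L), n, replace = TRUE),
      coord = child_coord))

    # kinship of the new generation from the previous one
    pa <- pairs_m[fam]; ma <- pairs_f[fam]
    kin_new <- 0.25 * (kin_prev[pa, pa] + kin_prev[pa, ma] +
                       kin_prev[ma, pa] + kin_prev[ma, ma])
    diag(kin_new) <- 0.5 * (1 + kin_prev[cbind(pa, ma)])
    kin_prev <- kin_new
    prev_rows <- new_rows
  }
  structure(ped, class = c("pedigree", "data.frame"), n = n)
}

#' @export
print.pedigree <- function(x, ...) {
  G <- max(x$generation)
  cat(sprintf("pedigree: %d generations x %d individuals\n", G, attr(x, "n")))
  NextMethod()
}

#' Pedigree kinship by recursion
#'
#' Computes per-generation kinship matrices using the standard recursion:
#' `phi(child, x) = (phi(father, x) + phi(mother, x)) / 2` for `x` in the
#' parental generation, and self-kinship
#' `phi(child, child) = (1 + phi(father, mother)) / 2`.  With
#' `founder_coancestry = NULL` the founders are unrelated and outbred (local
#' kinship); supplying the founders' ancestry-induced coancestry yields total
#' kinship combining population structure and the family.
#'
#' @param ped A `pedigree` from [draw_pedigree()].
#' @param founder_coancestry Optional n x n founder coancestry matrix
#'   (diagonal = inbreeding); NULL for local kinship.
#' @return List of per-generation n x n kinship matrices.
#' @export
pedigree_kinship <- function(ped, founder_coancestry = NULL) {
  n <- attr(ped, "n")
  G <- max(ped$generation)
  K1 <- if (is.null(founder_coancestry)) diag(n) / 2
        else kinship_from_coancestry(founder_coancestry)
  out <- vector("list", G)
  out[[1]] <- K1
  rows_of <- split(seq_len(nrow(ped)), ped$generation)
  for (g in seq_len(G)[-1]) {
    rows <- rows_of[[g]]
    prev <- rows_of[[g - 1]]
    pa <- match(ped$father[rows], prev)
    ma <- match(ped$mother[rows], prev)
    if (anyNA(pa) || anyNA(ma))
      stop("invalid pedigree: parents not in previous generation")
    Kp <- out[[g - 1]]
    Kg <- 0.25 * (Kp[pa, pa] + Kp[pa, ma] + Kp[ma, pa] + Kp[ma, ma])
    diag(Kg) <- 0.5 * (1 + Kp[cbind(pa, ma)])
    out[[g]] <- Kg
  }
  out
}

#' Drop genotypes through a pedigree
#'
#' Each child draws one allele from each parent independently per locus: the
#' transmitted allele from a parent with dosage d is Bernoulli(d/2), so the
#' child dosage is the sum of the two transmitted alleles.
#'
#' @param ped A `pedigree`.
#' @param founder_X Genotype matrix (loci x founders) for generation 1.
#' @param last_only Return only the last generation's matrix (default) or a
#'   list of per-generation matrices.
#' @return m x n dosage matrix of the last generation (or list of matrices).
#' @export
drop_genotypes <- function(ped, founder_X, last_only = TRUE) {
  n <- attr(ped, "n")
  if (ncol(founder_X) != n)
    stop("founder_X must have one column per founder")
  m <- nrow(founder_X)
  G <- max(ped$generation)
  rows_of <- split(seq_len(nrow(ped)), ped$generation)
  Xg <- founder_X
  all_gens <- if (last_only) NULL else vector("list", G)
  if (!last_only) all_gens[[1]] <- Xg
  for (g in seq_len(G)[-1]) {
    rows <- rows_of[[g]]
    prev <- rows_of[[g - 1]]
    pa <- match(ped$father[rows], prev)
    ma <- match(ped$mother[rows], prev)
    Xp <- Xg[, pa, drop = FALSE]
    Xm <- Xg[, ma, drop = FALSE]
    Xc <- matrix(stats::rbinom(m * n, 1L, Xp / 2) +
                 stats::rbinom(m * n, 1L, Xm / 2), nrow = m)
    colnames(Xc) <- paste0("g", g, "_", seq_len(n))
    rownames(Xc) <- rownames(founder_X)
    Xg <- Xc
    if (!last_only) all_gens[[g]] <- Xg
  }
  if (last_only) Xg else all_gens
}
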