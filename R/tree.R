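# Subpopulation trees: allele frequencies drift down a rooted tree by
# per-edge Balding-Nichols draws.  Per-edge inbreeding coefficients f
# (relative to the parent) convert to "additive edges" delta whose sums over
# common ancestors give coancestry; trees are fitted back from coancestry
# estimates by WPGMA clustering plus non-negative least squares.

#' Construct a subpopulation tree
#'
#' @param parent Integer vector: `parent[w]` is the parent node of node w
#'   (NA for the root).  Leaves are the nodes that are no one's parent.
#' @param labels Node labels (leaf labels name subpopulations).
#' @param f_edge Optional per-edge inbreeding `f` in `[0,1]` (NA at root).
#' @param delta Optional per-edge additive values (NA at root).
#' @param delta0 Fitted intercept, treated as an extra root edge when
#'   converting delta to f but ignored when simulating; default 0.
#' @return Object of class `subpop_tree` with fields `parent`, `labels`,
#'   `f_edge`, `delta`, `f_total`, `delta0`, `root`, `leaves`, `order`
#'   (a preorder of the nodes).
#' @export
subpop_tree <- function(parent, labels = NULL, f_edge = NULL, delta = NULL,
                        delta0 = 0) {
  N <- length(parent)
  root <- which(is.na(parent))
  if (length(root) != 1) stop("tree must have exactly one root")
  leaves <- setdiff(seq_len(N), parent[!is.na(parent)])
  if (is.null(labels)) labels <- paste0("S", seq_len(N))
  # preorder: parents before children
  ord <- root
  remaining <- setdiff(seq_len(N), root)
  while (length(remaining)) {
    nxt <- remaining[parent[remaining] %in% ord]
    if (!length(nxt)) stop("cyclic or disconnected tree")
    ord <- c(ord, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  tr <- structure(list(parent = parent, labels = labels, f_edge = f_edge,
                       delta = delta, f_total = NULL, delta0 = delta0,
                       root = root, leaves = sort(leaves), order = ord),
                  class = "subpop_tree")
  if (!is.null(f_edge) || !is.null(delta)) tr <- additive_edges(tr)
  tr
}

#' Fill in additive edges and cumulative inbreeding
#'
#' Given per-edge inbreeding `f_edge` (each node's inbreeding relative to its
#' parent), computes for every non-root node the cumulative inbreeding
#' `f_total[w] = f_total[parent] + delta[w]` with additive edge
#' `delta[w] = f_edge[w] * (1 - f_total[parent])`; or, given `delta`, inverts
#' the map via `f_edge[w] = delta[w] / (1 - f_total[parent])`.  When a fitted
#' intercept `delta0` is present it acts as an additional edge above the root
#' for this conversion (the root's cumulative inbreeding starts at `delta0`).
#'
#' @param tree A `subpop_tree` with `f_edge` or `delta` set.
#' @return The tree with `f_edge`, `delta`, `f_total` all filled.
#' @export
additive_edges <- function(tree) {
  from_f <- !is.null(tree$f_edge)
  src <- if (from_f) tree$f_edge else tree$delta
  if (is.null(src)) stop("tree has neither f_edge nor delta")
  if (from_f && any(src[-tree$root] < 0 | src[-tree$root] > 1, na.rm = TRUE))
    stop("edge inbreeding coefficients must be in [0,1]")
  N <- length(tree$parent)
  f_total <- numeric(N)
  delta <- if (from_f) rep(NA_real_, N) else tree$delta
  f_edge <- if (from_f) tree$f_edge else rep(NA_real_, N)
  f_total[tree$root] <- tree$delta0
  for (w in tree$order[-1]) {
    fp <- f_total[tree$parent[w]]
    if (from_f) {
      delta[w] <- f_edge[w] * (1 - fp)
    } else {
      f_edge[w] <- if (fp < 1) delta[w] / (1 - fp) else 0
    }
    f_total[w] <- fp + delta[w]
  }
  tree$delta <- delta
  tree$f_edge <- f_edge
  tree$f_total <- f_total
  tree
}

#' @export
print.subpop_tree <- function(x, ...) {
  cat(sprintf("subpopulation tree: %d nodes, %d leaves, delta0 = %.4g\n",
              length(x$parent), length(x$leaves), x$delta0))
  invisible(x)
}

# logical leaves x nodes matrix: is leaf u a descendant of (or equal to) node w
.tree_leafsets <- function(tree) {
  N <- length(tree$parent)
  L <- length(tree$leaves)
  anc <- matrix(FALSE, L, N)
  for (li in seq_along(tree$leaves)) {
    w <- tree$leaves[li]
    while (!is.na(w)) {
      anc[li, w] <- TRUE
      w <- tree$parent[w]
    }
  }
  anc
}

#' Coancestry matrix implied by a subpopulation tree
#'
#' The coancestry of subpopulations u and v is the sum of the additive edges
#' `delta[w]` over all common ancestor nodes w of u and v (a node counts as
#' its own ancestor), plus the intercept `delta0` if set.  The diagonal equals
#' the leaves' cumulative inbreeding.
#'
#' @param tree A `subpop_tree` with `delta` filled.
#' @param include_delta0 Add `delta0` to every entry (default TRUE).
#' @return K x K symmetric coancestry matrix over leaves.
#' @export
tree_coancestry <- function(tree, include_delta0 = TRUE) {
  if (is.null(tree$delta)) stop("tree has no additive edges; run additive_edges()")
  anc <- .tree_leafsets(tree)
  L <- nrow(anc)
  Theta <- matrix(if (include_delta0) tree$delta0 else 0, L, L)
  for (w in seq_along(tree$parent)) {
    if (w == tree$root) next
    members <- anc[, w]
    Theta[members, members] <- Theta[members, members] + tree$delta[w]
  }
  leaf_labels <- tree$labels[tree$leaves]
  dimnames(Theta) <- list(leaf_labels, leaf_labels)
  Theta
}

#' Draw genotypes from a subpopulation tree
#'
#' Ancestral frequencies from `p_anc_sampler` evolve down the tree by
#' per-edge Balding-Nichols draws with the edge inbreeding `f_edge`
#' (the fitted intercept `delta0` is ignored); each individual in leaf
#' subpopulation u draws `Binomial(2, p_u)`.  Loci with sample minor allele
#' frequency below `maf_min` are redrawn from the top until none remain.
#'
#' @param tree A `subpop_tree` with `f_edge` filled.
#' @param n_per_subpop Individuals per leaf (scalar or per-leaf vector).
#' @param m Number of loci.
#' @param p_anc_sampler Ancestral frequency sampler (default Uniform(0.01, 0.5)).
#' @param maf_min Minimum sample MAF in `[0, 0.5)`; default 0.01.
#' @param max_redraws Cap on redraw rounds.
#' @return List with `X` (m x n dosages), `labels` (subpopulation of each
#'   individual), `p_anc`, `p_leaves` (m x K leaf frequencies).
#' @export
draw_tree_genotypes <- function(tree, n_per_subpop, m,
                                p_anc_sampler = function(m) stats::runif(m, 0.01, 0.5),
                                maf_min = 0.01, max_redraws = 1000) {
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must be in [0, 0.5)")
  L <- length(tree$leaves)
  n_per <- rep_len(n_per_subpop, L)
  n <- sum(n_per)
  labels <- rep(tree$labels[tree$leaves], n_per)

  draw_block <- function(mm) {
    p_anc <- p_anc_sampler(mm)
    N <- length(tree$parent)
    P <- matrix(NA_real_, mm, N)
    P[, tree$root] <- p_anc
    for (w in tree$order[-1])
      P[, w] <- rbalding_nichols(P[, tree$parent[w]], tree$f_edge[w])
    p_leaves <- P[, tree$leaves, drop = FALSE]
    X <- matrix(stats::rbinom(mm * n, 2L, p_leaves[, rep(seq_len(L), n_per)]),
                nrow = mm, ncol = n)
    list(p_anc = p_anc, p_leaves = p_leaves, X = X)
  }

  blk <- draw_block(m)
  for (round in seq_len(max_redraws)) {
    p_hat <- rowMeans(blk$X) / 2
    maf <- pmin(p_hat, 1 - p_hat)
    bad <- which(maf < maf_min)
    if (!length(bad)) break
    if (round == max_redraws)
      stop("MAF redraw cap exceeded (", max_redraws, " rounds)")
    sub <- draw_block(length(bad))
    blk$p_anc[bad] <- sub$p_anc
    blk$p_leaves[bad, ] <- sub$p_leaves
    blk$X[bad, ] <- sub$X
  }
  rownames(blk$X) <- paste0("snp", seq_len(m))
  colnames(blk$X) <- paste0(labels, "_", stats::ave(seq_len(n), labels, FUN = seq_along))
  list(X = blk$X, labels = labels, p_anc = blk$p_anc, p_leaves = blk$p_leaves)
}

#' Subpopulation-level coancestry from individual coancestry
#'
#' Averages individual coancestry over all ordered pairs of members of each
#' pair of subpopulations (including self-pairs on the diagonal blocks, whose
#' diagonal terms are the individual inbreeding coefficients).
#'
#' @param Theta n x n individual coancestry matrix (diagonal = inbreeding,
#'   e.g. from [coancestry_from_kinship()]).
#' @param labels Length-n subpopulation labels.
#' @return K x K symmetric matrix, dimnames = sorted unique labels.
#' @export
subpop_coancestry <- function(Theta, labels) {
  if (length(labels) != nrow(Theta)) stop("labels must match matrix dimension")
  groups <- sort(unique(labels))
  idx <- lapply(groups, function(g) which(labels == g))
  if (any(lengths(idx) == 0)) stop("empty subpopulation")
  K <- length(groups)
  out <- matrix(NA_real_, K, K, dimnames = list(groups, groups))
  for (u in seq_len(K)) for (v in u:K) {
    out[u, v] <- out[v, u] <- mean(Theta[idx[[u]], idx[[v]]])
  }
  out
}

#' Fit a subpopulation tree to a coancestry matrix
#'
#' Topology by WPGMA hierarchical clustering with the distance
#' `d(u, v) = max(Theta) - Theta[u, v]` (coancestry is monotone in the depth
#' of the most recent common ancestor); edge values by non-negative least
#' squares regression of the coancestry entries on the common-ancestor
#' indicators of the fitted topology, with an all-ones intercept column whose
#' coefficient `delta0` (also constrained non-negative) absorbs small
#' estimation biases.  Edge inbreeding coefficients are recovered from the
#' additive edges treating `delta0` as an extra root edge.
#'
#' @param Theta K x K symmetric subpopulation coancestry matrix
#'   (dimnames used as leaf labels).
#' @return A `subpop_tree` with `delta`, `f_edge`, `f_total`, `delta0` filled.
#' @export
fit_tree <- function(Theta) {
  K <- nrow(Theta)
  if (K < 2) stop("need at least 2 subpopulations")
  labels_in <- rownames(Theta)
  if (is.null(labels_in)) labels_in <- paste0("S", seq_len(K))
  D <- max(Theta) - Theta
  hc <- stats::hclust(stats::as.dist(D), method = "mcquitty")

  # nodes: leaves 1..K, internal K+i for merge i; root = node of last merge
  N <- 2L * K - 1L
  parent <- rep(NA_integer_, N)
  for (i in seq_len(K - 1L)) {
    for (ch in hc$merge[i, ]) {
      node <- if (ch < 0) -ch else K + ch
      parent[node] <- K + i
    }
  }
  labels <- c(labels_in, paste0("N", seq_len(K - 1L)))
  root <- N

  tr <- subpop_tree(parent, labels)
  anc <- .tree_leafsets(tr)  # leaves x nodes
  # design over unordered pairs (u <= v): columns = non-root nodes + intercept
  pairs <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  nodes <- setdiff(seq_len(N), root)
  A <- matrix(0, nrow(pairs), length(nodes) + 1L)
  for (ci in seq_along(nodes)) {
    w <- nodes[ci]
    A[, ci] <- anc[pairs[, 1], w] & anc[pairs[, 2], w]
  }
  A[, length(nodes) + 1L] <- 1
  b <- Theta[pairs]
  fit <- pracma::lsqnonneg(A, b)
  delta <- rep(NA_real_, N)
  delta[nodes] <- fit$x[seq_along(nodes)]
  tr$delta0 <- fit$x[length(nodes) + 1L]
  tr$delta <- delta
  additive_edges(tr)
}

#' Convert a subpopulation tree to an ape `phylo` object
#'
#' Branch lengths carry the additive edges `delta`; the intercept `delta0`
#' is stored as the root edge.
#'
#' @param tree A `subpop_tree`.
#' @return An object of class `phylo`.
#' @export
as_phylo <- function(tree) {
  N <- length(tree$parent)
  L <- length(tree$leaves)
  internal <- c(tree$root, setdiff(which(!(seq_len(N) %in% tree$leaves)), tree$root))
  ape_id <- integer(N)
  ape_id[tree$leaves] <- seq_len(L)
  ape_id[internal] <- L + seq_along(internal)
  nonroot <- setdiff(seq_len(N), tree$root)
  edge <- cbind(ape_id[tree$parent[nonroot]], ape_id[nonroot])
  lens <- if (!is.null(tree$delta)) tree$delta[nonroot] else rep(0, length(nonroot))
  phy <- list(edge = edge, tip.label = tree$labels[tree$leaves],
              Nnode = length(internal), edge.length = lens,
              node.label = tree$labels[internal], root.edge = tree$delta0)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Build a `subpop_tree` from an ape `phylo` object
#'
#' Branch lengths are interpreted as either additive edges (`delta`) or
#' per-edge inbreeding coefficients (`f`).
#'
#' @param phy An ape `phylo` tree (rooted).
#' @param lengths One of "delta" or "f".
#' @return A `subpop_tree`.
#' @export
from_phylo <- function(phy, lengths = c("delta", "f")) {
  lengths <- match.arg(lengths)
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  N <- ape::Ntip(phy) + phy$Nnode
  parent <- rep(NA_integer_, N)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  vals <- rep(NA_real_, N)
  if (!is.null(phy$edge.length)) vals[phy$edge[, 2]] <- phy$edge.length
  labels <- c(phy$tip.label,
              if (!is.null(phy$node.label) && length(phy$node.label) == phy$Nnode)
                phy$node.label else paste0("N", seq_len(phy$Nnode)))
  delta0 <- if (!is.null(phy$root.edge)) phy$root.edge else 0
  if (lengths == "delta")
    subpop_tree(parent, labels, delta = vals, delta0 = delta0)
  else
    subpop_tree(parent, labels, f_edge = vals, delta0 = delta0)
}

#' Write a fitted tree as newick (delta as branch lengths)
#' @param tree A `subpop_tree`.
#' @param path Output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(as_phylo(tree), file = path)
  invisible(path)
}

#' Read a newick tree into a `subpop_tree`
#' @param path Newick file.
#' @param lengths Interpretation of branch lengths ("delta" or "f").
#' @export
read_tree_newick <- function(path, lengths = c("delta", "f")) {
  from_phylo(ape::read.tree(path), lengths = lengths)
}
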