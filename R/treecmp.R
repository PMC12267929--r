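# Tree building (for synthetic validation) and comparison of the two
# organellar phylogenies: p-distances, neighbor-joining,
# Robinson-Foulds distance, tanglegram crossing minimization, and
# polytomy / low-support summaries.

#' Pairwise p-distance matrix of an alignment
#'
#' Entry = mismatches / compared sites with pairwise deletion of
#' gap/ambiguity columns.
#' @param alignment a [dna_alignment] with >= 3 sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(alignment) {
  mat <- alignment$matrix
  if (nrow(mat) < 3) stop_ob("need >= 3 sequences")
  pw <- pairwise_stats(alignment)
  if (any(pw$compared == 0))
    stop_ob("a pair of sequences shares no compared sites")
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (p in seq_along(pw$i))
    d[pw$i[p], pw$j[p]] <- d[pw$j[p], pw$i[p]] <-
      pw$diffs[p] / pw$compared[p]
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ; negative branch lengths are clamped to zero with the
#' deficit shifted to the sister edge so path lengths are preserved.
#'
#' @param d symmetric distance matrix with row/col names.
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop_ob("need >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop_ob("distance matrix is not symmetric")
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    sib <- which(tr$edge[, 1] == tr$edge[e, 1] & seq_along(tr$edge[, 1]) != e)
    if (length(sib)) tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
  }
  tr
}

# nontrivial bipartitions of an unrooted tree as canonical keys
bipartition_keys <- function(tr) {
  tr <- ape::unroot(tr)
  n <- ape::Ntip(tr)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  keys <- character(0)
  for (s in pp) {
    side <- labs[s]
    if (length(side) < 2 || length(side) > n - 2) next
    # canonical side: the one NOT containing the alphabetically first leaf
    if (sort(labs)[1] %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of nontrivial bipartitions (trees
#' compared unrooted), normalized by `2 * (n - 3)`.
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return list `rf` (integer) and `normalized` (in [0, 1]).
#' @export
rf_distance <- function(t1, t2) {
  d1 <- setdiff(t1$tip.label, t2$tip.label)
  d2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(d1) || length(d2))
    stop_ob("leaf sets differ: only in tree1 {%s}; only in tree2 {%s}",
            paste(d1, collapse = ","), paste(d2, collapse = ","))
  k1 <- bipartition_keys(t1)
  k2 <- bipartition_keys(t2)
  rf <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
  n <- ape::Ntip(t1)
  norm <- if (n > 3) rf / (2 * (n - 3)) else 0
  list(rf = rf, normalized = norm)
}

# children lists + per-node child order from a phylo edge matrix
tree_kids <- function(tr) {
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  lapply(kids, as.integer)
}

leaf_order <- function(tr, kids, flip = NULL) {
  n <- ape::Ntip(tr)
  root <- n + 1L
  out <- integer(0)
  stack <- list(root)
  while (length(stack)) {
    x <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (x <= n) { out <- c(out, x); next }
    ch <- kids[[as.character(x)]]
    if (!is.null(flip) && isTRUE(flip[x])) ch <- rev(ch)
    for (c_ in rev(ch)) stack[[length(stack) + 1L]] <- c_
  }
  tr$tip.label[out]
}

count_crossings <- function(ord1, ord2) {
  pos <- match(ord1, ord2)
  pos <- pos[!is.na(pos)]
  n <- length(pos)
  cr <- 0L
  for (i in seq_len(n - 1L))
    cr <- cr + sum(pos[(i + 1L):n] < pos[i])
  cr
}

#' Tanglegram leaf orders and crossing count
#'
#' Greedy subtree-rotation heuristic: internal nodes of both trees are
#' repeatedly flipped whenever flipping reduces the number of line
#' crossings between matched leaves; deterministic given input order.
#'
#' @param t1,t2 [ape::phylo] trees sharing a leaf set.
#' @param max_passes maximum sweeps over the nodes.
#' @return list `order1`, `order2` (leaf label orders),
#'   `crossings` (after optimization), `initial_crossings`.
#' @export
tanglegram <- function(t1, t2, max_passes = 10) {
  k1 <- tree_kids(t1); k2 <- tree_kids(t2)
  f1 <- logical(ape::Ntip(t1) + t1$Nnode)
  f2 <- logical(ape::Ntip(t2) + t2$Nnode)
  o1 <- leaf_order(t1, k1, f1); o2 <- leaf_order(t2, k2, f2)
  cr <- count_crossings(o1, o2)
  init <- cr
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (side in 1:2) {
      tr <- if (side == 1) t1 else t2
      kd <- if (side == 1) k1 else k2
      fl <- if (side == 1) f1 else f2
      nodes <- (ape::Ntip(tr) + 1L):(ape::Ntip(tr) + tr$Nnode)
      for (nd in nodes) {
        fl[nd] <- !fl[nd]
        oo1 <- if (side == 1) leaf_order(t1, k1, fl) else o1
        oo2 <- if (side == 2) leaf_order(t2, k2, fl) else o2
        cc <- count_crossings(oo1, oo2)
        if (cc < cr) {
          cr <- cc; o1 <- oo1; o2 <- oo2; improved <- TRUE
        } else fl[nd] <- !fl[nd]
      }
      if (side == 1) f1 <- fl else f2 <- fl
    }
    if (!improved) break
  }
  list(order1 = o1, order2 = o2, crossings = cr,
       initial_crossings = init)
}

#' Polytomy and low-support summary of a tree
#'
#' Polytomy = internal node with more than two children (the root of an
#' unrooted-stored tree is allowed three); low-support clade = internal
#' edge whose support value falls below the threshold.
#'
#' @param tree an [ape::phylo]; internal node labels are read as
#'   bootstrap supports in percent.
#' @param support_threshold clades below this support (percent) are
#'   counted.
#' @param outgroup optional tip label(s); the tree is rerooted on them
#'   before summarizing.
#' @return list `polytomies`, `low_support_clades`, `n_internal_edges`.
#' @export
tree_summary <- function(tree, support_threshold = 60, outgroup = NULL) {
  if (!is.null(outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = FALSE)
  n <- ape::Ntip(tree)
  nk <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  root <- n + 1L
  lim <- ifelse(seq_along(nk) == root & !ape::is.rooted(tree), 3L, 2L)
  poly <- sum(nk > lim & nk > 0)
  low <- 0L
  n_int <- 0L
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    internal <- setdiff((n + 1L):(n + tree$Nnode), root)
    for (nd in internal) {
      s <- sup[nd - n]
      n_int <- n_int + 1L
      if (!is.na(s) && s < support_threshold) low <- low + 1L
    }
  }
  list(polytomies = poly, low_support_clades = low,
       n_internal_edges = n_int)
}
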