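# Indexing helpers over ape "phylo" trees.
#
# ape numbers tips 1..n and internal nodes (n+1)..(n+Nnode) with the root at
# n+1 for rooted trees. All per-node vectors below are indexed by that
# numbering; "branch" means the edge entering a node from its parent, so a
# branch is identified by its child node id.

# Build a reusable index: parent/child links, incoming branch lengths,
# traversal orders and the tip set below every node.
tree_index <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n_all)
  blen_in <- rep(NA_real_, n_all)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  if (is.null(phy$edge.length)) {
    abort("tree has no branch lengths")
  }
  blen_in[phy$edge[, 2]] <- phy$edge.length
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])
  if (length(root) != 1L) abort("tree must have exactly one root")
  children <- vector("list", n_all)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    children[[p]] <- c(children[[p]], phy$edge[i, 2])
  }
  # preorder: parents before children
  preorder <- integer(n_all)
  stack <- root
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    preorder[k] <- v
    stack <- c(stack, children[[v]])
  }
  postorder <- rev(preorder)
  # tips below each node (node itself when a tip)
  tips_below <- vector("list", n_all)
  for (v in postorder) {
    if (v <= n_tip) {
      tips_below[[v]] <- v
    } else {
      tips_below[[v]] <- unlist(lapply(children[[v]], function(c) tips_below[[c]]))
    }
  }
  list(
    phy = phy, n_tip = n_tip, n_all = n_all, root = root,
    parent = parent, children = children, blen_in = blen_in,
    preorder = preorder, postorder = postorder, tips_below = tips_below,
    tip_label = phy$tip.label
  )
}

# All ancestors of a node, nearest first (excludes the node, includes root).
node_ancestors <- function(idx, node) {
  out <- integer(0)
  v <- idx$parent[node]
  while (!is.na(v)) {
    out <- c(out, v)
    v <- idx$parent[v]
  }
  out
}

# Is `anc` an ancestor of (or equal to) `node`?
is_ancestor_or_self <- function(idx, anc, node) {
  v <- node
  while (!is.na(v)) {
    if (v == anc) return(TRUE)
    v <- idx$parent[v]
  }
  FALSE
}
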