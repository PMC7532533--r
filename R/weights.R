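# Tree-based sequence weighting and weighted ancestral state
# reconstruction with branch-midpoint transitions.

#' Leaf weights from a root-to-tip recursion
#'
#' The root receives the total tree weight T (the sum of all branch
#' lengths). Moving from root to leaves, every node receives weight
#' A*B/C, where A is the length of its incoming branch plus the summed
#' branch length of its entire subtree, B is the parent's weight, and C is
#' the sum of the A values over the parent's children. Weight is thus
#' conserved at every split and the leaf weights sum to T, down-weighting
#' densely sampled clades. When all of a node's child branches and
#' subtrees have zero length the weight is split equally.
#'
#' @param tree an ape `phylo` with branch lengths.
#' @return An object of class `leaf_weights`: list with `leaf` (named
#'   numeric over tip labels), `node` (numeric over all node ids),
#'   `total` (T).
#' @export
leaf_weights <- function(tree) {
  idx <- if (inherits(tree, "phylo")) tree_index(tree) else tree
  n <- idx$n_all
  # summed branch length of the subtree below each node
  sub <- numeric(n)
  for (v in idx$postorder) {
    ch <- idx$children[[v]]
    if (length(ch)) sub[v] <- sum(idx$blen_in[ch] + sub[ch])
  }
  a <- ifelse(is.na(idx$blen_in), 0, idx$blen_in) + sub
  total <- sub[idx$root]
  w <- numeric(n)
  w[idx$root] <- total
  for (v in idx$preorder) {
    ch <- idx$children[[v]]
    if (!length(ch)) next
    cc <- sum(a[ch])
    if (cc == 0) {
      w[ch] <- w[v] / length(ch)
    } else {
      w[ch] <- a[ch] * w[v] / cc
    }
  }
  structure(
    list(leaf = stats::setNames(w[seq_len(idx$n_tip)], idx$tip_label),
         node = w, total = total),
    class = "leaf_weights"
  )
}

#' @export
print.leaf_weights <- function(x, ...) {
  cat(sprintf("<leaf_weights> %d leaves, total tree weight %.4g\n",
              length(x$leaf), x$total))
  invisible(x)
}

#' Weighted-Fitch ancestral state reconstruction at one site
#'
#' Two passes over the tree. Bottom-up, every node receives a character
#' weight vector whose entry for residue a is the sum of the leaf weights
#' of its descendant leaves carrying a at the column (leaves gapped or
#' unknown there carry no character), normalized to sum to 1. Top-down,
#' every interior non-root node's vector is replaced by the normalized
#' elementwise product of its bottom-up vector with its parent's bottom-up
#' vector (a pseudo-conditional probability); the root, having no
#' ancestor, keeps its bottom-up vector, and leaves keep their observed
#' residue. Every node is then assigned the residue with the highest
#' final weight if that weight exceeds 0.5 (strictly), and the undefined
#' state (`NA`) otherwise.
#'
#' @param family a [gene_family] (or pass `tree`/`msa` via `idx` and
#'   `mat` internally).
#' @param column 1-based alignment column.
#' @param weights a [leaf_weights] for the family's tree.
#' @return Object of class `ancestral_states`: list with `assignment`
#'   (character vector over node ids, `NA` = undefined), `bottom_up` and
#'   `final` (matrices node x residue), `residues`, `column`.
#' @export
reconstruct_ancestral_states <- function(family, column, weights) {
  idx <- family$idx
  chars <- family$msa$mat[idx$tip_label, column]
  chars[is_gaplike(chars)] <- NA
  residues <- sort(unique(chars[!is.na(chars)]))
  n <- idx$n_all
  k <- length(residues)
  if (k == 0) {
    warn(sprintf("column %d is all-gap among tree leaves", column))
    return(structure(list(assignment = rep(NA_character_, n),
                          bottom_up = NULL, final = NULL,
                          residues = character(0), column = column),
                     class = "ancestral_states"))
  }
  # bottom-up: per-residue sums of descendant leaf weights
  V <- matrix(0, n, k, dimnames = list(NULL, residues))
  lw <- weights$leaf[idx$tip_label]
  tip_res <- match(chars, residues)
  for (t in seq_len(idx$n_tip)) {
    if (!is.na(tip_res[t])) V[t, tip_res[t]] <- lw[t]
  }
  for (v in idx$postorder) {
    ch <- idx$children[[v]]
    if (length(ch)) V[v, ] <- colSums(V[ch, , drop = FALSE])
  }
  rs <- rowSums(V)
  B <- V / ifelse(rs > 0, rs, 1)          # normalized bottom-up
  # top-down pseudo-conditional: product with the parent's bottom-up
  Fin <- B
  interior <- setdiff(seq_len(n), c(seq_len(idx$n_tip), idx$root))
  for (v in interior) {
    p <- B[v, ] * B[idx$parent[v], ]
    s <- sum(p)
    Fin[v, ] <- if (s > 0) p / s else 0
  }
  # leaves: their own observed character (weight 1), or nothing if gapped
  for (t in seq_len(idx$n_tip)) {
    Fin[t, ] <- 0
    if (!is.na(tip_res[t])) Fin[t, tip_res[t]] <- 1
  }
  best <- max.col(Fin, ties.method = "first")
  bw <- Fin[cbind(seq_len(n), best)]
  assignment <- ifelse(bw > 0.5, residues[best], NA_character_)
  structure(list(assignment = assignment, bottom_up = B, final = Fin,
                 residues = residues, column = column),
            class = "ancestral_states")
}

#' Extract branch-midpoint transitions from an ancestral assignment
#'
#' A transition is recorded on every branch whose endpoints carry
#' different defined residues, placed at the branch midpoint. Undefined
#' stretches are bridged: a defined node whose nearest defined ancestor
#' (walking through undefined nodes) carries a different residue yields
#' one transition, attributed to the branch entering the defined
#' descendant; if the flanking residues agree, no transition is recorded.
#'
#' @param family a [gene_family].
#' @param states an `ancestral_states` (or bare assignment vector).
#' @param site optional site label stored in the output.
#' @return Tibble: `site`, `parent`, `child` (node ids; the branch is the
#'   edge entering `child`), `from`, `to`.
#' @export
extract_transitions <- function(family, states, site = NA_integer_) {
  idx <- family$idx
  assignment <- if (inherits(states, "ancestral_states")) states$assignment else states
  if (inherits(states, "ancestral_states") && is.na(site)) site <- states$column
  out <- list()
  for (v in seq_len(idx$n_all)) {
    if (v == idx$root || is.na(assignment[v])) next
    # nearest defined ancestor, bridging undefined nodes
    a <- idx$parent[v]
    while (!is.na(a) && is.na(assignment[a])) a <- idx$parent[a]
    if (is.na(a) || assignment[a] == assignment[v]) next
    out[[length(out) + 1L]] <- tibble(
      site = site, parent = idx$parent[v], child = v,
      from = assignment[a], to = assignment[v])
  }
  if (length(out)) dplyr::bind_rows(out)
  else tibble(site = integer(), parent = integer(), child = integer(),
              from = character(), to = character())
}

#' Full ancestral record over a set of columns
#'
#' Runs [reconstruct_ancestral_states] and [extract_transitions] for each
#' requested column and collects the results.
#'
#' @param family a [gene_family].
#' @param weights a [leaf_weights].
#' @param columns columns to reconstruct (default: every column mapped to
#'   a reference position).
#' @return Object of class `ancestral_record`: list with `assignment`
#'   (node x column character matrix), `transitions` (one tibble, `site`
#'   = column), `columns`.
#' @export
ancestral_record <- function(family, weights, columns = NULL) {
  columns <- columns %||% family$ref_map$column
  asn <- matrix(NA_character_, family$idx$n_all, length(columns),
                dimnames = list(NULL, columns))
  trans <- vector("list", length(columns))
  for (i in seq_along(columns)) {
    st <- suppressWarnings(
      reconstruct_ancestral_states(family, columns[i], weights))
    asn[, i] <- st$assignment
    trans[[i]] <- extract_transitions(family, st)
  }
  structure(list(assignment = asn, transitions = dplyr::bind_rows(trans),
                 columns = columns),
            class = "ancestral_record")
}

#' @export
print.ancestral_record <- function(x, ...) {
  cat(sprintf("<ancestral_record> %d columns, %d transitions\n",
              length(x$columns), nrow(x$transitions)))
  invisible(x)
}
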