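# Compensatory ensemble construction: candidate compensator states,
# tree-fraction occupancy, the binomial co-occurrence probability, and the
# greedy/exhaustive ensemble search under the ensemble criteria.

#' Binomial probability of driver/compensator co-occurrence on the tree
#'
#' Upper-tail binomial probability that, were the driver and compensator
#' placed independently, at least `n_pair` of the `n_total` transitions to
#' the driver state would fall on or below a branch occupied by the
#' compensatory state, which occupies fraction `f` of the applicable
#' branch length.
#'
#' @param n_total number of transitions to the driver state in the whole
#'   ancestral record.
#' @param n_pair number of those descending from (or sharing a branch
#'   with) a transition to a compensatory state.
#' @param f fraction of applicable branch length occupied by the
#'   compensatory state (or ensemble).
#' @return `P(X >= n_pair)` for `X ~ Binomial(n_total, f)`; 1 when
#'   `n_pair` is 0 and `f^n_total` when `n_pair == n_total`.
#' @export
cooccurrence_probability <- function(n_total, n_pair, f) {
  if (any(n_pair < 0 | n_pair > n_total)) {
    abort("require 0 <= n_pair <= n_total")
  }
  if (any(f < 0 | f > 1)) abort("require 0 <= f <= 1")
  stats::pbinom(n_pair - 1, n_total, f, lower.tail = FALSE)
}

# Assignment vector for one column of an ancestral_record.
record_assignment <- function(record, column) {
  j <- match(column, record$columns)
  if (is.na(j)) abort(sprintf("column %d not in ancestral record", column))
  record$assignment[, j]
}

# Per-branch occupancy of `residue` at a site: for every non-root node v
# (the branch parent(v) -> v), the occupied length and whether the branch
# is applicable (both endpoints defined). A branch fully inside the state
# counts whole; a transition branch (state at exactly one defined
# endpoint) counts half; branches touching undefined nodes are excluded
# from both numerator and denominator.
branch_occupancy <- function(idx, assignment, residue) {
  v <- setdiff(seq_len(idx$n_all), idx$root)
  p <- idx$parent[v]
  av <- assignment[v]
  ap <- assignment[p]
  applicable <- !is.na(av) & !is.na(ap)
  hit_v <- !is.na(av) & av == residue
  hit_p <- !is.na(ap) & ap == residue
  occ <- numeric(length(v))
  occ[applicable & hit_v & hit_p] <- idx$blen_in[v][applicable & hit_v & hit_p]
  half <- applicable & xor(hit_v, hit_p)
  occ[half] <- idx$blen_in[v][half] / 2
  list(child = v, length = idx$blen_in[v], occupied = occ,
       applicable = applicable)
}

#' Fraction of the tree occupied by a residue state
#'
#' Sums the lengths of branches on which the state is the assigned
#' residue at both endpoints, plus half-lengths of transition branches,
#' divided by the total length of branches with a defined assignment at
#' both endpoints for that site.
#'
#' @param family a [gene_family].
#' @param states an `ancestral_states` (or assignment vector) for the
#'   state's site.
#' @param residue the residue state.
#' @return The occupancy fraction in `[0, 1]`, or `NA` when no branch has
#'   a defined assignment.
#' @export
branch_state_fraction <- function(family, states, residue) {
  assignment <- if (inherits(states, "ancestral_states")) states$assignment else states
  b <- branch_occupancy(family$idx, assignment, residue)
  denom <- sum(b$length[b$applicable])
  if (denom == 0) return(NA_real_)
  sum(b$occupied) / denom
}

#' Candidate compensator states for a driver
#'
#' States (site, residue) at other sites with at least one transition on
#' the same branch as, or on an ancestral branch of, at least one
#' transition to the driver state.
#'
#' @param family a [gene_family].
#' @param record an [ancestral_record] covering the gene's sites.
#' @param driver_column alignment column of the driver site.
#' @param driver_residue driver (alternate) residue.
#' @return Tibble of distinct candidate states: `site`, `residue`.
#' @export
candidate_compensators <- function(family, record, driver_column, driver_residue) {
  tr <- record$transitions
  dt <- tr$child[tr$site == driver_column & tr$to == driver_residue]
  if (length(dt) == 0) return(tibble(site = integer(), residue = character()))
  allowed <- unique(unlist(lapply(dt, function(d) c(d, node_ancestors(family$idx, d)))))
  cand <- tr[tr$site != driver_column & tr$child %in% allowed, ]
  dplyr::distinct(tibble(site = cand$site, residue = cand$to))
}

# Precompute, for every candidate state, the structures the subset search
# needs: coverage of driver-bearing leaves, pairing with each driver
# transition, per-branch occupancy, and qualifying transition nodes.
prepare_candidates <- function(family, record, candidates, driver_column,
                               driver_residue, driver_leaves) {
  idx <- family$idx
  tr <- record$transitions
  dt <- tr$child[tr$site == driver_column & tr$to == driver_residue]
  anc_sets <- lapply(dt, function(d) c(d, node_ancestors(idx, d)))
  n_branch <- idx$n_all - 1L
  m <- nrow(candidates)
  cover <- matrix(FALSE, m, length(driver_leaves))
  pair <- matrix(FALSE, m, length(dt))
  occ <- matrix(0, m, n_branch)
  apl <- matrix(FALSE, m, n_branch)
  nodes <- vector("list", m)
  blen <- NULL
  for (i in seq_len(m)) {
    s <- candidates$site[i]
    r <- candidates$residue[i]
    cover[i, ] <- family$msa$mat[idx$tip_label[driver_leaves], s] == r
    mc <- tr$child[tr$site == s & tr$to == r]
    pair[i, ] <- vapply(seq_along(dt), function(j) any(mc %in% anc_sets[[j]]),
                        logical(1))
    b <- branch_occupancy(idx, record_assignment(record, s), r)
    occ[i, ] <- b$occupied
    apl[i, ] <- b$applicable
    blen <- b$length
    # transition nodes with >= 2 driver-bearing descendant leaves
    nodes[[i]] <- mc[vapply(mc, function(v)
      sum(idx$tips_below[[v]] %in% driver_leaves) >= 2, logical(1))]
  }
  # per-member binomial probability: each member's own pairing count and
  # occupied fraction
  f_single <- vapply(seq_len(m), function(i) {
    denom <- sum(blen[apl[i, ]])
    if (denom > 0) min(1, sum(occ[i, ]) / denom) else NA_real_
  }, numeric(1))
  p_single <- vapply(seq_len(m), function(i) {
    if (is.na(f_single[i])) return(NA_real_)
    cooccurrence_probability(length(dt), sum(pair[i, ]), f_single[i])
  }, numeric(1))
  list(cover = cover, pair = pair, occ = occ, apl = apl, blen = blen,
       nodes = nodes, n_total = length(dt),
       f_single = f_single, p_single = p_single)
}

# Evaluate one candidate subset (row indices into the prepared
# structures). The ensemble's probability is its weakest member's
# binomial probability: every member state must itself be improbably
# well placed, which keeps opportunistic unions of individually
# unremarkable states from passing. The pooled pairing count and the
# union occupied fraction are reported descriptively.
eval_subset <- function(prep, sel) {
  covered <- apply(prep$cover[sel, , drop = FALSE], 2, any)
  n_pair <- sum(apply(prep$pair[sel, , drop = FALSE], 2, any))
  occ <- apply(prep$occ[sel, , drop = FALSE], 2, max)
  apl <- apply(prep$apl[sel, , drop = FALSE], 2, any)
  denom <- sum(prep$blen[apl])
  f <- if (denom > 0) min(1, sum(occ) / denom) else NA_real_
  ps <- prep$p_single[sel]
  p <- if (any(is.na(ps))) NA_real_ else max(ps)
  q_nodes <- unique(unlist(prep$nodes[sel]))
  list(
    coverage = all(covered), n_pair = n_pair, f = f, p = p,
    n_nodes = length(q_nodes),
    ok = all(covered) && !is.na(p) && length(q_nodes) >= 2
  )
}

#' Build the compensatory ensemble for one driver
#'
#' Searches candidate compensator subsets for the minimal-probability
#' ensemble satisfying all ensemble criteria: (1) every driver-bearing
#' leaf carries at least one member state, (2) the binomial co-occurrence
#' probability is below `p_max`, (3) member transitions occur at two or
#' more independent nodes, (4) at least two driver-bearing leaves descend
#' from each such node. Drivers present in fewer than `min_leaves` leaves
#' are skipped. For candidate pools of at most `max_exhaustive` states
#' the search enumerates subsets by increasing size, stopping one size
#' above the smallest accepted ensemble (larger ensembles are not
#' reported); bigger pools are searched greedily, growing by the
#' candidate that most reduces the probability while extending coverage.
#'
#' @param family a [gene_family].
#' @param record an [ancestral_record].
#' @param driver_column alignment column of the driver.
#' @param driver_residue driver residue.
#' @param p_max acceptance threshold on the co-occurrence probability.
#' @param min_leaves minimum driver-bearing leaves (default 4).
#' @param max_exhaustive largest candidate pool searched exhaustively.
#' @param exclude states (tibble `site`, `residue`) already consumed by
#'   another ensemble.
#' @return One-row tibble: `column`, `residue`, `n_leaves`, `n_total`,
#'   `n_pair`, `f`, `p`, `members` (list-column tibble), `accepted`,
#'   `reason`.
#' @export
build_ensemble <- function(family, record, driver_column, driver_residue,
                           p_max = 0.01, min_leaves = 4, max_exhaustive = 15,
                           exclude = NULL) {
  idx <- family$idx
  res_row <- function(accepted, reason, members = tibble(site = integer(),
                                                         residue = character()),
                      n_total = NA_integer_, n_pair = NA_integer_,
                      f = NA_real_, p = NA_real_, n_leaves = NA_integer_) {
    tibble(column = driver_column, residue = driver_residue,
           n_leaves = n_leaves, n_total = n_total, n_pair = n_pair,
           f = f, p = p, members = list(members),
           accepted = accepted, reason = reason)
  }
  leaf_chars <- family$msa$mat[idx$tip_label, driver_column]
  driver_leaves <- which(leaf_chars == driver_residue)
  n_leaves <- length(driver_leaves)
  if (n_leaves < min_leaves) {
    return(res_row(FALSE, sprintf("driver present in %d < %d leaves",
                                  n_leaves, min_leaves),
                   n_leaves = n_leaves))
  }
  cand <- candidate_compensators(family, record, driver_column, driver_residue)
  if (!is.null(exclude) && nrow(exclude)) {
    cand <- dplyr::anti_join(cand, exclude, by = c("site", "residue"))
  }
  tr <- record$transitions
  n_total <- sum(tr$site == driver_column & tr$to == driver_residue)
  if (nrow(cand) == 0) {
    return(res_row(FALSE, "no candidate compensator states",
                   n_total = n_total, n_leaves = n_leaves))
  }
  prep <- prepare_candidates(family, record, cand, driver_column,
                             driver_residue, driver_leaves)
  # every member must individually pass the probability threshold, so
  # candidates that cannot are dropped before the subset search
  viable <- which(!is.na(prep$p_single) & prep$p_single < p_max)
  if (length(viable) == 0) {
    i <- if (all(is.na(prep$p_single))) 1L else which.min(prep$p_single)
    ev <- eval_subset(prep, i)
    return(res_row(FALSE, "no candidate state individually improbable enough",
                   members = cand[i, ], n_total = prep$n_total,
                   n_pair = ev$n_pair, f = ev$f, p = ev$p,
                   n_leaves = n_leaves))
  }
  cand <- cand[viable, ]
  prep$cover <- prep$cover[viable, , drop = FALSE]
  prep$pair <- prep$pair[viable, , drop = FALSE]
  prep$occ <- prep$occ[viable, , drop = FALSE]
  prep$apl <- prep$apl[viable, , drop = FALSE]
  prep$nodes <- prep$nodes[viable]
  prep$f_single <- prep$f_single[viable]
  prep$p_single <- prep$p_single[viable]
  finish <- function(sel, ev) {
    res_row(ev$ok && ev$p < p_max,
            if (ev$ok && ev$p < p_max) "accepted"
            else if (!ev$coverage) "driver-bearing leaves not covered"
            else if (ev$n_nodes < 2) "member transitions at < 2 qualifying nodes"
            else "co-occurrence probability above threshold",
            members = cand[sel, ], n_total = prep$n_total,
            n_pair = ev$n_pair, f = ev$f, p = ev$p, n_leaves = n_leaves)
  }
  m <- nrow(cand)
  if (m <= max_exhaustive) {
    best_sel <- NULL
    best_ev <- NULL
    smallest <- NA_integer_
    for (size in seq_len(m)) {
      if (!is.na(smallest) && size > smallest + 1L) break
      sets <- utils::combn(m, size, simplify = FALSE)
      for (sel in sets) {
        ev <- eval_subset(prep, sel)
        if (ev$ok && ev$p < p_max) {
          if (is.na(smallest)) smallest <- size
          if (is.null(best_ev) || ev$p < best_ev$p) {
            best_sel <- sel
            best_ev <- ev
          }
        }
      }
    }
    if (!is.null(best_sel)) return(finish(best_sel, best_ev))
    # nothing accepted: report the best singleton for diagnostics
    evs <- lapply(seq_len(m), function(i) eval_subset(prep, i))
    ps <- vapply(evs, function(e) e$p %||% NA_real_, numeric(1))
    i <- if (all(is.na(ps))) 1L else which.min(ps)
    return(finish(i, evs[[i]]))
  }
  # greedy: best singleton, then grow toward coverage by the candidate
  # that most reduces p; one optional extra member that lowers p further
  evs <- lapply(seq_len(m), function(i) eval_subset(prep, i))
  ps <- vapply(evs, function(e) e$p %||% NA_real_, numeric(1))
  sel <- if (all(is.na(ps))) 1L else which.min(ps)
  ev <- eval_subset(prep, sel)
  covered <- apply(prep$cover[sel, , drop = FALSE], 2, any)
  while (!all(covered)) {
    gain <- vapply(seq_len(m), function(i) {
      if (i %in% sel) return(FALSE)
      any(prep$cover[i, !covered])
    }, logical(1))
    if (!any(gain)) break
    trial <- lapply(which(gain), function(i) list(i = i, ev = eval_subset(prep, c(sel, i))))
    pt <- vapply(trial, function(t) t$ev$p %||% NA_real_, numeric(1))
    jbest <- which.min(pt)
    sel <- c(sel, trial[[jbest]]$i)
    ev <- trial[[jbest]]$ev
    covered <- apply(prep$cover[sel, , drop = FALSE], 2, any)
  }
  if (ev$ok && ev$p < p_max) {
    extra <- setdiff(seq_len(m), sel)
    if (length(extra)) {
      pe <- vapply(extra, function(i) eval_subset(prep, c(sel, i))$p, numeric(1))
      if (any(!is.na(pe)) && min(pe, na.rm = TRUE) < ev$p) {
        i <- extra[which.min(pe)]
        sel <- c(sel, i)
        ev <- eval_subset(prep, sel)
      }
    }
  }
  finish(sel, ev)
}

#' Build compensatory ensembles for all drivers of a gene
#'
#' Applies [build_ensemble] to every driver and enforces that each
#' individual state joins at most one ensemble: accepted ensembles are
#' consumed in order of increasing probability, and remaining drivers are
#' re-searched with consumed states excluded until no further ensemble is
#' accepted.
#'
#' @param family a [gene_family].
#' @param record an [ancestral_record].
#' @param drivers tibble with `column` and `residue` (e.g. selected
#'   drivers joined to the reference map).
#' @inheritParams build_ensemble
#' @return Tibble, one row per driver, as in [build_ensemble].
#' @export
build_ensembles <- function(family, record, drivers, p_max = 0.01,
                            min_leaves = 4, max_exhaustive = 15) {
  consumed <- tibble(site = integer(), residue = character())
  pending <- seq_len(nrow(drivers))
  rows <- vector("list", nrow(drivers))
  while (length(pending)) {
    trial <- lapply(pending, function(i) {
      build_ensemble(family, record, drivers$column[i], drivers$residue[i],
                     p_max = p_max, min_leaves = min_leaves,
                     max_exhaustive = max_exhaustive, exclude = consumed)
    })
    acc <- vapply(trial, function(t) t$accepted, logical(1))
    if (!any(acc)) {
      for (j in seq_along(pending)) rows[[pending[j]]] <- trial[[j]]
      break
    }
    ps <- vapply(trial, function(t) t$p, numeric(1))
    ps[!acc] <- Inf
    j <- which.min(ps)
    rows[[pending[j]]] <- trial[[j]]
    consumed <- dplyr::bind_rows(consumed, trial[[j]]$members[[1]])
    pending <- pending[-j]
  }
  dplyr::bind_rows(rows)
}
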