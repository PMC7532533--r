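# Independent oracle implementations, deliberately written as plain
# straight-line code over different data structures than the package.

# Direct binomial upper-tail summation.
oracle_binom_tail <- function(n_total, n_pair, f) {
  if (n_pair == 0) return(1)
  s <- 0
  for (k in n_pair:n_total) {
    s <- s + choose(n_total, k) * f^k * (1 - f)^(n_total - k)
  }
  s
}

# Log-space Poisson tail by explicit term summation (no ppois).
# Returns log P(X <= k) and log P(X > k) for integer k.
oracle_poisson_logtails <- function(k, lambda, extra = 3000) {
  terms <- function(i) -lambda + i * log(lambda) - lgamma(i + 1)
  lse <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
  lo <- lse(terms(0:k))
  hi_range <- (k + 1):(k + 1 + extra + 20 * sqrt(lambda + 1))
  hi <- lse(terms(hi_range))
  c(log_cdf = lo, log_sf = hi)
}

oracle_association_score <- function(exp, obs) {
  k <- floor(obs)
  t <- oracle_poisson_logtails(k, exp)
  if (obs > exp) -t[["log_sf"]] else if (obs < exp) t[["log_cdf"]] else 0
}

# Straight-line weighted two-pass reconstruction, using explicit
# ancestor walks instead of the package's traversal machinery.
oracle_fitch <- function(phy, chars, leaf_w) {
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n_all)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])
  descends <- function(node, anc) {
    v <- node
    while (!is.na(v)) {
      if (v == anc) return(TRUE)
      v <- parent[v]
    }
    FALSE
  }
  residues <- sort(unique(stats::na.omit(chars)))
  bottom <- matrix(0, n_all, length(residues), dimnames = list(NULL, residues))
  for (v in seq_len(n_all)) {
    for (t in seq_len(n_tip)) {
      if (is.na(chars[t])) next
      if (descends(t, v)) {
        bottom[v, chars[t]] <- bottom[v, chars[t]] + leaf_w[phy$tip.label[t]]
      }
    }
    if (sum(bottom[v, ]) > 0) bottom[v, ] <- bottom[v, ] / sum(bottom[v, ])
  }
  final <- bottom
  for (v in seq_len(n_all)) {
    if (v == root) next
    if (v <= n_tip) {
      final[v, ] <- 0
      if (!is.na(chars[v])) final[v, chars[v]] <- 1
      next
    }
    pr <- bottom[v, ] * bottom[parent[v], ]
    final[v, ] <- if (sum(pr) > 0) pr / sum(pr) else 0
  }
  assignment <- rep(NA_character_, n_all)
  for (v in seq_len(n_all)) {
    if (length(residues) == 0) next
    i <- which.max(final[v, ])
    if (final[v, i] > 0.5) assignment[v] <- residues[i]
  }
  assignment
}

# Brute-force ranks: sort-and-count over distinct mutations.
oracle_ranks <- function(counts) {
  vapply(counts, function(k) 1L + sum(counts > k), integer(1))
}

# Brute-force target clade over every taxonomy node, coded with set
# operations on path strings.
oracle_target_clade <- function(paths, harboring, all_species) {
  paths <- paths[names(paths) %in% all_species]
  labels <- unique(unlist(strsplit(unname(paths), ";", fixed = TRUE)))
  info <- lapply(labels, function(lab) {
    sp <- names(paths)[vapply(strsplit(unname(paths), ";", fixed = TRUE),
                              function(p) lab %in% p, logical(1))]
    list(label = lab, n = length(sp), h = length(intersect(sp, harboring)))
  })
  n <- vapply(info, `[[`, numeric(1), "n")
  h <- vapply(info, `[[`, numeric(1), "h")
  maj <- which(h / n > 0.5)
  a <- if (length(maj)) maj[order(-n[maj], labels[maj])][1] else NA
  cov <- which(h > 0.9 * length(harboring))
  b <- cov[order(n[cov], labels[cov])][1]
  if (is.na(a) || n[b] <= n[a]) {
    list(clade = labels[b], rule = "ninety-percent")
  } else {
    list(clade = labels[a], rule = "majority")
  }
}

# Brute-force sum-of-pairs homogeneity with an explicit double loop.
oracle_homogeneity <- function(residues, M, f, hom_residue) {
  n <- length(residues)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + M[residues[i], residues[j]]
    }
  }
  npairs <- n * (n - 1) / 2
  s_hom <- npairs * M[hom_residue, hom_residue]
  e_pair <- 0
  for (a in rownames(M)) {
    for (b in colnames(M)) {
      e_pair <- e_pair + f[a] * f[b] * M[a, b]
    }
  }
  s_rand <- npairs * e_pair
  unname((s - s_rand) / (s_hom - s_rand))
}
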