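# Column conservation: sum-of-pairs homogeneity, neighborhood smoothing,
# the tree-building site filter and deep/shallow site classification.

# BLOSUM62 restricted to the 20 canonical amino acids, loaded once.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA20, AA20]
    }
    cache
  }
})

#' Background amino-acid frequencies of an alignment
#'
#' Empirical frequencies of the 20 canonical residues over the given rows
#' of the whole alignment (gaps and unknowns ignored); uniform if the rows
#' contain no residues.
#'
#' @param msa an [msa].
#' @param rows sequence ids to pool over (default: all rows).
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
aa_background <- function(msa, rows = NULL) {
  m <- msa$mat[rows %||% rownames(msa$mat), , drop = FALSE]
  counts <- table(factor(m[!is_gaplike(m)], levels = AA20))
  n <- sum(counts)
  if (n == 0) return(stats::setNames(rep(1 / 20, 20), AA20))
  stats::setNames(as.numeric(counts) / n, AA20)
}

#' Sum-of-pairs column homogeneity
#'
#' For a column with residue counts `c` over `n = sum(c)` non-gap rows,
#' three sum-of-pairs scores are formed under a substitution matrix M:
#' the column's own score S, the score `S_hom` of a homogeneous column of
#' the best self-scoring residue (tryptophan under BLOSUM62), and the
#' expectation `S_rand` of a column of residues drawn i.i.d. from the
#' background frequency vector. The reported homogeneity is the linear
#' rescaling `(S - S_rand) / (S_hom - S_rand)`, so a random column scores
#' about 0 and the top homogeneous column scores 1. Values below 0 are
#' possible and not clamped.
#'
#' @param msa an [msa].
#' @param column 1-based alignment column.
#' @param rows sequence ids to score over (default: all rows).
#' @param background background frequencies (default [aa_background] of
#'   `rows` over the whole alignment).
#' @param matrix substitution matrix (default BLOSUM62).
#' @param hom_mode `"max"` scores the homogeneous column with the residue
#'   maximizing self-score; `"consensus"` uses the column's own majority
#'   residue.
#' @return Homogeneity, or `NA` when fewer than 2 non-gap residues.
#' @export
site_homogeneity <- function(msa, column, rows = NULL, background = NULL,
                             matrix = NULL, hom_mode = c("max", "consensus")) {
  hom_mode <- match.arg(hom_mode)
  M <- matrix %||% blosum62()
  rows <- rows %||% rownames(msa$mat)
  col <- msa$mat[rows, column]
  res <- col[!is_gaplike(col)]
  n <- length(res)
  if (n < 2) return(NA_real_)
  f <- background %||% aa_background(msa, rows)
  cnt <- as.numeric(table(factor(res, levels = AA20)))
  npairs <- n * (n - 1) / 2
  # sum over unordered pairs: (c'Mc - sum_a c_a M_aa) / 2
  s <- (drop(cnt %*% M %*% cnt) - sum(cnt * diag(M))) / 2
  s_hom <- npairs * switch(hom_mode,
    max = max(diag(M)),
    consensus = diag(M)[which.max(cnt)]
  )
  s_rand <- npairs * drop(f %*% M %*% f)
  unname((s - s_rand) / (s_hom - s_rand))
}

#' Homogeneity for every alignment column
#'
#' @inheritParams site_homogeneity
#' @return Tibble with columns `column` and `h` (`NA` where undefined).
#' @export
homogeneity_track <- function(msa, rows = NULL, background = NULL,
                              matrix = NULL, hom_mode = "max") {
  rows <- rows %||% rownames(msa$mat)
  background <- background %||% aa_background(msa, rows)
  h <- vapply(seq_len(msa$n_columns), function(j) {
    site_homogeneity(msa, j, rows, background, matrix, hom_mode)
  }, numeric(1))
  tibble(column = seq_len(msa$n_columns), h = h)
}

#' Neighborhood homogeneity
#'
#' Mean homogeneity over a site and its `window` nearest neighbors on each
#' side (seven values for the default window of 3); at the alignment edges
#' or next to undefined columns the mean runs over the values actually
#' available.
#'
#' @param h numeric homogeneity track (`NA` allowed).
#' @param column column(s) to evaluate; default all.
#' @param window number of flanking sites per side.
#' @return Numeric vector of neighborhood means (`NA` when no neighbor
#'   value is defined).
#' @export
neighborhood_homogeneity <- function(h, column = seq_along(h), window = 3) {
  vapply(column, function(j) {
    win <- max(1, j - window):min(length(h), j + window)
    v <- h[win]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Site filter used before tree building
#'
#' Retains columns with gap fraction at most 0.5 and homogeneity at least
#' 0.1, both computed over all alignment rows (unknown residues count as
#' gaps).
#'
#' @param msa an [msa].
#' @param max_gap_fraction maximum tolerated gap fraction.
#' @param min_homogeneity minimum homogeneity.
#' @return Integer vector of retained column indices.
#' @export
tree_site_filter <- function(msa, max_gap_fraction = 0.5, min_homogeneity = 0.1) {
  gapfrac <- colMeans(is_gaplike(msa$mat))
  h <- homogeneity_track(msa)$h
  which(gapfrac <= max_gap_fraction & !is.na(h) & h >= min_homogeneity)
}

#' Classify alignment sites as deep or shallow
#'
#' A site is "deep" when at least one fungal or plant sequence carries a
#' non-gap residue there — i.e. the column has a confidently aligned
#' counterpart outside metazoa — and "shallow" otherwise.
#'
#' @param msa an [msa].
#' @param taxa taxon annotations.
#' @param column column(s) to classify; default all.
#' @return Character vector, `"deep"` or `"shallow"`.
#' @export
classify_site_depth <- function(msa, taxa, column = seq_len(msa$n_columns)) {
  deep_rows <- taxa$seq_id[taxa$clade %in% c("fungus", "plant")]
  deep_rows <- intersect(deep_rows, rownames(msa$mat))
  if (length(deep_rows) == 0) return(rep("shallow", length(column)))
  sub <- msa$mat[deep_rows, column, drop = FALSE]
  ifelse(colSums(!is_gaplike(sub)) > 0, "deep", "shallow")
}

#' Per-site conservation track for a gene family
#'
#' Homogeneity is computed over the sequences of one major clade
#' (vertebrates by default, matching how driver-site conservation is
#' usually summarized), smoothed over the +/-3 neighborhood, and combined
#' with the deep/shallow classification and reference coordinates.
#'
#' @param family a [gene_family].
#' @param clade clade whose rows define the homogeneity row subset.
#' @param window neighborhood half-width.
#' @return Tibble: `column`, `ref_pos` (`NA` off the reference), `h`,
#'   `neighborhood_h`, `depth`.
#' @export
conservation_track <- function(family, clade = "vertebrate", window = 3) {
  rows <- family$taxa$seq_id[family$taxa$clade == clade]
  rows <- intersect(rows, rownames(family$msa$mat))
  if (length(rows) < 2) {
    warn(sprintf("fewer than 2 '%s' rows; homogeneity computed over all rows", clade))
    rows <- rownames(family$msa$mat)
  }
  tr <- homogeneity_track(family$msa, rows = rows)
  tr$neighborhood_h <- neighborhood_homogeneity(tr$h, window = window)
  tr$ref_pos <- NA_integer_
  tr$ref_pos[family$ref_map$column] <- family$ref_map$ref_pos
  tr$depth <- classify_site_depth(family$msa, family$taxa)
  out <- tr[, c("column", "ref_pos", "h", "neighborhood_h", "depth")]
  class(out) <- c("conservation_track", class(out))
  out
}
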