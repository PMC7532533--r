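# Mutation-pair association: expected/observed pair counts in the tumor
# table and in the leaf-weighted alignment, and the signed Poisson-tail
# association score.

#' Expected and observed pair counts in a tumor table
#'
#' A state is a (position, alternate residue) mutation. The observed
#' count is the number of tumor samples carrying both states; the
#' expected count is the product of the two per-tumor frequencies and the
#' number of tumors.
#'
#' @param records mutation records for one gene.
#' @param pos1,alt1 first state.
#' @param pos2,alt2 second state.
#' @param n_tumors total tumors in the dataset (default: distinct
#'   `sample_id`s in `records`).
#' @return List with `exp`, `obs`, `n_tumors`; `NULL` when there are no
#'   tumors.
#' @export
cosmic_pair_counts <- function(records, pos1, alt1, pos2, alt2,
                               n_tumors = NULL) {
  n_tumors <- n_tumors %||% dplyr::n_distinct(records$sample_id)
  if (n_tumors == 0) return(NULL)
  t1 <- unique(records$sample_id[records$pos == pos1 & records$alt_aa == alt1])
  t2 <- unique(records$sample_id[records$pos == pos2 & records$alt_aa == alt2])
  obs <- length(intersect(t1, t2))
  f1 <- length(t1) / n_tumors
  f2 <- length(t2) / n_tumors
  list(exp = f1 * f2 * n_tumors, obs = obs, n_tumors = n_tumors)
}

#' Expected and observed pair counts in the leaf-weighted alignment
#'
#' Over tree sequences with non-gap residues at both columns, leaf
#' weights are renormalized to sum to 1. With `n` the number of
#' nonzero-weighted qualifying sequences, the observed count is `n` times
#' the summed weight of sequences harboring both residues, and the
#' expected count is `n` times the product of the summed weights
#' harboring each residue. Both may be non-integer.
#'
#' @param family a [gene_family].
#' @param weights a [leaf_weights].
#' @param col1,res1 first state (alignment column, residue).
#' @param col2,res2 second state.
#' @return List with `exp`, `obs`, `n`; `NULL` when no sequence
#'   qualifies.
#' @export
msa_pair_counts <- function(family, weights, col1, res1, col2, res2) {
  tips <- family$idx$tip_label
  c1 <- family$msa$mat[tips, col1]
  c2 <- family$msa$mat[tips, col2]
  ok <- !is_gaplike(c1) & !is_gaplike(c2)
  w <- weights$leaf[tips][ok]
  if (!length(w) || sum(w) == 0) return(NULL)
  w <- w / sum(w)
  n_nz <- sum(w > 0)
  if (n_nz == 0) return(NULL)
  h1 <- c1[ok] == res1
  h2 <- c2[ok] == res2
  list(obs = sum(w[h1 & h2]) * n_nz,
       exp = sum(w[h1]) * sum(w[h2]) * n_nz,
       n = n_nz)
}

#' Signed Poisson-tail association score
#'
#' With PCDF the Poisson cumulative distribution with mean `exp`
#' evaluated at `obs`, the score is `-ln(1 - PCDF)` when more pairs are
#' observed than expected and `ln(PCDF)` when fewer, and 0 at equality —
#' a signed log-probability analogous to a log-odds ratio. Tails are
#' computed in log space so extreme deviations survive double precision.
#' Non-integer observed counts (the alignment side) enter the CDF at
#' their floor by default; `"round"` and `"continuous"` (regularized
#' incomplete gamma) alternatives are provided.
#'
#' @param exp expected pair count (> 0).
#' @param obs observed pair count (>= 0, possibly non-integer).
#' @param obs_mode how non-integer `obs` enters the CDF.
#' @return The score (vectorized); `NA` where `exp <= 0`.
#' @export
association_score <- function(exp, obs, obs_mode = c("floor", "round", "continuous")) {
  obs_mode <- match.arg(obs_mode)
  stopifnot(length(exp) == length(obs) || length(exp) == 1 || length(obs) == 1)
  n <- max(length(exp), length(obs))
  exp <- rep_len(exp, n)
  obs <- rep_len(obs, n)
  out <- rep(NA_real_, n)
  valid <- exp > 0 & obs >= 0
  k <- switch(obs_mode, floor = floor(obs), round = round(obs), continuous = obs)
  log_cdf <- function(k, lambda) {
    if (obs_mode == "continuous") {
      # P(X <= x) continued to real x via the regularized gamma integral
      stats::pgamma(lambda, shape = k + 1, lower.tail = FALSE, log.p = TRUE)
    } else {
      stats::ppois(k, lambda, log.p = TRUE)
    }
  }
  log_sf <- function(k, lambda) {
    # log P(X > k), the strict upper tail
    if (obs_mode == "continuous") {
      stats::pgamma(lambda, shape = k + 1, lower.tail = TRUE, log.p = TRUE)
    } else {
      stats::ppois(k, lambda, lower.tail = FALSE, log.p = TRUE)
    }
  }
  hi <- valid & obs > exp
  lo <- valid & obs < exp
  eq <- valid & obs == exp
  out[hi] <- -log_sf(k[hi], exp[hi])
  out[lo] <- log_cdf(k[lo], exp[lo])
  out[eq] <- 0
  out
}

#' Association table for a gene's driver states
#'
#' Builds the pair universe — every pair of mutation states with at least
#' one member a selected driver, present in at least one tumor or one
#' alignment row — and scores each pair in both the tumor table and the
#' leaf-weighted alignment. Pairs with a score magnitude of 1 or less in
#' either dataset are marked discarded.
#'
#' @param family a [gene_family].
#' @param records mutation records for the gene (with `column`, see
#'   [map_mutations_to_columns]).
#' @param drivers tibble of selected drivers with `pos`, `alt_aa`,
#'   `column`.
#' @param weights a [leaf_weights].
#' @param n_tumors total tumors in the dataset.
#' @param obs_mode passed to [association_score].
#' @return Tibble: one row per pair with `pos1`, `res1`, `pos2`, `res2`,
#'   `exp_cosmic`, `obs_cosmic`, `exp_msa`, `obs_msa`, `score_cosmic`,
#'   `score_msa`, `kept`.
#' @export
association_table <- function(family, records, drivers, weights,
                              n_tumors = NULL, obs_mode = "floor") {
  states <- dplyr::distinct(records[, c("pos", "alt_aa", "column")])
  dkey <- paste(drivers$pos, drivers$alt_aa)
  states$is_driver <- paste(states$pos, states$alt_aa) %in% dkey
  if (!any(states$is_driver) || nrow(states) < 2) {
    return(tibble(pos1 = integer(), res1 = character(), pos2 = integer(),
                  res2 = character(), exp_cosmic = numeric(),
                  obs_cosmic = numeric(), exp_msa = numeric(),
                  obs_msa = numeric(), score_cosmic = numeric(),
                  score_msa = numeric(), kept = logical()))
  }
  n_tumors <- n_tumors %||% dplyr::n_distinct(records$sample_id)
  pairs <- t(utils::combn(nrow(states), 2))
  keep <- states$is_driver[pairs[, 1]] | states$is_driver[pairs[, 2]]
  keep <- keep & states$pos[pairs[, 1]] != states$pos[pairs[, 2]]
  pairs <- pairs[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    s1 <- states[pairs[i, 1], ]
    s2 <- states[pairs[i, 2], ]
    cc <- cosmic_pair_counts(records, s1$pos, s1$alt_aa, s2$pos, s2$alt_aa,
                             n_tumors = n_tumors)
    mm <- msa_pair_counts(family, weights, s1$column, s1$alt_aa,
                          s2$column, s2$alt_aa)
    tibble(
      pos1 = s1$pos, res1 = s1$alt_aa, pos2 = s2$pos, res2 = s2$alt_aa,
      exp_cosmic = if (is.null(cc)) NA_real_ else cc$exp,
      obs_cosmic = if (is.null(cc)) NA_real_ else cc$obs,
      exp_msa = if (is.null(mm)) NA_real_ else mm$exp,
      obs_msa = if (is.null(mm)) NA_real_ else mm$obs
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$score_cosmic <- association_score(out$exp_cosmic, out$obs_cosmic,
                                        obs_mode = obs_mode)
  out$score_msa <- association_score(out$exp_msa, out$obs_msa,
                                     obs_mode = obs_mode)
  out$kept <- !is.na(out$score_cosmic) & !is.na(out$score_msa) &
    abs(out$score_cosmic) > 1 & abs(out$score_msa) > 1
  out
}

#' Classify scored pairs into association quadrants
#'
#' Kept pairs (both score magnitudes above 1) are classified by the signs
#' of the tumor-table and alignment scores: `++` co-occurring more than
#' expected in both, `--` less in both, `+-`/`-+` discordant.
#'
#' @param records output of [association_table].
#' @return List with `counts` (tibble quadrant/n) and `outliers` (kept
#'   pairs with quadrant, sorted by combined magnitude).
#' @export
association_quadrants <- function(records) {
  kept <- records[records$kept, ]
  sgn <- function(x) ifelse(x > 0, "+", "-")
  kept$quadrant <- paste0(sgn(kept$score_cosmic), sgn(kept$score_msa))
  counts <- kept |>
    dplyr::count(.data$quadrant) |>
    tidyr::complete(quadrant = c("++", "--", "+-", "-+"),
                    fill = list(n = 0L))
  outliers <- kept |>
    dplyr::mutate(magnitude = abs(.data$score_cosmic) + abs(.data$score_msa)) |>
    dplyr::arrange(.data$quadrant, dplyr::desc(.data$magnitude))
  list(counts = counts, outliers = outliers)
}
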