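# Clade-level driver prevalence, bootstrap summaries, species mode
# residues and target-clade identification.

#' Mode residue of a species at an alignment column
#'
#' The most frequent residue (gaps included) among a species' sequences
#' at the column. Ties are broken toward the human reference residue at
#' that column, then lexicographically.
#'
#' @param msa an [msa].
#' @param taxa taxon annotations.
#' @param species species name.
#' @param column 1-based alignment column.
#' @return A single character (residue or `-`).
#' @export
species_mode_residue <- function(msa, taxa, species, column) {
  rows <- taxa$seq_id[taxa$species == species]
  rows <- intersect(rows, rownames(msa$mat))
  if (length(rows) == 0) abort(sprintf("species '%s' has no alignment rows", species))
  chars <- msa$mat[rows, column]
  chars[chars == UNKNOWN] <- GAP
  cnt <- table(chars)
  top <- names(cnt)[cnt == max(cnt)]
  if (length(top) == 1) return(top)
  ref <- unname(msa$mat[msa$reference_id, column])
  if (ref %in% top) return(ref)
  sort(top)[1]
}

# Mode residues for all species at a column, as a named vector.
species_modes <- function(msa, taxa, column) {
  sp <- unique(taxa$species[taxa$seq_id %in% rownames(msa$mat)])
  stats::setNames(
    vapply(sp, function(s) species_mode_residue(msa, taxa, s, column),
           character(1)),
    sp)
}

#' Species harboring a driver state
#'
#' Under the default `"mode"` convention a species harbors the state when
#' its mode residue at the column equals the driver residue; `"any"`
#' requires only one sequence carrying it.
#'
#' @param family a [gene_family].
#' @param column alignment column.
#' @param residue driver residue.
#' @param convention `"mode"` or `"any"`.
#' @return Character vector of harboring species names.
#' @export
harboring_species <- function(family, column, residue,
                              convention = c("mode", "any")) {
  convention <- match.arg(convention)
  taxa <- family$taxa
  if (convention == "mode") {
    m <- species_modes(family$msa, taxa, column)
    names(m)[m == residue]
  } else {
    rows <- rownames(family$msa$mat)
    hit <- rows[family$msa$mat[, column] == residue]
    unique(taxa$species[taxa$seq_id %in% hit])
  }
}

#' Leaf-weighted driver-state frequency within a clade
#'
#' The summed leaf weight of the clade's tree sequences carrying the
#' driver residue at the column, divided by the summed leaf weight of the
#' clade's sequences with any non-gap residue there.
#'
#' @param family a [gene_family].
#' @param weights a [leaf_weights].
#' @param clade major clade label.
#' @param column alignment column.
#' @param residue driver residue.
#' @return Frequency in `[0, 1]`, or `NA` when no clade sequence has the
#'   site.
#' @export
clade_driver_frequency <- function(family, weights, clade, column, residue) {
  tips <- intersect(family$taxa$seq_id[family$taxa$clade == clade],
                    family$idx$tip_label)
  if (length(tips) == 0) return(NA_real_)
  chars <- family$msa$mat[tips, column]
  ok <- !is_gaplike(chars)
  if (!any(ok)) return(NA_real_)
  w <- weights$leaf[tips]
  denom <- sum(w[ok])
  if (denom == 0) return(NA_real_)
  sum(w[ok & chars == residue]) / denom
}

#' Bootstrap percentiles of the mean clade frequency
#'
#' Resamples the per-driver frequency set with replacement `B` times,
#' records each resample's mean, and returns the 25th, 50th and 75th
#' percentiles of those means.
#'
#' @param frequencies numeric vector of per-driver frequencies (`NA`
#'   dropped).
#' @param B number of bootstrap resamples (default 1000).
#' @param seed optional seed for reproducibility.
#' @return Named numeric vector `p25`, `p50`, `p75`.
#' @export
bootstrap_clade_means <- function(frequencies, B = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- frequencies[!is.na(frequencies)]
  if (length(x) == 0) return(c(p25 = NA_real_, p50 = NA_real_, p75 = NA_real_))
  means <- vapply(seq_len(B), function(i) mean(sample(x, replace = TRUE)),
                  numeric(1))
  stats::setNames(stats::quantile(means, c(0.25, 0.5, 0.75), names = FALSE),
                  c("p25", "p50", "p75"))
}

#' Per-driver, per-clade frequency table with bootstrap summaries
#'
#' @param family a [gene_family].
#' @param drivers tibble with `pos`, `alt_aa`, `column`.
#' @param weights a [leaf_weights].
#' @param B bootstrap resamples per clade.
#' @param seed optional seed.
#' @return List with `per_driver` (driver x clade frequencies) and
#'   `per_clade` (bootstrap percentiles of the mean frequency over
#'   drivers).
#' @export
clade_frequency_table <- function(family, drivers, weights, B = 1000,
                                  seed = NULL) {
  clades <- intersect(MAJOR_CLADES, unique(family$taxa$clade))
  per_driver <- tidyr::expand_grid(
    i = seq_len(nrow(drivers)), clade = clades) |>
    dplyr::mutate(
      pos = drivers$pos[.data$i], residue = drivers$alt_aa[.data$i],
      frequency = purrr::map2_dbl(.data$i, .data$clade, function(i, cl) {
        clade_driver_frequency(family, weights, cl, drivers$column[i],
                               drivers$alt_aa[i])
      })) |>
    dplyr::select(-"i")
  if (!is.null(seed)) set.seed(seed)
  per_clade <- per_driver |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(
      n_drivers = sum(!is.na(.data$frequency)),
      p25 = bootstrap_clade_means(.data$frequency, B)[["p25"]],
      p50 = bootstrap_clade_means(.data$frequency, B)[["p50"]],
      p75 = bootstrap_clade_means(.data$frequency, B)[["p75"]],
      .groups = "drop")
  list(per_driver = per_driver, per_clade = per_clade)
}

#' Target clade of a driver state
#'
#' The taxonomic group summarizing where a driver state occurs: the
#' largest group in which more than half of the species harbor the state
#' (majority rule), or the smallest group containing more than 90% of all
#' harboring species (ninety-percent rule), whichever contains fewer
#' species. If no group satisfies the majority rule the ninety-percent
#' clade is returned.
#'
#' @param taxa taxon annotations (the `path` column defines the taxonomy;
#'   a species' own name terminates its path).
#' @param harboring character vector of harboring species.
#' @param all_species species eligible at the site (e.g. those with the
#'   site present); defaults to all annotated species.
#' @return One-row tibble: `clade`, `rule` (`"majority"` or
#'   `"ninety-percent"`), `n_species`, `n_harboring`.
#' @export
find_target_clade <- function(taxa, harboring, all_species = NULL) {
  if (length(harboring) == 0) abort("no harboring species")
  all_species <- all_species %||% unique(taxa$species)
  paths <- strsplit(taxa$path[!duplicated(taxa$species)], ";", fixed = TRUE)
  names(paths) <- taxa$species[!duplicated(taxa$species)]
  paths <- paths[names(paths) %in% all_species]
  nodes <- unique(unlist(paths))
  under <- lapply(nodes, function(nd)
    names(paths)[vapply(paths, function(p) nd %in% p, logical(1))])
  names(under) <- nodes
  n_under <- lengths(under)
  n_harb <- vapply(under, function(s) sum(s %in% harboring), integer(1))
  # majority rule: largest node where harboring species are the majority
  maj <- which(n_harb / n_under > 0.5)
  clade_a <- if (length(maj)) {
    m <- maj[order(-n_under[maj], nodes[maj])][1]
    nodes[m]
  } else NA_character_
  # ninety-percent rule: smallest node covering > 90% of harboring species
  cov <- which(n_harb > 0.9 * length(harboring))
  m <- cov[order(n_under[cov], nodes[cov])][1]
  clade_b <- nodes[m]
  pick_b <- is.na(clade_a) || n_under[clade_b] <= n_under[clade_a]
  clade <- if (pick_b) clade_b else clade_a
  tibble(clade = clade,
         rule = if (pick_b) "ninety-percent" else "majority",
         n_species = n_under[[clade]], n_harboring = n_harb[[clade]])
}

#' Histogram of drivers binned by species frequency
#'
#' For each driver, the fraction of species with the site present whose
#' mode residue is the driver residue, binned into a zero bin plus ten
#' equal-width bins over (0, 1].
#'
#' @param family a [gene_family].
#' @param drivers tibble with `pos`, `alt_aa`, `column`.
#' @return List with `per_driver` (driver, fraction) and `histogram`
#'   (bin, n).
#' @export
species_frequency_histogram <- function(family, drivers) {
  frac <- vapply(seq_len(nrow(drivers)), function(i) {
    m <- species_modes(family$msa, family$taxa, drivers$column[i])
    present <- m[m != GAP]
    if (length(present) == 0) return(0)
    mean(present == drivers$alt_aa[i])
  }, numeric(1))
  breaks <- seq(0, 1, by = 0.1)
  labels <- c("0", paste0("(", utils::head(breaks, -1), ",", breaks[-1], "]"))
  bin <- ifelse(frac == 0, "0",
                labels[-1][findInterval(frac, breaks, left.open = TRUE,
                                        rightmost.closed = TRUE)])
  hist <- tibble(bin = factor(bin, levels = labels)) |>
    dplyr::count(.data$bin, .drop = FALSE)
  list(per_driver = tibble(pos = drivers$pos, residue = drivers$alt_aa,
                           fraction = frac),
       histogram = hist)
}
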