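# End-to-end orchestration of the per-gene analysis.

#' Analysis run configuration
#'
#' Collects the pipeline thresholds; defaults are the standard analysis
#' settings used throughout the package.
#'
#' @param rank_threshold strict rank cutoff for driver selection.
#' @param missense_threshold maximum more-frequent distinct missense
#'   mutations.
#' @param max_per_gene driver cap per gene.
#' @param p_max co-occurrence probability threshold for ensembles.
#' @param min_driver_leaves minimum driver-bearing leaves.
#' @param local_min Local Score threshold for pair structures.
#' @param bootstrap_B bootstrap resamples for clade summaries.
#' @param max_exhaustive largest candidate pool searched exhaustively.
#' @param seed seed for the bootstrap.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(rank_threshold = 20, missense_threshold = 5,
                       max_per_gene = 9, p_max = 0.01,
                       min_driver_leaves = 4, local_min = 1.9,
                       bootstrap_B = 1000, max_exhaustive = 15, seed = 1) {
  structure(
    list(rank_threshold = rank_threshold,
         missense_threshold = missense_threshold,
         max_per_gene = max_per_gene, p_max = p_max,
         min_driver_leaves = min_driver_leaves, local_min = local_min,
         bootstrap_B = bootstrap_B, max_exhaustive = max_exhaustive,
         seed = seed),
    class = "run_config")
}

#' Run the full per-gene analysis
#'
#' Executes driver selection, conservation scoring, leaf weighting,
#' ancestral reconstruction, clade statistics, compensatory ensemble
#' construction, association scoring and structure coverage for one gene
#' family, collecting all stage outputs and a manifest.
#'
#' @param family a [gene_family].
#' @param tumor_table mutation records for the gene.
#' @param hits optional structure hit table (see [read_structure_hits]).
#' @param config a [run_config].
#' @param n_tumors total tumors in the dataset (default: distinct
#'   samples in `tumor_table`).
#' @return Object of class `gene_report`: list with `drivers`,
#'   `conservation`, `weights`, `record`, `clade_freq`, `target_clades`,
#'   `ensembles`, `associations`, `structures`, `manifest`.
#' @export
run_gene <- function(family, tumor_table, hits = NULL,
                     config = run_config(), n_tumors = NULL) {
  n_tumors <- n_tumors %||% dplyr::n_distinct(tumor_table$sample_id)
  ranked <- compute_ranks(tumor_table, gene = family$gene)
  ranked <- select_drivers(ranked,
                           rank_threshold = config$rank_threshold,
                           missense_threshold = config$missense_threshold,
                           max_per_gene = config$max_per_gene)
  drivers <- suppressMessages(
    map_mutations_to_columns(ranked[ranked$selected, ], family))
  conservation <- conservation_track(family)
  weights <- leaf_weights(family$tree)
  empty <- nrow(drivers) == 0
  record <- NULL
  ensembles <- tibble()
  associations <- tibble()
  clade_freq <- list(per_driver = tibble(), per_clade = tibble())
  target_clades <- tibble()
  structures <- tibble()
  if (!empty) {
    record <- ancestral_record(family, weights)
    ensembles <- build_ensembles(
      family, record,
      tibble(column = drivers$column, residue = drivers$alt_aa),
      p_max = config$p_max, min_leaves = config$min_driver_leaves,
      max_exhaustive = config$max_exhaustive)
    recs <- suppressMessages(map_mutations_to_columns(tumor_table, family))
    associations <- association_table(family, recs, drivers, weights,
                                      n_tumors = n_tumors)
    clade_freq <- clade_frequency_table(family, drivers, weights,
                                        B = config$bootstrap_B,
                                        seed = config$seed)
    target_clades <- dplyr::bind_rows(lapply(seq_len(nrow(drivers)), function(i) {
      harb <- harboring_species(family, drivers$column[i], drivers$alt_aa[i])
      if (length(harb) == 0) return(NULL)
      modes <- species_modes(family$msa, family$taxa, drivers$column[i])
      eligible <- names(modes)[modes != GAP]
      dplyr::bind_cols(tibble(pos = drivers$pos[i], residue = drivers$alt_aa[i]),
                       find_target_clade(family$taxa, harb, eligible))
    }))
    if (!is.null(hits)) {
      protein_length <- nrow(family$ref_map)
      scored <- score_hits(hits, protein_length)
      structures <- structure_site_coverage(scored, drivers$pos)
      pair_rows <- lapply(which(ensembles$accepted), function(i) {
        members <- ensembles$members[[i]]
        dpos <- family$ref_map$ref_pos[match(ensembles$column[i],
                                             family$ref_map$column)]
        dplyr::bind_rows(lapply(seq_len(nrow(members)), function(j) {
          mpos <- family$ref_map$ref_pos[match(members$site[j],
                                               family$ref_map$column)]
          b <- best_pair_structure(scored, dpos, mpos,
                                   local_min = config$local_min)
          if (is.null(b)) return(NULL)
          dplyr::bind_cols(tibble(driver_pos = dpos, member_pos = mpos), b)
        }))
      })
      structures <- list(per_site = structures,
                         per_pair = dplyr::bind_rows(pair_rows))
    }
  }
  manifest <- list(
    gene = family$gene,
    n_sequences = nrow(family$msa$mat),
    n_columns = family$msa$n_columns,
    n_leaves = length(family$tree$tip.label),
    n_tumors = n_tumors,
    n_mutation_records = nrow(tumor_table),
    n_candidates = nrow(ranked),
    n_drivers = nrow(drivers),
    n_ensembles = if (nrow(ensembles)) sum(ensembles$accepted) else 0L,
    n_kept_associations = if (nrow(associations)) sum(associations$kept) else 0L,
    skipped = if (empty) "no drivers selected; downstream stages skipped" else NA,
    config = unclass(config)
  )
  structure(
    list(drivers = drivers, candidates = ranked, conservation = conservation,
         weights = weights, record = record, clade_freq = clade_freq,
         target_clades = target_clades, ensembles = ensembles,
         associations = associations, structures = structures,
         manifest = manifest),
    class = "gene_report")
}

#' @export
print.gene_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<gene_report> %s: %d drivers, %d ensembles, %d kept associations\n",
    m$gene, m$n_drivers, m$n_ensembles, m$n_kept_associations))
  invisible(x)
}

#' Write a gene report to TSV files
#'
#' Writes every tabular stage output plus a YAML manifest into `dir`;
#' reruns with identical inputs produce byte-identical files.
#'
#' @param report a [run_gene] result.
#' @param dir output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    df <- as.data.frame(df)
    list_cols <- vapply(df, is.list, logical(1))
    for (j in which(list_cols)) {
      df[[j]] <- vapply(df[[j]], function(v) {
        if (is.data.frame(v)) paste(paste(v$site, v$residue, sep = ":"),
                                    collapse = ",")
        else paste(unlist(v), collapse = ",")
      }, character(1))
    }
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    candidates = wt(report$candidates, "candidates"),
    conservation = wt(report$conservation, "conservation"),
    ensembles = if (nrow(report$ensembles)) wt(report$ensembles, "ensembles"),
    associations = if (nrow(report$associations))
      wt(report$associations, "associations"),
    clade_freq = if (nrow(report$clade_freq$per_clade))
      wt(report$clade_freq$per_clade, "clade_frequencies"),
    target_clades = if (nrow(report$target_clades))
      wt(report$target_clades, "target_clades"),
    structures = if (is.list(report$structures) &&
                       !is.null(report$structures$per_site) &&
                       nrow(report$structures$per_site))
      wt(report$structures$per_site, "structure_sites"),
    structure_pairs = if (is.list(report$structures) &&
                            !is.null(report$structures$per_pair) &&
                            nrow(report$structures$per_pair))
      wt(report$structures$per_pair, "structure_pairs")
  )
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(report$manifest, manifest_path)
  invisible(c(paths, manifest = manifest_path))
}
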