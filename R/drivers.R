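# Ranking of tumor mutations and driver-candidate selection.

#' Rank the distinct mutations of a gene by tumor recurrence
#'
#' Records are first deduplicated to (mutation, tumor sample) pairs and
#' common-polymorphism (SNP-flagged) mutations are removed. Each remaining
#' distinct mutation is counted across tumor samples and assigned a rank
#' equal to 1 plus the number of distinct mutations (of any class)
#' observed in strictly more tumors, so equally frequent mutations share a
#' rank. A separate field counts the distinct *missense* mutations
#' observed strictly more frequently.
#'
#' @param records mutation records (see [read_mutation_table]); may span
#'   several genes.
#' @param gene optional gene id to restrict to.
#' @return Tibble with one row per distinct non-SNP mutation: `gene`,
#'   `ref_aa`, `pos`, `alt_aa`, `class`, `n_tumors`, `rank`,
#'   `n_more_frequent_missense`.
#' @export
compute_ranks <- function(records, gene = NULL) {
  if (!is.null(gene)) records <- records[records$gene == gene, ]
  records <- records[!records$snp, ]
  if (nrow(records) == 0) {
    return(tibble(gene = character(), ref_aa = character(), pos = integer(),
                  alt_aa = character(), class = character(),
                  n_tumors = integer(), rank = integer(),
                  n_more_frequent_missense = integer()))
  }
  counts <- records |>
    dplyr::distinct(.data$gene, .data$ref_aa, .data$pos, .data$alt_aa,
                    .data$class, .data$sample_id) |>
    dplyr::count(.data$gene, .data$ref_aa, .data$pos, .data$alt_aa,
                 .data$class, name = "n_tumors")
  counts |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(
      rank = vapply(.data$n_tumors,
                    function(k) 1L + sum(n_tumors > k), integer(1)),
      n_more_frequent_missense = vapply(
        .data$n_tumors,
        function(k) sum(n_tumors > k & class == "missense"), integer(1))
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene, .data$rank, .data$pos, .data$alt_aa)
}

#' Select driver candidates per gene
#'
#' Keeps missense mutations with rank below `rank_threshold` that are
#' observed less frequently than at most `missense_threshold` distinct
#' missense mutations, then truncates to the `max_per_gene` most recurrent
#' per gene (ties broken by rank, position, then alternate residue, for
#' reproducibility). Nonsense and SNP mutations are never selected; an
#' empty selection is a legitimate outcome.
#'
#' @param candidates output of [compute_ranks].
#' @param rank_threshold strict upper bound on rank (default 20).
#' @param missense_threshold maximum number of strictly more frequent
#'   distinct missense mutations (default 5).
#' @param max_per_gene cap on selected drivers per gene (default 9).
#' @return `candidates` with an added logical `selected` column.
#' @export
select_drivers <- function(candidates, rank_threshold = 20,
                           missense_threshold = 5, max_per_gene = 9) {
  ok <- candidates$class == "missense" &
    candidates$rank < rank_threshold &
    candidates$n_more_frequent_missense <= missense_threshold
  sel <- candidates[ok, ] |>
    dplyr::arrange(.data$gene, dplyr::desc(.data$n_tumors), .data$rank,
                   .data$pos, .data$alt_aa) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_head(n = max_per_gene) |>
    dplyr::ungroup()
  key <- function(d) paste(d$gene, d$ref_aa, d$pos, d$alt_aa)
  candidates$selected <- key(candidates) %in% key(sel)
  candidates
}
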