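# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gene family into a per-sequence tibble
#'
#' @param x a [gene_family].
#' @param ... unused.
#' @return Tibble: `seq_id`, `species`, `clade`, `in_tree`, `n_residues`.
#' @export
tidy.gene_family <- function(x, ...) {
  ids <- rownames(x$msa$mat)
  tibble(
    seq_id = ids,
    species = x$taxa$species[match(ids, x$taxa$seq_id)],
    clade = x$taxa$clade[match(ids, x$taxa$seq_id)],
    in_tree = ids %in% x$tree$tip.label,
    n_residues = rowSums(!is_gaplike(x$msa$mat))
  )
}

#' One-row summary of a gene family
#'
#' @param x a [gene_family].
#' @param ... unused.
#' @return Tibble with sequence, column, leaf and clade counts.
#' @export
glance.gene_family <- function(x, ...) {
  tibble(
    gene = x$gene,
    n_sequences = nrow(x$msa$mat),
    n_columns = x$msa$n_columns,
    n_leaves = length(x$tree$tip.label),
    n_species = dplyr::n_distinct(x$taxa$species),
    n_clades = dplyr::n_distinct(x$taxa$clade),
    reference_length = nrow(x$ref_map)
  )
}

#' Tidy leaf weights
#'
#' @param x a [leaf_weights].
#' @param ... unused.
#' @return Tibble: `leaf`, `weight`.
#' @export
tidy.leaf_weights <- function(x, ...) {
  tibble(leaf = names(x$leaf), weight = unname(x$leaf))
}

#' Tidy an ancestral reconstruction into node assignments
#'
#' @param x an `ancestral_states`.
#' @param ... unused.
#' @return Tibble: `node`, `residue` (`NA` = undefined), `weight` of the
#'   assigned residue.
#' @export
tidy.ancestral_states <- function(x, ...) {
  w <- if (is.null(x$final)) rep(NA_real_, length(x$assignment)) else
    apply(x$final, 1, max)
  tibble(node = seq_along(x$assignment), residue = x$assignment, weight = w)
}

#' Tidy an ancestral record into its transition table
#'
#' @param x an [ancestral_record].
#' @param ... unused.
#' @return The transitions tibble (`site`, `parent`, `child`, `from`,
#'   `to`).
#' @export
tidy.ancestral_record <- function(x, ...) x$transitions

#' Tidy a gene report into its ensemble table
#'
#' @param x a `gene_report`.
#' @param ... unused.
#' @return The ensembles tibble with members flattened to
#'   `site:residue` strings.
#' @export
tidy.gene_report <- function(x, ...) {
  e <- x$ensembles
  if (nrow(e) == 0) return(e)
  e$members <- vapply(e$members, function(m)
    paste(paste(m$site, m$residue, sep = ":"), collapse = ","), character(1))
  e
}

#' One-row summary of a gene report
#'
#' @param x a `gene_report`.
#' @param ... unused.
#' @return Tibble of headline counts for the run.
#' @export
glance.gene_report <- function(x, ...) {
  m <- x$manifest
  tibble(gene = m$gene, n_candidates = m$n_candidates,
         n_drivers = m$n_drivers, n_ensembles = m$n_ensembles,
         n_kept_associations = m$n_kept_associations,
         n_tumors = m$n_tumors)
}
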