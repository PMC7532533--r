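#' Construct a protein multiple sequence alignment object
#'
#' An `msa` stores an aligned protein family as a character matrix (one row
#' per sequence, one column per alignment position) together with the id of
#' the designated human reference row used for coordinate bookkeeping.
#' Residues are restricted to the 20 canonical amino acids, the gap symbol
#' `-` and the explicit unknown symbol `X`; anything else (B, Z, U, J, O,
#' `*`, `.`) is mapped to `X`, and unknowns are treated as gaps by every
#' counting operation.
#'
#' @param sequences named character vector of aligned sequences, all the
#'   same length.
#' @param reference_id name of the reference row; must be present.
#' @return An object of class `msa` with elements `mat` (character matrix),
#'   `reference_id` and `n_columns`.
#' @export
msa <- function(sequences, reference_id) {
  if (length(sequences) == 0) abort("empty alignment")
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    abort("all sequences must be named")
  }
  if (anyDuplicated(names(sequences))) abort("duplicated sequence ids")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    abort(sprintf("ragged alignment: row lengths %s",
                  paste(sort(unique(lens)), collapse = ", ")))
  }
  if (!reference_id %in% names(sequences)) {
    abort(sprintf("reference row '%s' not found in alignment", reference_id))
  }
  seqs <- toupper(sequences)
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(sequences)
  mat[mat == "."] <- GAP
  bad <- !(mat %in% c(AA20, GAP, UNKNOWN))
  if (any(bad)) mat[bad] <- UNKNOWN
  structure(
    list(mat = mat, reference_id = reference_id, n_columns = ncol(mat)),
    class = "msa"
  )
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns (reference: %s)\n",
              nrow(x$mat), x$n_columns, x$reference_id))
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' @param path path to an aligned FASTA file.
#' @param reference_id id of the human reference row (must be present).
#' @return An [msa] object; residues are uppercased and non-canonical
#'   characters mapped to `X`.
#' @export
read_msa <- function(path, reference_id) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  if (length(recs) == 0) abort(sprintf("empty FASTA: %s", path))
  seqs <- vapply(recs, as.character, character(1))
  msa(seqs, reference_id)
}

#' Write an alignment back to FASTA
#'
#' @param x an [msa] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path) {
  seqs <- apply(x$mat, 1, paste0, collapse = "")
  seqinr::write.fasta(as.list(unname(seqs)), names = rownames(x$mat),
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' Read a rooted gene tree in Newick format
#'
#' Leaves must be a subset of the alignment rows; alignment rows without a
#' leaf (e.g. a reference row added only for coordinates) are allowed and
#' are excluded from all tree-based statistics.
#'
#' @param path path to a Newick file with branch lengths.
#' @param msa the [msa] whose rows the leaves must match.
#' @return An ape `phylo` object, validated.
#' @export
read_tree <- function(path, msa) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  phy <- ape::read.tree(path)
  if (is.null(phy)) abort(sprintf("could not parse Newick: %s", path))
  validate_tree(phy, msa)
}

#' Validate a phylogeny against an alignment
#'
#' @param phy an ape `phylo`.
#' @param msa the matching [msa].
#' @return `phy`, invisibly checked: one root, non-negative branch lengths,
#'   every leaf present among MSA rows. MSA rows absent from the tree only
#'   raise a warning.
#' @export
validate_tree <- function(phy, msa) {
  if (is.null(phy$edge.length)) abort("tree has no branch lengths")
  if (any(phy$edge.length < 0)) abort("negative branch length in tree")
  missing <- setdiff(phy$tip.label, rownames(msa$mat))
  if (length(missing)) {
    abort(sprintf("tree leaves absent from alignment: %s",
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(rownames(msa$mat), phy$tip.label)
  if (length(extra)) {
    warn(sprintf(
      "%d alignment row(s) not in tree (excluded from tree-based statistics): %s",
      length(extra), paste(extra, collapse = ", ")))
  }
  nb <- tabulate(phy$edge[, 1])
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])
  if (length(root) == 1 && nb[root] > 2) {
    inform("tree has a multifurcating root; accepted as-is")
  }
  phy
}

#' Read the taxon annotation table
#'
#' A TSV with header columns `seq_id`, `species`, `clade` and `path`, where
#' `clade` is one of vertebrate, invertebrate, protist, fungus, plant,
#' prokaryote, and `path` is the taxonomy from root to species separated by
#' semicolons (the species name itself is appended if absent).
#'
#' @param path path to the TSV.
#' @return A tibble with columns `seq_id`, `species`, `clade`, `path`.
#' @export
read_taxa <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "species", "clade", "path")
  if (!all(need %in% names(tab))) {
    abort(sprintf("taxon table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  validate_taxa(as_tibble(tab[need]))
}

validate_taxa <- function(taxa) {
  bad <- setdiff(unique(taxa$clade), MAJOR_CLADES)
  if (length(bad)) {
    abort(sprintf("unknown clade label(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(!nzchar(taxa$path))) abort("empty taxonomy path")
  # ensure the species terminates its own path
  parts <- strsplit(taxa$path, ";", fixed = TRUE)
  taxa$path <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (p[length(p)] != taxa$species[i]) p <- c(p, taxa$species[i])
    paste(p, collapse = ";")
  }, character(1))
  taxa
}

#' Read a tumor mutation table
#'
#' A TSV with header columns `gene`, `sample_id`, `ref_aa`, `pos`,
#' `alt_aa`, `snp` (logical), `class` (missense, nonsense or other), one
#' row per (mutation, tumor sample) observation, emulating per-tumor
#' protein-level mutation records.
#'
#' @param path path to the TSV.
#' @return A tibble of mutation records.
#' @export
read_mutation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample_id", "ref_aa", "pos", "alt_aa", "snp", "class")
  if (!all(need %in% names(tab))) {
    abort(sprintf("mutation table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  tab <- as_tibble(tab[need])
  tab$snp <- as.logical(tab$snp)
  validate_mutations(tab)
}

validate_mutations <- function(records) {
  bad <- setdiff(unique(records$class), c("missense", "nonsense", "other"))
  if (length(bad)) {
    abort(sprintf("unknown mutation class(es): %s", paste(bad, collapse = ", ")))
  }
  if (any(records$pos < 1)) abort("mutation positions must be >= 1")
  same <- records$class == "missense" & records$ref_aa == records$alt_aa
  if (any(same)) abort("missense records with ref == alt")
  records
}

#' Read coordinate offset rules from YAML
#'
#' Rules remap positions of a mutation table onto the reference sequence
#' numbering when the two disagree (e.g. alternative start sites or
#' truncated references). The YAML maps each gene to a list of rules with
#' fields `start`, `end` (a number or the string `"end"` for an open
#' interval) and `offset` (signed integer).
#'
#' @param path path to the YAML file.
#' @return A tibble with columns `gene`, `start`, `end` (Inf when open),
#'   `offset`; intervals per gene are checked for overlap.
#' @export
read_offset_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- purrr::imap(raw, function(rules, gene) {
    purrr::map(rules, function(r) {
      end <- r$end %||% "end"
      tibble(gene = gene,
             start = as.numeric(r$start),
             end = if (identical(end, "end")) Inf else as.numeric(end),
             offset = as.integer(r$offset))
    })
  })
  rules <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  validate_offset_rules(rules)
}

validate_offset_rules <- function(rules) {
  if (nrow(rules) == 0) return(rules)
  if (any(rules$start > rules$end)) abort("offset rule with start > end")
  split(rules, rules$gene) |> purrr::walk(function(g) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)])) {
      abort(sprintf("overlapping offset intervals for gene %s", g$gene[1]))
    }
  })
  rules
}

#' Apply position offset rules to mutation records
#'
#' Each record whose position falls in a rule interval for its gene is
#' shifted by that rule's offset; records matching no interval are
#' unchanged. When `reference_length` is given, shifted positions falling
#' outside `[1, reference_length]` are dropped with a message.
#'
#' @param records mutation records (see [read_mutation_table]).
#' @param rules offset rules (see [read_offset_rules]).
#' @param reference_length optional length of the reference protein.
#' @return The records tibble with remapped `pos`.
#' @export
apply_offsets <- function(records, rules, reference_length = NULL) {
  if (nrow(rules) > 0) {
    # offsets applied simultaneously: intervals match original positions
    newpos <- records$pos
    for (i in seq_len(nrow(rules))) {
      hit <- records$gene == rules$gene[i] &
        records$pos >= rules$start[i] & records$pos <= rules$end[i]
      newpos[hit] <- records$pos[hit] + rules$offset[i]
    }
    records$pos <- newpos
  }
  if (!is.null(reference_length)) {
    out <- records$pos < 1 | records$pos > reference_length
    if (any(out)) {
      inform(sprintf("dropping %d record(s) outside the reference after remapping",
                     sum(out)))
      records <- records[!out, ]
    }
  }
  records
}

#' Map reference protein positions to alignment columns
#'
#' @param msa an [msa] object.
#' @return A tibble with columns `ref_pos` (1-based position along the
#'   ungapped reference row) and `column` (1-based alignment column); a
#'   bijection covering every non-gap reference residue.
#' @export
build_reference_map <- function(msa) {
  ref <- msa$mat[msa$reference_id, ]
  cols <- which(!is_gaplike(ref))
  tibble(ref_pos = seq_along(cols), column = cols,
         ref_residue = unname(ref[cols]))
}

#' Place mutation records onto alignment columns
#'
#' Joins records to the reference map and drops records whose stated
#' reference residue disagrees with the reference row at the mapped
#' column, or whose position is unmapped, with a message.
#'
#' @param records mutation records for one gene.
#' @param family a [gene_family].
#' @return Records with added `column` and only residue-consistent rows.
#' @export
map_mutations_to_columns <- function(records, family) {
  m <- family$ref_map
  j <- match(records$pos, m$ref_pos)
  records$column <- m$column[j]
  unmapped <- is.na(records$column)
  mismatch <- !unmapped & records$ref_aa != m$ref_residue[j]
  if (any(unmapped | mismatch)) {
    inform(sprintf(
      "excluded %d unmapped and %d reference-mismatched mutation record(s)",
      sum(unmapped), sum(mismatch)))
  }
  records[!unmapped & !mismatch, ]
}

#' Bundle one gene family
#'
#' Ties together the alignment, rooted tree, taxon annotations and the
#' reference-position/column map for one gene. Alignment rows absent from
#' the tree stay available for coordinate mapping but are excluded from
#' leaf weighting, ancestry and frequency statistics.
#'
#' @param msa an [msa].
#' @param tree a validated ape `phylo` (see [read_tree]).
#' @param taxa taxon annotations covering every alignment row.
#' @param gene gene identifier.
#' @return An object of class `gene_family`.
#' @export
gene_family <- function(msa, tree, taxa, gene = "gene") {
  validate_tree(tree, msa)
  taxa <- validate_taxa(taxa)
  missing <- setdiff(rownames(msa$mat), taxa$seq_id)
  if (length(missing)) {
    abort(sprintf("alignment rows without taxon annotation: %s",
                  paste(missing, collapse = ", ")))
  }
  structure(
    list(gene = gene, msa = msa, tree = tree, taxa = taxa,
         ref_map = build_reference_map(msa),
         idx = tree_index(tree)),
    class = "gene_family"
  )
}

#' @export
print.gene_family <- function(x, ...) {
  cat(sprintf("<gene_family> %s: %d sequences x %d columns, %d tree leaves\n",
              x$gene, nrow(x$msa$mat), x$msa$n_columns, length(x$tree$tip.label)))
  invisible(x)
}
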