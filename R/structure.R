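# Structure hit scoring and selection of covering structures for driver
# sites and driver/compensator pairs.

#' Read a tabular structure search output
#'
#' Reads a 12-column tab-separated hit table (the standard outfmt-6
#' dialect: query, subject, identity, length, mismatches, gap opens,
#' qstart, qend, sstart, send, evalue, bitscore). Subject ids of the form
#' `PDBID_CHAIN` are split into structure and chain.
#'
#' @param path path to the TSV (no header).
#' @return Tibble of hits with `query`, `structure`, `chain`, `qstart`,
#'   `qend`, `bitscore` (plus the remaining standard columns).
#' @export
read_structure_hits <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.delim(path, header = FALSE, col.names = cols,
                           stringsAsFactors = FALSE)
  tab <- as_tibble(tab)
  parts <- strsplit(tab$subject, "_", fixed = TRUE)
  tab$structure <- vapply(parts, `[`, character(1), 1)
  tab$chain <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                      character(1))
  tab
}

#' Global and Local Scores for structure hits
#'
#' The Global Score is the hit's bit score divided by the full reference
#' protein length; the Local Score is the bit score divided by the length
#' of the query footprint (`qend - qstart + 1`). Zero-length footprints
#' are dropped with a message.
#'
#' @param hits hit table (see [read_structure_hits]).
#' @param protein_length length of the reference protein (> 0).
#' @return `hits` with added `global_score` and `local_score`.
#' @export
score_hits <- function(hits, protein_length) {
  if (protein_length <= 0) abort("protein_length must be > 0")
  if (any(hits$qstart > hits$qend)) {
    inform(sprintf("dropping %d hit(s) with empty footprint",
                   sum(hits$qstart > hits$qend)))
    hits <- hits[hits$qstart <= hits$qend, ]
  }
  hits$global_score <- hits$bitscore / protein_length
  hits$local_score <- hits$bitscore / (hits$qend - hits$qstart + 1)
  hits
}

#' Best covering structure for a single site
#'
#' Among hits whose query footprint contains the position, returns the
#' maximizer of `global_score^2 + local_score^2` (ties: higher local
#' score, then lexicographic subject id).
#'
#' @param scored_hits output of [score_hits].
#' @param position 1-based reference position.
#' @return One-row tibble with the chosen hit plus `combined`, or `NULL`
#'   when no hit covers the position.
#' @export
best_structure_per_site <- function(scored_hits, position) {
  cov <- scored_hits[scored_hits$qstart <= position &
                       scored_hits$qend >= position, ]
  if (nrow(cov) == 0) return(NULL)
  cov$combined <- cov$global_score^2 + cov$local_score^2
  cov <- cov[order(-cov$combined, -cov$local_score, cov$subject), ]
  cov[1, ]
}

#' Best structure covering a driver/compensator pair
#'
#' Among hits whose footprint encompasses both positions, returns the one
#' with the highest Local Score, flagged as passing when that score
#' reaches `local_min`.
#'
#' @param scored_hits output of [score_hits].
#' @param pos1,pos2 the two reference positions.
#' @param local_min Local Score threshold for a usable structure
#'   (default 1.9).
#' @return One-row tibble with added `passing`, or `NULL` when no hit
#'   covers both positions.
#' @export
best_pair_structure <- function(scored_hits, pos1, pos2, local_min = 1.9) {
  lo <- min(pos1, pos2)
  hi <- max(pos1, pos2)
  cov <- scored_hits[scored_hits$qstart <= lo & scored_hits$qend >= hi, ]
  if (nrow(cov) == 0) return(NULL)
  cov <- cov[order(-cov$local_score, cov$subject), ]
  out <- cov[1, ]
  out$passing <- out$local_score >= local_min
  out
}

#' Structure coverage report over driver sites
#'
#' @param scored_hits output of [score_hits].
#' @param positions reference positions to cover.
#' @return Tibble, one row per position: chosen `structure`, `chain`,
#'   `global_score`, `local_score`, `combined` (`NA` when uncovered).
#' @export
structure_site_coverage <- function(scored_hits, positions) {
  rows <- lapply(positions, function(p) {
    b <- best_structure_per_site(scored_hits, p)
    if (is.null(b)) {
      tibble(pos = p, structure = NA_character_, chain = NA_character_,
             global_score = NA_real_, local_score = NA_real_,
             combined = NA_real_)
    } else {
      tibble(pos = p, structure = b$structure, chain = b$chain,
             global_score = b$global_score, local_score = b$local_score,
             combined = b$combined)
    }
  })
  dplyr::bind_rows(rows)
}
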