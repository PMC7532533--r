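# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline geom_vline geom_errorbar labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a conservation track
#'
#' Homogeneity and its +/-3-site neighborhood mean along the alignment,
#' with deep sites marked.
#'
#' @param object a [conservation_track] tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.conservation_track <- function(object, ...) {
  ggplot(object, aes(x = .data$column)) +
    geom_line(aes(y = .data$h), colour = "grey60", na.rm = TRUE) +
    geom_line(aes(y = .data$neighborhood_h), colour = "steelblue",
              na.rm = TRUE) +
    geom_point(data = object[object$depth == "deep", ],
               aes(y = -0.05), shape = 15, size = 0.8, colour = "darkgreen",
               na.rm = TRUE) +
    labs(x = "alignment column", y = "homogeneity",
         title = "Site homogeneity (grey) and neighborhood mean (blue); deep sites marked") +
    theme_minimal()
}

#' Association quadrant plot
#'
#' Tumor-table association score against alignment association score for
#' kept mutation pairs; the unit box marks the discarded band.
#'
#' @param records output of [association_table].
#' @return A ggplot.
#' @export
plot_association_quadrants <- function(records) {
  kept <- records[records$kept & !is.na(records$kept), ]
  ggplot(kept, aes(x = .data$score_cosmic, y = .data$score_msa)) +
    geom_hline(yintercept = c(-1, 1), linetype = 3, colour = "grey50") +
    geom_vline(xintercept = c(-1, 1), linetype = 3, colour = "grey50") +
    geom_point(alpha = 0.7) +
    labs(x = "tumor-table association score",
         y = "alignment association score") +
    theme_minimal()
}

#' Clade frequency summary plot
#'
#' Bootstrap quartiles of the mean driver-state frequency per major
#' clade.
#'
#' @param per_clade the `per_clade` table of [clade_frequency_table].
#' @return A ggplot.
#' @export
plot_clade_frequencies <- function(per_clade) {
  ggplot(per_clade, aes(x = .data$clade, y = .data$p50)) +
    geom_errorbar(aes(ymin = .data$p25, ymax = .data$p75), width = 0.2) +
    geom_point(size = 2) +
    labs(x = NULL, y = "mean driver-state frequency (bootstrap quartiles)") +
    theme_minimal()
}

#' Structure coverage plot
#'
#' Combined (global^2 + local^2) score of the best covering structure at
#' each driver position.
#'
#' @param per_site output of [structure_site_coverage].
#' @return A ggplot.
#' @export
plot_structure_coverage <- function(per_site) {
  ggplot(per_site, aes(x = factor(.data$pos), y = .data$combined,
                       fill = .data$structure)) +
    geom_col(na.rm = TRUE) +
    labs(x = "driver position", y = "global² + local²",
         fill = "structure") +
    theme_minimal()
}
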