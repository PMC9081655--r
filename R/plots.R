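#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   geom_vline geom_text labs theme_minimal facet_wrap position_dodge
#' @export
ggplot2::autoplot

#' Bar chart of a classified family
#'
#' @param object A `myb_calls` tibble from [classify_proteins()].
#' @param ... Unused.
#' @return A ggplot: member counts per subfamily, MYB-related broken down
#'   by type.
#' @method autoplot myb_calls
#' @export
autoplot.myb_calls <- function(object, ...) {
  s <- summarize_family(object)
  s <- s[s$n > 0, , drop = FALSE]
  s$group <- ifelse(is.na(s$related_type), s$subfamily,
                    paste0(s$subfamily, "/", s$related_type))
  ggplot(s, aes(x = .data$group, y = .data$n, fill = .data$subfamily)) +
    geom_col() +
    labs(x = NULL, y = "members", title = "MYB family composition") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Volcano plot of a DEG screen
#'
#' @param object A `myb_deg` tibble from [deg_screen()].
#' @param lfc_cutoff,p_cutoff Cutoff guides to draw (defaults match the
#'   screen defaults).
#' @param ... Unused.
#' @return A ggplot of -log10 p against log2 fold change, passing genes
#'   highlighted.
#' @method autoplot myb_deg
#' @export
autoplot.myb_deg <- function(object, lfc_cutoff = 1, p_cutoff = 0.05, ...) {
  d <- as_tibble(object)
  d <- d[!is.na(d$pvalue), , drop = FALSE]
  ggplot(d, aes(x = .data$log2fc, y = -log10(.data$pvalue),
                colour = .data$passes)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_vline(xintercept = c(-lfc_cutoff, lfc_cutoff), linetype = 2) +
    geom_hline(yintercept = -log10(p_cutoff), linetype = 2) +
    labs(x = "log2 fold change", y = "-log10 p",
         colour = "passes screen", title = "Differential-expression screen") +
    theme_minimal()
}

#' Fold-change bars for a qPCR screen
#'
#' @param object A `myb_ddct` tibble from [qpcr_screen()].
#' @param ... Unused.
#' @return A ggplot of relative expression (2^-ddCt) per gene, condition
#'   and timepoint, significance stars on top of each bar.
#' @method autoplot myb_ddct
#' @export
autoplot.myb_ddct <- function(object, ...) {
  d <- as_tibble(object)
  d$timepoint <- factor(d$timepoint)
  ggplot(d, aes(x = .data$timepoint, y = .data$fold,
                fill = .data$condition)) +
    geom_col(position = position_dodge(width = 0.9)) +
    geom_text(aes(label = .data$signif),
              position = position_dodge(width = 0.9), vjust = -0.2) +
    geom_hline(yintercept = 1, linetype = 2) +
    facet_wrap(~gene, scales = "free_y") +
    labs(x = "timepoint (h)", y = "relative expression (2^-ddCt)",
         title = "qPCR relative quantification") +
    theme_minimal()
}

#' Repeat and motif map of classified proteins
#'
#' Draws each protein as a horizontal track with its detected repeats and
#' motifs as segments.
#'
#' @param calls A `myb_calls` tibble from [classify_proteins()].
#' @return A ggplot.
#' @export
plot_domain_map <- function(calls) {
  reps <- dplyr::bind_rows(calls$repeats)
  mots <- dplyr::bind_rows(calls$motifs)
  feats <- dplyr::bind_rows(
    if (nrow(reps) > 0)
      tibble(seq_id = reps$seq_id, start = reps$start, end = reps$end,
             feature = reps$repeat_class),
    if (nrow(mots) > 0)
      tibble(seq_id = mots$seq_id, start = mots$start, end = mots$end,
             feature = mots$motif_name)
  )
  if (is.null(feats) || nrow(feats) == 0) {
    abort("no features to plot", class = "cwmyb_input_error")
  }
  ggplot(feats, aes(y = .data$seq_id)) +
    ggplot2::geom_segment(aes(x = .data$start, xend = .data$end,
                              yend = .data$seq_id, colour = .data$feature),
                          linewidth = 3) +
    labs(x = "position (aa)", y = NULL, colour = "feature",
         title = "Repeat and motif map") +
    theme_minimal()
}
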