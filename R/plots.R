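#' Diagnostic rank-frequency (distribution) plot
#'
#' Clone frequency against descending frequency rank on log10 axes, one
#' line per repertoire.
#'
#' @param reps A list of [tcr_repertoire()] objects.
#' @param top_n Number of top clones per repertoire.
#' @return A ggplot object.
#' @export
plot_rank_frequency <- function(reps, top_n = 300L) {
  df <- purrr::map_dfr(reps, function(r) {
    dplyr::mutate(rank_frequency(r, top_n),
                  sample = paste(r$mouse_id, r$compartment, sep = " / "))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$freq,
                                   colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "clone rank", y = "clone frequency") +
    ggplot2::theme_minimal()
}

#' Diagnostic dLN-tumor overlap scatter plot
#'
#' Each overlapping clone at its log10 frequency in the tumor (x) and the
#' dLN (y), with dashed lines at the major/minor threshold.
#'
#' @param tbl An [build_overlap()] table with dLN and tumor columns.
#' @param threshold Major/minor frequency cut (default 0.1%).
#' @param tumor,dln Compartment column names.
#' @return A ggplot object.
#' @export
plot_overlap_scatter <- function(tbl, threshold = 0.001,
                                 tumor = "tumor", dln = "dLN_CD44hi") {
  df <- tibble::tibble(tumor_freq = tbl[[tumor]], dln_freq = tbl[[dln]])
  df <- df[df$tumor_freq > 0 & df$dln_freq > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tumor_freq,
                                   y = .data$dln_freq)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency in tumor", y = "frequency in dLN") +
    ggplot2::theme_minimal()
}
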