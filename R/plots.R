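# ggplot2 views of the main result types.

#' Windowed depth profile of one locus across individuals
#'
#' @param profiles Tibble from [depth_profile()].
#' @param locus Locus id to plot (default: first).
#' @return A ggplot object (step plot of window mean depth per individual).
#' @export
plot_depth_profile <- function(profiles, locus = NULL) {
  locus <- locus %||% profiles$locus_id[1]
  d <- profiles |>
    dplyr::filter(.data$locus_id == locus) |>
    dplyr::select("individual_id", "windows") |>
    tidyr::unnest("windows")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window_start,
                                  y = .data$mean_depth,
                                  colour = .data$individual_id)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position (nt)", y = "mean depth (100-bp windows)",
                  colour = "individual", title = locus) +
    ggplot2::theme_minimal()
}

#' @rdname presence_matrix_pca
#' @param object An `eve_pca` object.
#' @export
autoplot.eve_pca <- function(object, ...) {
  s <- object$scores
  lab <- sprintf("PC%d (%.1f%%)", 1:2, 100 * object$explained_variance[1:2])
  ggplot2::ggplot(s, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' Small-RNA size distribution with the piRNA band shaded
#'
#' @param profile One-row tibble from [srna_size_profile()].
#' @param pirna_band Band to shade.
#' @return A ggplot object.
#' @export
plot_srna_profile <- function(profile, pirna_band = c(24, 29)) {
  counts <- profile$counts[[1]]
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::annotate("rect", xmin = pirna_band[1] - 0.5,
                      xmax = pirna_band[2] + 0.5, ymin = -Inf, ymax = Inf,
                      alpha = 0.15) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "read length (nt)", y = "mapped reads",
                  title = sprintf("%s: piRNA fraction %.2f%s",
                                  profile$target_id, profile$pirna_fraction,
                                  if (profile$pirna_flag) " (flagged)" else "")) +
    ggplot2::theme_minimal()
}

#' Polymorphism-level distributions per group (violin)
#'
#' @param eve_records,feg_records,seg_records Tibbles from
#'   [polymorphism_level()].
#' @return A ggplot object.
#' @export
plot_polymorphism_levels <- function(eve_records, feg_records, seg_records) {
  d <- dplyr::bind_rows(EVE = eve_records, FEG = feg_records,
                        SEG = seg_records, .id = "group")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$level)) +
    ggplot2::geom_violin() +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.4) +
    ggplot2::labs(x = NULL, y = "variants per kb") +
    ggplot2::theme_minimal()
}
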