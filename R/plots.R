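#' Genome-wide VAF scatter for one sample
#'
#' The classic diagnostic: catalog-site VAFs along the genome, coloured by
#' assigned strain-origin state when a track is supplied. Balanced
#' heterozygous territory clusters around 0.5; allelic imbalance shows as
#' heterozygous points pulled toward 0 or 1.
#'
#' @param ad Allele-depth tibble for one sample (or pass `sample`).
#' @param track Optional `state_track` supplying per-site states.
#' @param sample Optional sample id to select.
#' @return A ggplot object.
#' @export
plot_vaf_scatter <- function(ad, track = NULL, sample = NULL) {
  if (!is.null(sample)) ad <- ad[ad$sample == sample, ]
  d <- vaf_matrix(ad) |> dplyr::filter(!.data$missing)
  if (!is.null(track)) {
    d <- dplyr::left_join(d, track$sites[, c("chrom", "pos", "state")],
                          by = c("chrom", "pos"))
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$pos, .data$vaf,
                                         colour = .data$state))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$pos, .data$vaf))
  }
  p +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(HOM_REF = "#c0392b", HET = "#27ae60", HOM_ALT = "#2980b9"),
      na.value = "grey50") +
    ggplot2::labs(x = "position (bp)", y = "variant allele fraction") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a VAF density summary
#'
#' @param density A [vaf_density()] tibble.
#' @return A ggplot object.
#' @export
plot_vaf_density <- function(density) {
  ggplot2::ggplot(density, ggplot2::aes(.data$mid, .data$density)) +
    ggplot2::geom_col(width = density$bin_high[1] - density$bin_low[1],
                      fill = "#27ae60") +
    ggplot2::labs(x = "variant allele fraction", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a denoised copy-ratio track with segments
#'
#' @param track A [denoise()] copy-ratio track.
#' @param segments Optional [segment_copy_ratios()] output to overlay.
#' @return A ggplot object.
#' @export
plot_copy_ratio <- function(track, segments = NULL) {
  p <- ggplot2::ggplot(track, ggplot2::aes(.data$start, .data$copy_ratio)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5, colour = "grey40") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "copy ratio") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$mean_ratio, yend = .data$mean_ratio),
      colour = "#c0392b", linewidth = 1
    )
  }
  p
}

#' @export
#' @rdname plot_vaf_scatter
#' @param object A `state_track`.
#' @param ... Unused.
autoplot.state_track <- function(object, ...) {
  d <- dplyr::filter(object$sites, !is.na(.data$vaf))
  plot_vaf_scatter(
    tibble::tibble(chrom = d$chrom, pos = d$pos, ref = "N", alt = "N",
                   sample = object$sample, alt_count = d$alt_count,
                   total_depth = d$total_depth),
    track = object
  )
}

#' @export
#' @rdname plot_copy_ratio
#' @param object A `copy_ratio_track`.
#' @param ... Unused.
autoplot.copy_ratio_track <- function(object, ...) plot_copy_ratio(object)
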