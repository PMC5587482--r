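#' Heatmap of an interspecific correlation scan
#'
#' Tiles the host x parasite correlation matrix, outlining significant pairs.
#' Intended as a quick diagnostic; for large scans consider filtering
#' [tidy()] output instead.
#'
#' @param object A `coev_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coev_scan <- function(object, ...) {
  d <- tidy(object)
  d$host_locus <- factor(d$host_locus, levels = unique(d$host_locus))
  d$parasite_locus <- factor(d$parasite_locus,
                             levels = unique(d$parasite_locus))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parasite_locus,
                                  y = .data$host_locus,
                                  fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = d[d$significant, , drop = FALSE],
                       fill = NA, colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  na.value = "grey80") +
    ggplot2::labs(x = "parasite locus", y = "host locus",
                  fill = expression(rho),
                  title = sprintf(
                    "Interspecific correlation scan (N = %d, alpha = %g)",
                    object$n_pops, object$alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Detection power by local-adaptation bin
#'
#' Bar chart of [power_table()] output: the fraction of replicates in which
#' every functional host-parasite pair was significant, per bin.
#'
#' @param records A list of `replicate_record`s.
#' @param alpha Significance level at which to summarize.
#' @return A ggplot object.
#' @export
plot_power <- function(records, alpha = 0.01) {
  pt <- power_table(records, alpha)
  ggplot2::ggplot(pt, ggplot2::aes(x = .data$bin, y = .data$power)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("n=%d", .data$n)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = "local adaptation bin", y = "detection power",
                  title = sprintf("Power at alpha = %g", alpha)) +
    ggplot2::theme_minimal()
}

#' Type I error rate versus local adaptation
#'
#' Scatter of per-replicate type I error rates against `L`, with per-bin
#' medians overlaid and the nominal level marked: as local adaptation grows
#' (gene flow shrinks), the median rate converges on `alpha`.
#'
#' @param object A `type1_profile` from [type1_vs_L()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.type1_profile <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$L, y = .data$type1_rate)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_point(data = object$medians,
                        ggplot2::aes(x = .data$median_L,
                                     y = .data$median_type1),
                        colour = "red", size = 3, shape = 18) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "local adaptation (L)", y = "type I error rate",
                  title = sprintf(
                    "Type I error vs local adaptation (alpha = %g)",
                    object$alpha)) +
    ggplot2::theme_minimal()
}
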