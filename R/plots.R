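#' Plot a genome-wide methylome summary
#'
#' @param object A [methylome_summary()] result.
#' @param type `"levels"` (decile histogram of CG call levels),
#'   `"windows"` (strand-signed methylcytosine density track) or
#'   `"contexts"` (context composition).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.methylome_summary <- function(object,
                                       type = c("levels", "windows", "contexts"),
                                       ...) {
  type <- match.arg(type)
  if (type == "levels") {
    ggplot2::ggplot(object$level_histogram,
                    ggplot2::aes(x = .data$bin_low + 0.05, y = .data$fraction)) +
      ggplot2::geom_col(width = 0.095, fill = "steelblue") +
      ggplot2::labs(x = "CG methylation level", y = "fraction of mCGs") +
      ggplot2::theme_minimal()
  } else if (type == "windows") {
    ggplot2::ggplot(object$window_density,
                    ggplot2::aes(x = .data$window_start / 1e3, y = .data$density,
                                 colour = .data$strand)) +
      ggplot2::geom_point(size = 0.4) +
      ggplot2::facet_wrap(~contig, ncol = 1) +
      ggplot2::labs(x = "position (kb)", y = "signed mC density (per bp)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$context_fractions,
                    ggplot2::aes(x = .data$context, y = .data$fraction)) +
      ggplot2::geom_col(fill = "grey30") +
      ggplot2::labs(x = NULL, y = "fraction of methylcytosines") +
      ggplot2::theme_minimal()
  }
}

#' Plot a metagene methylation profile
#'
#' Segments appear 5' to 3' with dotted boundaries, the representation
#' used for gene-region methylation figures.
#'
#' @param object A [metagene_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  bins <- attr(object, "bins_per_segment")
  df <- dplyr::mutate(object,
                      x = (as.integer(.data$segment) - 1L) * bins + .data$bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$se,
                                      ymax = .data$value + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_vline(xintercept = seq_len(6) * bins - 0.5,
                        linetype = "dotted") +
    ggplot2::scale_x_continuous(
      breaks = (seq_len(7) - 0.5) * bins,
      labels = metagene_segment_levels()
    ) +
    ggplot2::labs(x = NULL, y = paste0("methylation (", attr(object, "metric"), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an element/flank methylation profile
#'
#' Absolute (mC/Length) and relative (mC/CG) profiles across element
#' bodies and fixed-width flanks.
#'
#' @param profile An [element_profile()] tibble.
#' @return A ggplot.
#' @export
plot_element_profile <- function(profile) {
  df <- profile %>%
    dplyr::mutate(x = dplyr::row_number()) %>%
    tidyr::pivot_longer(c("absolute_level", "relative_level"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "bin (5' flank | body | 3' flank)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-quintile TSS-anchored methylation profiles
#'
#' @param object An [expression_quintile_analysis()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.quintile_analysis <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$bin, y = .data$mean_degree,
                               colour = factor(.data$quintile))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "distance from TSS (bp)", y = "mean methylation degree",
                  colour = "expression\nquintile") +
    ggplot2::theme_minimal()
}

#' Plot the per-gene divergence p-value distributions
#'
#' Histograms of per-gene methylation and expression p-values between two
#' lines, for judging which axis varies more genome-wide.
#'
#' @param divergence A [per_gene_divergence()] tibble.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_divergence_histogram <- function(divergence, bins = 20) {
  df <- divergence %>%
    tidyr::pivot_longer(c("meth_p", "expr_p"), names_to = "axis",
                        values_to = "p") %>%
    dplyr::filter(!is.na(.data$p)) %>%
    dplyr::mutate(axis = dplyr::recode(.data$axis, meth_p = "methylation",
                                       expr_p = "expression"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, fill = .data$axis)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "p-value", y = "genes") +
    ggplot2::theme_minimal()
}
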