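# ggplot2 views of the main result types.

#' Plot the optimization trace of a progression fit
#'
#' Shows, for each improvement found by the scatter search, the
#' cross-validated RMSE, the fitted intermediate stage positions, and the
#' number of ranked features in the model.
#'
#' @param object A `dp_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dp_result <- function(object, ...) {
  tr <- object$trace |>
    tidyr::pivot_longer(c("rmse", "d_diabetic", "d_npdr", "n"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$evaluation, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "function evaluation", y = NULL,
                  title = sprintf("Progression model convergence (%s)", object$site))
}

#' Plot estimated cell-type proportions by disease group
#'
#' @param object A `deconv_result`.
#' @param metadata Sample metadata (`sample_id`, `group`) for grouping.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deconv_result <- function(object, metadata = NULL, ...) {
  d <- tidy(object)
  if (!is.null(metadata)) {
    d <- dplyr::left_join(d, metadata[, c("sample_id", "group")], by = "sample_id")
    d$group <- factor(d$group, levels = intersect(disease_groups(), unique(d$group)))
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$proportion)) +
      ggplot2::geom_boxplot(outlier.size = 0.5)
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$celltype, y = .data$proportion)) +
      ggplot2::geom_boxplot(outlier.size = 0.5)
  }
  p + ggplot2::facet_wrap(~celltype, scales = "free_y") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "estimated proportion")
}

#' Volcano plot of differential expression results
#'
#' Fold-change-passing transcripts are drawn opaque, the rest transparent.
#'
#' @param de_results Tibble from [fit_de()].
#' @param alpha Significance threshold on q.
#' @return A ggplot.
#' @export
plot_volcano <- function(de_results, alpha = 0.05) {
  d <- dplyr::mutate(de_results,
                     significant = !is.na(.data$q) & .data$q < alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                  colour = .data$significant,
                                  alpha = .data$passes_fc)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.25, `TRUE` = 1)) +
    ggplot2::facet_grid(site ~ contrast) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p")
}
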