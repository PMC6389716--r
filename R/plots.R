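#' @importFrom ggplot2 autoplot
NULL

#' Heatmap of a subject's module-level variability matrix
#'
#' Diagonal cells are intra-network variability, off-diagonal cells
#' inter-network variability.
#'
#' @param object A [variability_set()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variability_set
#' @export
autoplot.variability_set <- function(object, ...) {
  labels <- rownames(object$module_matrix)
  df <- tidyr::expand_grid(a = labels, b = labels)
  df$value <- as.vector(t(object$module_matrix))
  df$a <- factor(df$a, levels = labels)
  df$b <- factor(df$b, levels = rev(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "variability", limits = c(0, 2)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Module-level temporal variability (%s, l = %d)",
                                  object$subject_id, object$window_length)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Cross-length correlation heatmap of a window-length sweep
#'
#' @param object A [window_length_sweep()] result.
#' @param level `"nodal"` or `"module"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, level = c("nodal", "module"),
                                  ...) {
  level <- match.arg(level)
  m <- if (level == "nodal") object$cor_nodal else object$cor_module
  df <- tidyr::expand_grid(l1 = rownames(m), l2 = colnames(m))
  df$r <- as.vector(t(m))
  df$l1 <- factor(df$l1, levels = rownames(m))
  df$l2 <- factor(df$l2, levels = rownames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$l1, y = .data$l2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$r)),
                       size = 2.5) +
    ggplot2::scale_fill_viridis_c(name = "r") +
    ggplot2::labs(x = "window length (volumes)",
                  y = "window length (volumes)",
                  title = sprintf("Cross-length correlation of %s variability",
                                  level)) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of a unit-level group comparison
#'
#' Plots the observed patient-minus-control difference against
#' -log10(two-sided permutation p) for every unit, faceted by level.
#'
#' @param comparison A [group_compare()] tibble (optionally with the
#'   significance flags added by [run_pipeline()]).
#' @param alpha Reference significance level drawn as a horizontal line
#'   (default 0.05).
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(comparison, alpha = 0.05) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$observed_diff,
                               y = -log10(.data$p_two_sided))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$level), scales = "free") +
    ggplot2::labs(x = "patient - control mean variability",
                  y = expression(-log[10](p)),
                  title = "Permutation group comparison") +
    ggplot2::theme_minimal()
}
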