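#' Plot a fitted trait model
#'
#' Boxplot of the raw trait values by genotype with the dual-alpha
#' compact-letter annotation above each group (upper-case letters when the
#' genotypes separate at `alpha_high`, else lower-case at `alpha`).
#'
#' @param object A `trait_fit` from [fit_trait_model()].
#' @param method,alpha,alpha_high Passed to
#'   [summarize_trait_by_genotype()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trait_fit
#' @export
autoplot.trait_fit <- function(object, method = "lsd", alpha = 0.05,
                               alpha_high = 0.01, ...) {
  summ <- summarize_trait_by_genotype(object, method = method,
                                      alpha = alpha,
                                      alpha_high = alpha_high)
  sep_high <- length(unique(summ$letters_001)) > 1
  summ$label <- if (sep_high) summ$letters_001 else summ$letters_005
  dat <- object$data
  dat$genotype <- factor(as.character(dat$genotype),
                         levels = object$genotype_levels)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$genotype, y = .data$y)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::geom_text(
      data = summ,
      ggplot2::aes(x = .data$genotype, label = .data$label,
                   y = max(dat$y) + 0.05 * diff(range(dat$y))),
      inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "Genotype", y = object$trait,
                  subtitle = sprintf("genotype F = %.2f, p = %.3g",
                                     object$genotype_F,
                                     object$genotype_p)) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot relative expression by group
#'
#' Bar chart of mean fold change (2^-ddCt) per group with standard-error
#' bars, optionally annotated with significance marks from
#' [compare_expression()] against a reference group.
#'
#' @param rel Output of [relative_expression()].
#' @param reference Optional group label; each other group is tested
#'   against it and its mark (`*`, `**`, `ns`) drawn above the bar.
#' @param ... Passed to [compare_expression()] (e.g. `scale`,
#'   `var_equal`).
#' @return A ggplot object.
#' @export
plot_relative_expression <- function(rel, reference = NULL, ...) {
  summ <- rel |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean_fold = mean(.data$fold_change),
      se = stats::sd(.data$fold_change) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  p <- ggplot2::ggplot(summ,
                       ggplot2::aes(x = .data$group, y = .data$mean_fold)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_fold - .data$se,
                   ymax = .data$mean_fold + .data$se),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "Relative expression (2^-ddCt)") +
    ggplot2::theme_classic()
  if (!is.null(reference)) {
    others <- setdiff(unique(rel$group), reference)
    cmp <- compare_expression(
      rel, pairs = data.frame(a = rep(reference, length(others)),
                              b = others), ...
    )
    marks <- summ |>
      dplyr::inner_join(cmp, by = c(group = "group_b")) |>
      dplyr::filter(.data$mark != "ns")
    if (nrow(marks)) {
      p <- p + ggplot2::geom_text(
        data = marks,
        ggplot2::aes(x = .data$group, label = .data$mark,
                     y = .data$mean_fold + .data$se +
                       0.05 * max(summ$mean_fold)),
        inherit.aes = FALSE, size = 5
      )
    }
  }
  p
}
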