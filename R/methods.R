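#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a moderated differential-methylation result
#'
#' @param x a `meth_diff` tibble.
#' @param ... unused.
#' @return tibble with one row per feature.
#' @export
tidy.meth_diff <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.meth_diff
#' @export
glance.meth_diff <- function(x, ...) {
  tibble::tibble(n_features = nrow(x),
                 d0 = attr(x, "d0"),
                 s0_2 = attr(x, "s0_2"),
                 n_significant = if (!is.null(x$significant))
                   sum(x$significant) else NA_integer_,
                 threshold = attr(x, "threshold") %||% NA_real_)
}

#' @rdname tidy.meth_diff
#' @export
tidy.meth_gsea <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.meth_diff
#' @export
glance.meth_gsea <- function(x, ...) {
  tibble::tibble(n_sets = nrow(x),
                 n_activated = sum(x$direction == "activated"),
                 n_suppressed = sum(x$direction == "suppressed"),
                 min_p = min(x$p_geneperm))
}

#' Dot plot of top enriched gene sets
#'
#' Mirrors the usual enrichment dot plot: top sets per direction, dot size
#' the number of member genes, colour the permutation p-value.
#'
#' @param object a `meth_gsea` result.
#' @param top_k sets per direction.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.meth_gsea <- function(object, top_k = 5, ...) {
  df <- tibble::as_tibble(unclass(object)) |>
    dplyr::group_by(.data$direction) |>
    dplyr::slice_min(.data$p_geneperm, n = top_k, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes,
                                   y = stats::reorder(.data$set_id,
                                                      .data$nes))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$size,
                                     colour = .data$p_geneperm)) +
    ggplot2::facet_wrap(~ .data$direction, scales = "free_y") +
    ggplot2::labs(x = "normalized enrichment score", y = NULL,
                  size = "Count", colour = "p") +
    ggplot2::theme_bw()
}

#' Volcano plot of differential methylation results
#'
#' @param results a `meth_diff` tibble (after [call_significant()] if a
#'   threshold line is wanted).
#' @return a ggplot.
#' @export
plot_volcano <- function(results) {
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = .data$effect,
                                    y = -log10(.data$p))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::labs(x = "effect size (beta-scale difference)",
                  y = "-log10 p") +
    ggplot2::theme_bw()
  thr <- attr(results, "threshold")
  if (!is.null(thr))
    p <- p + ggplot2::geom_hline(yintercept = -log10(thr),
                                 colour = "red", linetype = 2)
  p
}

#' Scatter plot of effect attenuation between two stratum comparisons
#'
#' @param effects_early,effects_late matched per-feature effect vectors.
#' @param slope optional [attenuation_slope()] output to annotate.
#' @return a ggplot.
#' @export
plot_attenuation <- function(effects_early, effects_late, slope = NULL) {
  df <- tibble::tibble(early = effects_early, late = effects_late)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$early, .data$late)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "effect size, early comparison",
                  y = "effect size, late comparison") +
    ggplot2::theme_bw()
  if (!is.null(slope))
    p <- p + ggplot2::geom_abline(slope = slope$slope, intercept = 0,
                                  colour = "red") +
      ggplot2::annotate("text", x = Inf, y = -Inf, hjust = 1.1, vjust = -1,
                        label = sprintf("slope = %.2f (SE %.3f)",
                                        slope$slope, slope$stderr))
  p
}

#' @importFrom rlang .data %||%
NULL
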