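#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Box plot of credible-set sizes by design
#'
#' Distribution of the number of variants in constructed 95% credible sets
#' (restricted to sets containing the causal variant), per design and
#' optionally faceted by region.
#'
#' @param results a data frame combining [run_scenario()] outputs with a
#'   `design` column (and optionally `region`).
#' @param by_region facet by region if a `region` column is present.
#' @return a ggplot object.
#' @export
plot_set_sizes <- function(results, by_region = "region" %in% names(results)) {
  d <- dplyr::filter(results, .data$constructed %in% TRUE,
                     .data$contains_causal %in% TRUE)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$design, y = .data$set_size)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "meta-analysis design",
                  y = "variants in 95% credible set") +
    ggplot2::theme_minimal()
  if (by_region) p <- p + ggplot2::facet_wrap(~region)
  p
}

#' Coverage of constructed credible sets with binomial error bars
#'
#' @param coverage output of [coverage_probability()], optionally with a
#'   `design` column when several designs are compared.
#' @return a ggplot object.
#' @export
plot_coverage <- function(coverage) {
  d <- dplyr::filter(coverage, !is.na(.data$coverage))
  x <- if ("design" %in% names(d)) "design" else "region"
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[x]], y = .data$coverage)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$coverage - 1.96 * .data$se,
                                        ymax = .data$coverage + 1.96 * .data$se),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "P(causal variant in 95% credible set)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fm_scenario <- function(object, ...) {
  spec <- attr(object, "spec")
  d <- dplyr::mutate(tibble::as_tibble(object), design = spec$design)
  plot_set_sizes(d, by_region = FALSE) +
    ggplot2::ggtitle(paste0(spec$design, ", ", spec$heterogeneity,
                            ", MAF ", spec$maf_class))
}

#' @export
autoplot.fm_credible_set <- function(object, ...) {
  d <- object$region_posteriors
  d$in_set <- d$variant %in% object$members
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variant, y = .data$posterior,
                                  colour = .data$in_set)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60"),
                                 name = "in credible set") +
    ggplot2::labs(x = "variant index", y = "posterior probability") +
    ggplot2::theme_minimal()
}
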