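#' Coverage probability of constructed credible sets
#'
#' The proportion of constructed 95% credible sets that contain the causal
#' variant, per region, with binomial standard errors; the summary row is the
#' unweighted mean over regions. The denominator is the number of replicates
#' in which a set was constructed (the gate passed), so regions where few
#' replicates pass carry larger standard errors.
#'
#' @param results a data frame with columns `region`, `constructed`,
#'   `contains_causal` -- e.g. several [run_scenario()] outputs bound together
#'   with a `region` column.
#' @return a tibble with one row per region plus a `"summary"` row: `region`,
#'   `n_constructed`, `coverage`, `se`. The summary `se` is the mean of the
#'   region SEs; `se_empirical` (summary row only) is the SD of region
#'   coverages divided by sqrt(#regions). Regions with zero constructed sets
#'   get `NA` coverage and are excluded from the summary.
#' @export
coverage_probability <- function(results) {
  stopifnot(all(c("region", "constructed", "contains_causal") %in% names(results)))
  per <- results |>
    dplyr::filter(.data$constructed %in% TRUE) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_constructed = dplyr::n(),
                     coverage = mean(.data$contains_causal),
                     se = sqrt(.data$coverage * (1 - .data$coverage) /
                                 .data$n_constructed),
                     .groups = "drop") |>
    dplyr::mutate(region = as.character(.data$region), se_empirical = NA_real_)
  all_regions <- unique(as.character(results$region))
  missing <- setdiff(all_regions, per$region)
  if (length(missing) > 0) {
    per <- dplyr::bind_rows(per, tibble::tibble(region = missing,
                                                n_constructed = 0L,
                                                coverage = NA_real_,
                                                se = NA_real_,
                                                se_empirical = NA_real_))
  }
  if (nrow(per) == 0 || all(is.na(per$coverage))) {
    stop("no constructed credible sets in any region", call. = FALSE)
  }
  ok <- !is.na(per$coverage)
  summary_row <- tibble::tibble(
    region = "summary",
    n_constructed = sum(per$n_constructed[ok]),
    coverage = mean(per$coverage[ok]),
    se = mean(per$se[ok]),
    se_empirical = stats::sd(per$coverage[ok]) / sqrt(sum(ok)))
  dplyr::bind_rows(per[order(per$region), ], summary_row)
}

#' Median size of credible sets that contain the causal variant
#'
#' Restricted to constructed sets containing the causal variant (fine-mapping
#' resolution is only meaningful when the set localises the right signal);
#' even counts give the mean of the two middle sizes.
#'
#' @param results a data frame with columns `constructed`, `contains_causal`,
#'   `set_size` (one region's replicates, e.g. a [run_scenario()] output).
#' @return the median set size, or `NA` if no eligible set exists.
#' @export
median_set_size <- function(results) {
  eligible <- results$constructed %in% TRUE & results$contains_causal %in% TRUE
  if (!any(eligible)) return(NA_real_)
  stats::median(results$set_size[eligible])
}

#' Summary of per-region medians
#'
#' The unweighted arithmetic mean of region-specific values (e.g. median
#' credible-set sizes), the scalar used to compare designs across regions.
#'
#' @param medians numeric vector of per-region values.
#' @return their mean.
#' @export
summary_over_regions <- function(medians) {
  stopifnot(length(medians) >= 1)
  mean(medians)
}

#' Power to detect a variant
#'
#' Proportion of replicates whose meta-analysis P-value at the target variant
#' is strictly below `alpha`.
#'
#' @param results a data frame with a per-replicate P-value column.
#' @param alpha significance level in (0, 1) (default 0.05).
#' @param p_col name of the P-value column (default `"p_c1"`).
#' @return a proportion.
#' @export
power_at_variant <- function(results, alpha = 0.05, p_col = "p_c1") {
  stopifnot(alpha > 0, alpha < 1)
  p <- results[[p_col]]
  mean(p < alpha)
}
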