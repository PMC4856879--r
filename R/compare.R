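#' Kruskal-Wallis comparison of set-size distributions
#'
#' Wraps [stats::kruskal.test()] (tie-corrected H statistic, chi-square
#' reference with groups - 1 degrees of freedom) and returns a tidy one-row
#' tibble. Used to test whether credible-set sizes differ across ancestry
#' designs within a region.
#'
#' @param data a data frame with a value column and a group column, or a named
#'   list of numeric vectors.
#' @param value,group column names when `data` is a data frame.
#' @return a tibble: `statistic` (H), `df`, `p_value`, `n_groups`.
#' @export
#' @examples
#' kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))
kruskal_wallis <- function(data, value = "value", group = "group") {
  g <- as_grouped_values(data, value, group)
  if (length(g) < 2 || any(lengths(g) == 0)) {
    stop("need >= 2 nonempty groups", call. = FALSE)
  }
  x <- unlist(g, use.names = FALSE)
  if (length(unique(x)) == 1) {
    return(tibble::tibble(statistic = 0, df = length(g) - 1, p_value = 1,
                          n_groups = length(g)))
  }
  kt <- stats::kruskal.test(g)
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, n_groups = length(g))
}

as_grouped_values <- function(data, value, group) {
  if (is.data.frame(data)) {
    split(data[[value]], data[[group]])
  } else if (is.list(data)) {
    data
  } else {
    stop("data must be a data frame or a list of numeric vectors", call. = FALSE)
  }
}

#' Dunn's post-hoc pairwise rank test
#'
#' For each pair of groups, the Dunn z statistic compares mean ranks from the
#' joint (tie-corrected) ranking used by the Kruskal-Wallis test:
#' z = (Rbar_A - Rbar_B) / sqrt( (N(N+1)/12 - T) (1/n_A + 1/n_B) ), with tie
#' correction T = sum(t^3 - t) / (12 (N - 1)) over tied-value groups. P-values
#' are two-sided and unadjusted; apply a multiplicity correction in the caller
#' if required.
#'
#' @inheritParams kruskal_wallis
#' @return a tibble with one row per unordered pair: `group1`, `group2`, `z`,
#'   `p_value`.
#' @export
#' @examples
#' dunns_test(list(a = 1:3, b = 7:9))
dunns_test <- function(data, value = "value", group = "group") {
  g <- as_grouped_values(data, value, group)
  if (length(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(g) == 0)) stop("empty group", call. = FALSE)
  x <- unlist(g, use.names = FALSE)
  lab <- rep(names(g), lengths(g))
  r <- rank(x)
  n_tot <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  mean_rank <- tapply(r, lab, mean)
  n_g <- lengths(g)
  pairs <- utils::combn(names(g), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z <- if (se == 0) 0 else unname((mean_rank[[a]] - mean_rank[[b]]) / se)
    tibble::tibble(group1 = a, group2 = b, z = z,
                   p_value = if (se == 0) 1 else 2 * stats::pnorm(-abs(z)))
  })
}

#' Paired one-sided t-test of per-region medians
#'
#' Tests whether a lower-diversity design has larger per-region median
#' credible-set sizes than a higher-diversity design: one-sided paired t-test
#' of mean(lower - higher) > 0 on the region-matched values, df = n - 1.
#' The multiplicity-corrected threshold alpha = 0.011 conventionally applied to
#' the family of three design comparisons is reported alongside.
#'
#' @param lower_design,higher_design equal-length numeric vectors of per-region
#'   medians, paired by region.
#' @return a tibble: `t`, `df`, `p_value` (one-sided), `mean_difference`,
#'   `bonferroni_alpha`.
#' @export
#' @examples
#' paired_t_by_region(c(4, 6, 8), c(1, 2, 3))
paired_t_by_region <- function(lower_design, higher_design) {
  stopifnot(length(lower_design) == length(higher_design),
            length(lower_design) >= 2)
  d <- lower_design - higher_design
  if (stats::sd(d) == 0) {
    stop("degenerate pairing: all paired differences are equal", call. = FALSE)
  }
  tt <- stats::t.test(lower_design, higher_design, paired = TRUE,
                      alternative = "greater")
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_difference = mean(d),
                 bonferroni_alpha = 0.011)
}
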