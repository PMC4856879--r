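#' Inverse-variance fixed-effects meta-analysis
#'
#' Combines per-cohort association tables per variant with weights w_i = 1/V_i:
#' pooled beta = sum(w b)/sum(w), pooled variance = 1/sum(w), two-sided normal
#' P-value, and Cochran's Q = sum(w (b - pooled)^2). Variants absent from a
#' cohort are pooled over the cohorts that observed them (`k` records how
#' many). P-values are computed on the log scale to avoid premature underflow.
#'
#' @param stats a list of per-cohort tibbles as returned by
#'   [single_snp_association()] (columns `variant`, `beta_hat`, `var`;
#'   effect alleles are assumed aligned -- flip the sign of `beta_hat` before
#'   calling if a cohort's alleles are swapped).
#' @return a tibble of class `fm_meta`, one row per variant observed in at
#'   least one cohort: `variant`, `pooled_beta`, `pooled_var`, `se`,
#'   `p_value`, `q_stat`, `tau2` (0 for fixed effects), `k`, and `log_p`
#'   (natural-log P, exact even when `p_value` underflows).
#' @export
#' @examples
#' s1 <- tibble::tibble(variant = 1, beta_hat = 0.2, var = 0.01)
#' s2 <- tibble::tibble(variant = 1, beta_hat = 0.4, var = 0.04)
#' fixed_effects_meta(list(s1, s2))
fixed_effects_meta <- function(stats) {
  meta_ivw(stats, random = FALSE)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' As [fixed_effects_meta()], but with the between-cohort variance tau^2
#' estimated by the moment estimator
#' tau^2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w))) from the
#' fixed-effects weights, then re-pooling with weights 1/(V_i + tau^2).
#' Variants observed in a single cohort get tau^2 = 0.
#'
#' @inheritParams fixed_effects_meta
#' @return a tibble of class `fm_meta`; see [fixed_effects_meta()].
#' @export
random_effects_meta <- function(stats) {
  meta_ivw(stats, random = TRUE)
}

meta_ivw <- function(stats, random) {
  stopifnot(is.list(stats), length(stats) >= 1)
  stats <- lapply(stats, function(s) {
    s <- tibble::as_tibble(s)
    if (!all(c("variant", "beta_hat", "var") %in% names(s))) {
      stop("each cohort table needs columns variant, beta_hat, var", call. = FALSE)
    }
    if (any(s$var <= 0 | !is.finite(s$var))) {
      stop("non-positive or non-finite variance in a cohort table", call. = FALSE)
    }
    s
  })
  variants <- sort(unique(unlist(lapply(stats, `[[`, "variant"))))
  m <- length(variants)
  kc <- length(stats)
  b <- matrix(NA_real_, kc, m)
  v <- matrix(NA_real_, kc, m)
  for (i in seq_len(kc)) {
    j <- match(stats[[i]]$variant, variants)
    b[i, j] <- stats[[i]]$beta_hat
    v[i, j] <- stats[[i]]$var
  }
  w <- 1 / v
  w[is.na(w)] <- 0
  bw <- b
  bw[is.na(bw)] <- 0
  sw <- colSums(w)
  k <- colSums(w > 0)
  pooled <- colSums(w * bw) / sw
  q <- colSums(w * (bw - rep(pooled, each = kc))^2 * (w > 0))
  tau2 <- rep(0, m)
  if (random) {
    sw2 <- colSums(w^2)
    denom <- sw - sw2 / sw
    tau2 <- ifelse(k >= 2 & denom > 0, pmax(0, (q - (k - 1)) / denom), 0)
    wr <- 1 / sweep(v, 2, tau2, "+")
    wr[is.na(wr)] <- 0
    swr <- colSums(wr)
    pooled <- colSums(wr * bw) / swr
    pooled_var <- 1 / swr
  } else {
    pooled_var <- 1 / sw
  }
  z <- pooled / sqrt(pooled_var)
  log_p <- log(2) + stats::pnorm(-abs(z), log.p = TRUE)
  out <- tibble::tibble(variant = variants,
                        pooled_beta = pooled,
                        pooled_var = pooled_var,
                        se = sqrt(pooled_var),
                        p_value = exp(log_p),
                        q_stat = q,
                        tau2 = tau2,
                        k = as.integer(k),
                        log_p = log_p)
  class(out) <- c("fm_meta", class(out))
  attr(out, "model") <- if (random) "random" else "fixed"
  out
}

#' @export
tidy.fm_meta <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fm_meta")
  out
}

#' One-line summary of a meta-analysis table
#'
#' @param x an `fm_meta` tibble.
#' @param ... unused.
#' @return a one-row tibble: `model`, `n_variants`, `n_cohorts` (max `k`),
#'   `lead_variant`, `lead_p`, `median_tau2`.
#' @export
glance.fm_meta <- function(x, ...) {
  lead <- which.min(x$log_p)
  tibble::tibble(model = attr(x, "model") %||% NA_character_,
                 n_variants = nrow(x),
                 n_cohorts = max(x$k),
                 lead_variant = x$variant[lead],
                 lead_p = x$p_value[lead],
                 median_tau2 = stats::median(x$tau2))
}
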