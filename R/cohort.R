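#' Sample a case/control cohort from a population panel
#'
#' Individuals are formed by drawing two haplotypes uniformly with replacement
#' from the population panel (whole haplotypes, so within-region LD is
#' preserved exactly). Disease risk follows the multiplicative per-allele model
#' P(D | g) = K * rr^g at the cohort's assigned causal variant, where g is the
#' causal genotype and the baseline K is set so the population prevalence
#' equals `prevalence` under Hardy-Weinberg at the population's causal allele
#' frequency. Cases and controls are accumulated by rejection sampling until
#' the exact target counts are reached. Cohorts assigned `"null"` use
#' P(D) = K = `prevalence` for everyone.
#'
#' @param panel an `fm_panel`.
#' @param pop a population label, or several labels whose haplotypes are pooled
#'   (e.g. `c("EU1", "EU2")` for a combined-panel cohort).
#' @param config an [causal_config()] object; the effect used is
#'   `config$cohort_effects[[cohort]]`.
#' @param cohort cohort label keying into the config's effect map.
#' @param n_case,n_ctrl target counts (defaults 1000/1000).
#' @param prevalence population disease prevalence (default 0.01).
#' @param seed integer seed; cohorts are reproducible in isolation.
#' @param variants optional variant indices to materialise genotypes for
#'   (default all). The haplotype draws are identical whatever subset is
#'   requested.
#' @return an object of class `fm_cohort`: list with `genotypes`
#'   (n x length(variants) dosage matrix), `status` (1 = case), `variants`,
#'   `pop`, `effect_variant`, `n_case`, `n_ctrl`, `seed`.
#' @export
sample_cohort <- function(panel, pop, config, cohort,
                          n_case = 1000, n_ctrl = 1000,
                          prevalence = 0.01, seed = 1L, variants = NULL) {
  if (!cohort %in% names(config$cohort_effects)) {
    stop("no effect assignment for cohort '", cohort, "' in config", call. = FALSE)
  }
  effect <- config$cohort_effects[[cohort]]
  rr <- config$rr
  if (rr <= 0) stop("relative risk must be positive", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  }

  h <- pooled_haplotypes(panel, pop)
  n_hap <- nrow(h)
  m <- ncol(h)
  if (is.null(variants)) variants <- seq_len(m)

  causal <- switch(effect, c1 = config$c1, c2 = config$c2, null = NA_integer_)
  if (effect != "null") {
    p <- mean(h[, causal])
    # baseline so that E[K * rr^g] = prevalence under HWE
    k <- prevalence / ((1 - p)^2 + 2 * p * (1 - p) * rr + p^2 * rr^2)
    if (k * rr^2 > 1) {
      stop("prevalence and relative risk imply P(disease | g = 2) > 1",
           call. = FALSE)
    }
  } else {
    k <- prevalence
  }

  with_seed(seed, {
    idx_case <- matrix(integer(0), 0, 2)
    idx_ctrl <- matrix(integer(0), 0, 2)
    need_case <- n_case; need_ctrl <- n_ctrl
    guard <- 0
    while (need_case > 0 || need_ctrl > 0) {
      guard <- guard + 1
      if (guard > 10000) stop("rejection sampling failed to converge", call. = FALSE)
      batch <- max(2000L, ceiling(1.3 * max(need_case / prevalence,
                                            need_ctrl / (1 - prevalence))))
      i1 <- sample.int(n_hap, batch, replace = TRUE)
      i2 <- sample.int(n_hap, batch, replace = TRUE)
      pr <- if (effect == "null") rep(k, batch) else {
        g <- h[i1, causal] + h[i2, causal]
        k * rr^g
      }
      dis <- stats::runif(batch) < pr
      if (need_case > 0) {
        take <- which(dis)[seq_len(min(need_case, sum(dis)))]
        idx_case <- rbind(idx_case, cbind(i1[take], i2[take]))
        need_case <- n_case - nrow(idx_case)
      }
      if (need_ctrl > 0) {
        take <- which(!dis)[seq_len(min(need_ctrl, sum(!dis)))]
        idx_ctrl <- rbind(idx_ctrl, cbind(i1[take], i2[take]))
        need_ctrl <- n_ctrl - nrow(idx_ctrl)
      }
    }
    idx <- rbind(idx_case, idx_ctrl)
    hv <- if (length(variants) == m) h else h[, variants, drop = FALSE]
    genotypes <- hv[idx[, 1], , drop = FALSE] + hv[idx[, 2], , drop = FALSE]
    structure(list(genotypes = genotypes,
                   status = rep(c(1L, 0L), c(n_case, n_ctrl)),
                   variants = as.integer(variants),
                   pop = paste(pop, collapse = "+"),
                   effect_variant = effect,
                   n_case = as.integer(n_case), n_ctrl = as.integer(n_ctrl),
                   seed = as.integer(seed)),
              class = "fm_cohort")
  })
}

#' @export
print.fm_cohort <- function(x, ...) {
  cat("<fm_cohort> pop", x$pop, "|", x$n_case, "cases /", x$n_ctrl,
      "controls |", ncol(x$genotypes), "variants | effect", x$effect_variant, "\n")
  invisible(x)
}
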