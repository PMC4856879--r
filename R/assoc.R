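#' Per-variant additive logistic association
#'
#' Fits, for every variant of a cohort, the additive logistic model
#' logit P(case) = a + b * g of status on genotype dosage by maximum
#' likelihood, and reports the Wald statistic for the dosage coefficient.
#' Because dosage takes only the values 0/1/2, the 2 x 3 genotype-by-status
#' count table is sufficient, and the Newton-Raphson fit is vectorised across
#' variants; the estimates agree with `glm(family = binomial)` on the expanded
#' data to full convergence precision.
#'
#' Monomorphic variants are omitted from the output. Variants with a separated
#' or non-converged fit (e.g. an allele seen only in cases) are omitted with a
#' warning.
#'
#' @param cohort an `fm_cohort` from [sample_cohort()].
#' @return a tibble with one row per polymorphic, converged variant:
#'   `variant`, `beta_hat`, `var` (sampling variance of `beta_hat`), `se`,
#'   `p_value` (two-sided Wald), `eaf` (allele-1 frequency in the cohort),
#'   `n`.
#' @export
single_snp_association <- function(cohort) {
  status <- cohort$status
  if (sum(status == 1) < 2 || sum(status == 0) < 2) {
    stop("need at least 2 cases and 2 controls", call. = FALSE)
  }
  g <- cohort$genotypes
  n <- length(status)
  case <- status == 1
  # dosage is 0/1/2, so counts follow from column sums of g and g^2:
  # s1 = n1 + 2 n2, s2 = n1 + 4 n2
  g2 <- g * g
  s1 <- colSums(g); s2 <- colSums(g2)
  n2 <- (s2 - s1) / 2
  n1 <- s1 - 2 * n2
  t1 <- colSums(g[case, , drop = FALSE]); t2 <- colSums(g2[case, , drop = FALSE])
  y2 <- (t2 - t1) / 2
  y1 <- t1 - 2 * y2
  fit <- logistic_counts_fit(n_case = sum(case), n_total = n,
                             y1 = y1, y2 = y2, n1 = n1, n2 = n2)
  eaf <- (n1 + 2 * n2) / (2 * n)
  out <- tibble::tibble(variant = cohort$variants,
                        beta_hat = fit$beta, var = fit$var,
                        se = sqrt(fit$var), p_value = fit$p,
                        eaf = eaf, n = n)
  mono <- !fit$polymorphic
  bad <- fit$polymorphic & !fit$converged
  if (any(bad)) {
    warning(sum(bad), " variant(s) dropped: separated or non-converged ",
            "logistic fit", call. = FALSE)
  }
  out[fit$polymorphic & fit$converged, , drop = FALSE]
}

# Newton-Raphson logistic fit of status on dosage from 2x3 count tables,
# vectorised across variants. Returns beta, its variance, two-sided Wald p.
logistic_counts_fit <- function(n_case, n_total, y1, y2, n1, n2,
                                max_iter = 40, tol = 1e-12) {
  m <- length(y1)
  n0 <- n_total - n1 - n2
  y0 <- n_case - y1 - y2
  ng <- rbind(n0, n1, n2)           # 3 x m totals per dosage
  yg <- rbind(y0, y1, y2)           # 3 x m cases per dosage
  gval <- c(0, 1, 2)

  # polymorphic: at least two dosage groups non-empty
  polymorphic <- ((n0 > 0) + (n1 > 0) + (n2 > 0)) >= 2

  a <- rep(stats::qlogis(n_case / n_total), m)
  b <- rep(0, m)
  active <- polymorphic
  converged <- rep(FALSE, m)

  for (it in seq_len(max_iter)) {
    act <- which(active)
    if (length(act) == 0) break
    eta <- rbind(a[act], a[act] + b[act], a[act] + 2 * b[act])
    mu <- stats::plogis(eta)
    nga <- ng[, act, drop = FALSE]
    w <- mu * (1 - mu) * nga
    res <- yg[, act, drop = FALSE] - mu * nga
    ua <- colSums(res)
    ub <- colSums(res * gval)
    iaa <- colSums(w)
    iab <- colSums(w * gval)
    ibb <- colSums(w * gval^2)
    det <- iaa * ibb - iab^2
    ok <- det > 1e-12
    da <- (ibb * ua - iab * ub) / det
    db <- (iaa * ub - iab * ua) / det
    # damped step to keep separated fits from exploding too fast
    stepmax <- pmax(abs(da), abs(db))
    big <- is.finite(stepmax) & stepmax > 5
    scale <- ifelse(big, 5 / stepmax, 1)
    da <- da * scale
    db <- db * scale
    upd <- act[ok]
    a[upd] <- a[upd] + da[ok]
    b[upd] <- b[upd] + db[ok]
    done <- ok & abs(ua) < tol * pmax(1, iaa) & abs(ub) < tol * pmax(1, ibb)
    converged[act[done]] <- TRUE
    active[act] <- !done & ok
    active <- active & abs(b) < 15
  }

  eta0 <- a; eta1 <- a + b; eta2 <- a + 2 * b
  mu <- rbind(stats::plogis(eta0), stats::plogis(eta1), stats::plogis(eta2))
  w <- mu * (1 - mu) * ng
  iaa <- colSums(w); iab <- colSums(w * gval); ibb <- colSums(w * gval^2)
  det <- iaa * ibb - iab^2
  vb <- iaa / det
  ok <- converged & is.finite(vb) & vb > 0 & abs(b) < 15
  z <- b / sqrt(vb)
  p <- 2 * stats::pnorm(-abs(z))
  p[p == 0] <- .Machine$double.xmin
  list(beta = b, var = vb, p = p,
       polymorphic = polymorphic, converged = ok)
}
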