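#' Wakefield approximate Bayes factor
#'
#' Converts an effect estimate and its variance into the single-SNP
#' approximate Bayes factor for the alternative hypothesis that the allelic
#' log-odds effect is drawn from Normal(0, W) against the null of no effect:
#'
#'   ABF = sqrt(V / (V + W)) * exp( z^2 W / (2 (V + W)) ),  z = beta / sqrt(V).
#'
#' Evidence against the null increases with the ABF. For a case-control study
#' under an additive model the conventional prior variance is W = 0.04
#' (a 95% prior interval of roughly +/- 0.4 on the log-odds scale). The
#' computation is done in log space; use `log = TRUE` to retrieve log-ABF
#' without overflow for very large z.
#'
#' @param beta_hat effect estimate (log-odds scale); vectorised.
#' @param v sampling variance of `beta_hat` (> 0); vectorised.
#' @param w prior effect variance (default 0.04).
#' @param log if `TRUE`, return the natural log of the ABF.
#' @return numeric vector of (log) approximate Bayes factors.
#' @export
#' @examples
#' approx_bayes_factor(0, 0.04)        # sqrt(0.5)
#' approx_bayes_factor(0.3, 0.01)      # ~ 16.37
approx_bayes_factor <- function(beta_hat, v, w = 0.04, log = FALSE) {
  if (any(v <= 0 | !is.finite(v))) stop("v must be positive", call. = FALSE)
  if (length(w) != 1 || w < 0) stop("w must be a single value >= 0", call. = FALSE)
  z2 <- beta_hat^2 / v
  log_abf <- 0.5 * base::log(v / (v + w)) + z2 * w / (2 * (v + w))
  if (log) log_abf else exp(log_abf)
}

#' Posterior probabilities from per-variant Bayes factors
#'
#' Normalises per-variant (log) ABFs to posterior probabilities that each
#' variant is the causal one, assuming one causal variant in the region and a
#' uniform prior over variants: each probability is the variant's ABF divided
#' by the sum of ABFs over the region. Computed by log-sum-exp.
#'
#' @param abfs per-variant ABFs, or log-ABFs when `log = TRUE`.
#' @param log whether `abfs` are on the log scale.
#' @return numeric vector of probabilities summing to 1.
#' @export
#' @examples
#' posterior_probabilities(c(10, 5, 2, 1, 1, 1))
posterior_probabilities <- function(abfs, log = FALSE) {
  la <- if (log) abfs else base::log(abfs)
  if (length(la) == 0 || !any(is.finite(la))) {
    stop("need at least one finite ABF", call. = FALSE)
  }
  mx <- max(la[is.finite(la)])
  e <- exp(la - mx)
  e[!is.finite(la)] <- 0
  e / sum(e)
}

#' Build a gated 95% credible set from a meta-analysis table
#'
#' Converts every variant's pooled effect and variance to a Wakefield ABF,
#' normalises to posterior probabilities over the region, and -- provided the
#' lead variant's P-value passes the gate (strictly below `gate_threshold`,
#' default 5e-8) -- ranks variants by decreasing posterior (ties broken by
#' genomic position, ascending, via the variant index) and accumulates them
#' until the cumulative posterior mass first strictly exceeds `level`. When
#' the gate fails, no set is constructed (`constructed = FALSE`, no members).
#'
#' @param meta an `fm_meta` tibble (needs `variant`, `pooled_beta`,
#'   `pooled_var`, `p_value`, `log_p`).
#' @param w prior effect variance for the ABF (default 0.04).
#' @param level target credible mass in (0, 1) (default 0.95).
#' @param gate_threshold lead-SNP P-value gate (default 5e-8).
#' @return an object of class `fm_credible_set`: list with `constructed`,
#'   `members` (variant ids, decreasing posterior), `posteriors` (per member),
#'   `total_mass`, `lead_p`, `lead_variant`, `level`, `gate_threshold`, and
#'   `region_posteriors` (tibble of all variants' posteriors).
#' @export
build_credible_set <- function(meta, w = 0.04, level = 0.95,
                               gate_threshold = 5e-8) {
  stopifnot(nrow(meta) >= 1)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  log_p <- if ("log_p" %in% names(meta)) meta$log_p else base::log(meta$p_value)
  lead <- which.min(log_p)
  lead_p <- meta$p_value[lead]
  la <- approx_bayes_factor(meta$pooled_beta, meta$pooled_var, w = w, log = TRUE)
  post <- posterior_probabilities(la, log = TRUE)
  region <- tibble::tibble(variant = meta$variant, posterior = post)
  gate_pass <- log_p[lead] < base::log(gate_threshold)
  if (!gate_pass) {
    return(structure(list(constructed = FALSE, members = integer(0),
                          posteriors = numeric(0), total_mass = 0,
                          lead_p = lead_p, lead_variant = meta$variant[lead],
                          level = level, gate_threshold = gate_threshold,
                          region_posteriors = region),
                     class = "fm_credible_set"))
  }
  ord <- order(-post, meta$variant)
  cum <- cumsum(post[ord])
  # strict exceedance: a cumulative mass exactly equal to the level does not
  # close the set; the epsilon guards the comparison against floating-point
  # noise in the cumulative sum
  n_set <- which(cum > level + 1e-12)[1]
  if (is.na(n_set)) n_set <- length(ord) # numerical guard; mass sums to 1
  take <- ord[seq_len(n_set)]
  structure(list(constructed = TRUE,
                 members = meta$variant[take],
                 posteriors = post[take],
                 total_mass = cum[n_set],
                 lead_p = lead_p, lead_variant = meta$variant[lead],
                 level = level, gate_threshold = gate_threshold,
                 region_posteriors = region),
            class = "fm_credible_set")
}

#' @export
print.fm_credible_set <- function(x, ...) {
  if (!x$constructed) {
    cat("<fm_credible_set> not constructed (lead P =", format(x$lead_p),
        ">= gate", format(x$gate_threshold), ")\n")
  } else {
    cat("<fm_credible_set>", length(x$members), "variants, total mass",
        round(x$total_mass, 4), "| lead P =", format(x$lead_p), "\n")
  }
  invisible(x)
}

#' @export
tidy.fm_credible_set <- function(x, ...) {
  tibble::tibble(variant = x$members, posterior = x$posteriors,
                 rank = seq_along(x$members))
}

#' @export
glance.fm_credible_set <- function(x, ...) {
  tibble::tibble(constructed = x$constructed,
                 set_size = length(x$members),
                 total_mass = x$total_mass,
                 lead_variant = x$lead_variant,
                 lead_p = x$lead_p,
                 level = x$level,
                 gate_threshold = x$gate_threshold)
}
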