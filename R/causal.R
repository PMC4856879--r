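maf_of <- function(f) pmin(f, 1 - f)

# MAF-class -> per-allele relative risk pairing used throughout the study
rr_for_maf_class <- function(maf_class) {
  pairing <- c(`0.05` = 1.4, `0.1` = 1.3, `0.2` = 1.2)
  key <- as.character(maf_class)
  if (!key %in% names(pairing)) {
    stop("maf_class must be one of 0.05, 0.10, 0.20", call. = FALSE)
  }
  unname(pairing[key])
}

#' Select a causal variant in a MAF window
#'
#' Picks a variant whose minor allele frequency in the reference population
#' lies within `maf_class` +/- `maf_tol` and which is polymorphic in every
#' population of the panel. Among eligible variants the choice is a seeded
#' uniform draw (deterministic given `seed`); with `seed = NULL` the smallest
#' eligible index is returned.
#'
#' @param panel an `fm_panel`.
#' @param ref_pop population whose frequency defines the window (default the
#'   first population).
#' @param maf_class target minor allele frequency, in (0, 0.5].
#' @param maf_tol half-width of the frequency window (default 0.005).
#' @param seed optional integer seed for the tie-break draw.
#' @param window_pops optional further populations in which the variant's MAF
#'   must lie within `window_tol` of `maf_class` (used for scenarios that
#'   require a comparable causal frequency in every cohort).
#' @param window_tol half-width of the auxiliary window (default 0.03).
#' @return a variant index.
#' @export
select_causal_variant <- function(panel, ref_pop = names(panel$haplotypes)[1],
                                  maf_class = 0.05, maf_tol = 0.005,
                                  seed = NULL, window_pops = NULL,
                                  window_tol = 0.03) {
  stopifnot(maf_class > 0, maf_class <= 0.5)
  maf_ref <- maf_of(panel$freqs[[ref_pop]])
  in_window <- maf_ref >= maf_class - maf_tol & maf_ref <= maf_class + maf_tol
  poly_all <- Reduce(`&`, lapply(panel$freqs, function(f) f > 0 & f < 1))
  for (pop in setdiff(window_pops, ref_pop)) {
    maf_p <- maf_of(panel$freqs[[pop]])
    in_window <- in_window & abs(maf_p - maf_class) <= window_tol
  }
  eligible <- which(in_window & poly_all)
  if (length(eligible) == 0) {
    stop("no candidate causal variant in the MAF window that is polymorphic ",
         "in all populations; regenerate the panel", call. = FALSE)
  }
  if (is.null(seed)) return(eligible[1])
  with_seed(seed, eligible[sample.int(length(eligible), 1)])
}

#' Select a secondary causal variant in low LD with the first
#'
#' Picks a variant distinct from `c1` whose reference-population MAF is within
#' `maf_tol` of `c1`'s and whose r^2 with `c1` in the reference population is
#' below `r2_max` (default 0.2), emulating a second causal allele of similar
#' frequency but on a different haplotype background.
#'
#' @param panel an `fm_panel`.
#' @param c1 index of the primary causal variant.
#' @param ref_pop population in which MAF and LD constraints are evaluated.
#' @param maf_tol MAF half-window around `c1`'s MAF (default 0.005).
#' @param r2_max LD ceiling (default 0.2).
#' @param seed optional integer seed for the tie-break draw; `NULL` returns the
#'   smallest eligible index.
#' @param require_polymorphic if `TRUE`, candidates must also be polymorphic in
#'   every population of the panel.
#' @return a variant index.
#' @export
select_secondary_causal <- function(panel, c1,
                                    ref_pop = names(panel$haplotypes)[1],
                                    maf_tol = 0.005, r2_max = 0.2,
                                    seed = NULL, require_polymorphic = FALSE) {
  stopifnot(c1 >= 1, c1 <= length(panel$positions))
  maf_ref <- maf_of(panel$freqs[[ref_pop]])
  ok <- abs(maf_ref - maf_ref[c1]) <= maf_tol
  ok[c1] <- FALSE
  mono <- panel$freqs[[ref_pop]] <= 0 | panel$freqs[[ref_pop]] >= 1
  ok[mono] <- FALSE
  if (require_polymorphic) {
    ok <- ok & Reduce(`&`, lapply(panel$freqs, function(f) f > 0 & f < 1))
  }
  cand <- which(ok)
  if (length(cand) > 0) {
    h <- panel$haplotypes[[ref_pop]]
    r2 <- vapply(cand, function(j) hap_r2(h[, c1], h[, j]), numeric(1))
    cand <- cand[r2 < r2_max]
  }
  if (length(cand) == 0) {
    stop("no candidate secondary causal variant (similar MAF, r^2 < ",
         r2_max, "); regenerate the panel", call. = FALSE)
  }
  if (is.null(seed)) return(cand[1])
  with_seed(seed, cand[sample.int(length(cand), 1)])
}

#' Causal configuration for a simulated locus
#'
#' Bundles the causal variant(s), the MAF class with its paired per-allele
#' relative risk (1.4 at MAF 5%, 1.3 at 10%, 1.2 at 20%), and the per-cohort
#' effect assignment (`"c1"`, `"c2"` or `"null"`).
#'
#' @param c1 primary causal variant index.
#' @param maf_class one of 0.05, 0.10, 0.20.
#' @param cohort_effects named character vector mapping cohort labels to
#'   `"c1"`, `"c2"` or `"null"`.
#' @param c2 secondary causal variant index, or `NULL`.
#' @param rr per-allele relative risk; defaults to the class pairing.
#' @param maf_tol window half-width recorded for provenance.
#' @param seed tie-break seed recorded for provenance.
#' @return an object of class `fm_causal_config`.
#' @export
causal_config <- function(c1, maf_class, cohort_effects, c2 = NULL,
                          rr = rr_for_maf_class(maf_class), maf_tol = 0.005,
                          seed = NULL) {
  stopifnot(length(c1) == 1, c1 >= 1)
  if (rr <= 0) stop("relative risk must be positive", call. = FALSE)
  effects <- as.character(cohort_effects)
  names(effects) <- names(cohort_effects)
  if (!all(effects %in% c("c1", "c2", "null"))) {
    stop("cohort effects must be 'c1', 'c2' or 'null'", call. = FALSE)
  }
  if (any(effects == "c2") && is.null(c2)) {
    stop("cohort effects reference c2 but no c2 given", call. = FALSE)
  }
  structure(list(c1 = as.integer(c1),
                 c2 = if (is.null(c2)) NULL else as.integer(c2),
                 maf_class = maf_class, maf_tol = maf_tol, rr = rr,
                 cohort_effects = effects, seed = seed),
            class = "fm_causal_config")
}

#' @export
print.fm_causal_config <- function(x, ...) {
  cat("<fm_causal_config> c1 =", x$c1,
      if (!is.null(x$c2)) paste(", c2 =", x$c2) else "",
      "| MAF class", x$maf_class, "| RR", x$rr, "\n")
  cat("  cohort effects:",
      paste(names(x$cohort_effects), x$cohort_effects, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
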