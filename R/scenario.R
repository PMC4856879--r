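#' Cohort layout of a study design
#'
#' Returns the six-cohort composition of each meta-analysis design:
#' * `single_eu` -- six cohorts from the first European population;
#' * `moderate`  -- three cohorts from the pooled European pair and three from
#'   the pooled East Asian pair;
#' * `high`      -- one cohort from each of the six populations;
#' * `single_af` -- three cohorts from each of the two African populations.
#'
#' @param design one of `"single_eu"`, `"moderate"`, `"high"`, `"single_af"`.
#' @return a tibble with columns `cohort` (label), `pops` (list column of
#'   population labels to pool) and `ancestry` (`"EU"`, `"EA"` or `"AF"`).
#' @export
design_cohorts <- function(design = c("single_eu", "moderate", "high", "single_af")) {
  design <- match.arg(design)
  switch(design,
    single_eu = tibble::tibble(
      cohort = paste0("EU1_", 1:6),
      pops = rep(list("EU1"), 6),
      ancestry = rep("EU", 6)),
    moderate = tibble::tibble(
      cohort = c(paste0("EUpool_", 1:3), paste0("EApool_", 1:3)),
      pops = c(rep(list(c("EU1", "EU2")), 3), rep(list(c("EA1", "EA2")), 3)),
      ancestry = rep(c("EU", "EA"), each = 3)),
    high = tibble::tibble(
      cohort = c("EU1", "EU2", "EA1", "EA2", "AF1", "AF2"),
      pops = as.list(c("EU1", "EU2", "EA1", "EA2", "AF1", "AF2")),
      ancestry = c("EU", "EU", "EA", "EA", "AF", "AF")),
    single_af = tibble::tibble(
      cohort = c(paste0("AF1_", 1:3), paste0("AF2_", 1:3)),
      pops = c(rep(list("AF1"), 3), rep(list("AF2"), 3)),
      ancestry = rep("AF", 6))
  )
}

# effect assignment per cohort implied by a heterogeneity mode:
#   none             -- every cohort causal at c1
#   allelic          -- EA cohorts causal at c2, others at c1
#   locus            -- EA and AF cohorts null, others at c1
#   allelic_and_locus - EA cohorts at c2, AF cohorts null, others at c1
heterogeneity_effects <- function(cohorts, heterogeneity) {
  eff <- rep("c1", nrow(cohorts))
  if (heterogeneity == "allelic") {
    eff[cohorts$ancestry == "EA"] <- "c2"
  } else if (heterogeneity == "locus") {
    eff[cohorts$ancestry %in% c("EA", "AF")] <- "null"
  } else if (heterogeneity == "allelic_and_locus") {
    eff[cohorts$ancestry == "EA"] <- "c2"
    eff[cohorts$ancestry == "AF"] <- "null"
  } else if (heterogeneity != "none") {
    stop("unknown heterogeneity mode: ", heterogeneity, call. = FALSE)
  }
  stats::setNames(eff, cohorts$cohort)
}

#' Scenario specification
#'
#' Bundles the knobs of one replicated simulation scenario: the ancestry
#' design, the heterogeneity mode, the causal MAF class (which fixes the
#' per-allele relative risk), replication count, meta-analysis model, and the
#' fine-mapping parameters.
#'
#' @param design see [design_cohorts()].
#' @param heterogeneity one of `"none"`, `"allelic"`, `"locus"`,
#'   `"allelic_and_locus"`.
#' @param maf_class causal MAF class: 0.05, 0.10 or 0.20.
#' @param n_reps number of replicates (default 1000).
#' @param meta_model `"fixed"` or `"random"`.
#' @param seed scenario seed.
#' @param n_case,n_ctrl per-cohort counts (default 1000/1000).
#' @param prevalence disease prevalence (default 0.01).
#' @param w,level,gate_threshold fine-mapping parameters (defaults 0.04, 0.95,
#'   5e-8).
#' @return a list of class `fm_scenario_spec`.
#' @export
scenario_spec <- function(design = "single_eu", heterogeneity = "none",
                          maf_class = 0.05, n_reps = 1000,
                          meta_model = c("fixed", "random"), seed = 1L,
                          n_case = 1000, n_ctrl = 1000, prevalence = 0.01,
                          w = 0.04, level = 0.95, gate_threshold = 5e-8) {
  meta_model <- match.arg(meta_model)
  cohorts <- design_cohorts(design)
  if (heterogeneity %in% c("allelic", "allelic_and_locus") &&
      !any(cohorts$ancestry == "EA")) {
    stop("allelic heterogeneity requires a design with East Asian cohorts",
         call. = FALSE)
  }
  structure(list(design = design, heterogeneity = heterogeneity,
                 maf_class = maf_class, n_reps = as.integer(n_reps),
                 meta_model = meta_model, seed = as.integer(seed),
                 n_case = n_case, n_ctrl = n_ctrl, prevalence = prevalence,
                 w = w, level = level, gate_threshold = gate_threshold),
            class = "fm_scenario_spec")
}

#' Prepare the causal configuration a scenario needs from a panel
#'
#' Selects c1 in the reference population's MAF window (polymorphic in all
#' populations), selects c2 (similar MAF, r^2 < 0.2 with c1, polymorphic in
#' all populations) when the heterogeneity mode needs it, and assigns each
#' cohort of the design its effect.
#'
#' @param panel an `fm_panel`.
#' @param spec an [scenario_spec()].
#' @param ref_pop reference population for causal selection (default `"EU1"`).
#' @param window_pops,window_tol optional auxiliary MAF window passed to
#'   [select_causal_variant()] (e.g. all populations, for scenarios that need
#'   a comparable causal frequency in every cohort).
#' @return an [causal_config()] object.
#' @export
scenario_config <- function(panel, spec, ref_pop = "EU1",
                            window_pops = NULL, window_tol = 0.03) {
  cohorts <- design_cohorts(spec$design)
  effects <- heterogeneity_effects(cohorts, spec$heterogeneity)
  sel_seed <- seed_child(spec$seed, 777)
  c1 <- select_causal_variant(panel, ref_pop = ref_pop,
                              maf_class = spec$maf_class, seed = sel_seed,
                              window_pops = window_pops,
                              window_tol = window_tol)
  c2 <- NULL
  if (any(effects == "c2")) {
    c2 <- select_secondary_causal(panel, c1, ref_pop = ref_pop,
                                  seed = seed_child(spec$seed, 778),
                                  require_polymorphic = TRUE)
  }
  causal_config(c1 = c1, maf_class = spec$maf_class, cohort_effects = effects,
                c2 = c2, seed = sel_seed)
}

#' Generate a region panel guaranteed to carry eligible causal variants
#'
#' Builds haplotype panels with derived seeds until causal-variant selection
#' succeeds for every supplied scenario (MAF window in the reference
#' population, polymorphic everywhere, plus a low-LD secondary variant when a
#' scenario's heterogeneity mode needs one). Regions whose frequency spectrum
#' happens to contain no eligible variant are discarded and regenerated, the
#' behaviour the selection errors prescribe.
#'
#' @param specs a single [scenario_spec()] or a list of them.
#' @param seed base seed for the panel search (attempt k uses the k-th derived
#'   seed).
#' @param ... arguments passed to [build_reference_panel()] (`n_variants`,
#'   `n_haplotypes`, ...).
#' @param ref_pop,window_pops,window_tol causal-selection arguments, see
#'   [scenario_config()].
#' @param max_tries panel regeneration budget (default 25).
#' @return a list with `panel`, `configs` (one [causal_config()] per spec) and
#'   `attempts`.
#' @export
find_eligible_panel <- function(specs, seed, ..., ref_pop = "EU1",
                                window_pops = NULL, window_tol = 0.08,
                                max_tries = 25) {
  if (inherits(specs, "fm_scenario_spec")) specs <- list(specs)
  for (k in seq_len(max_tries)) {
    panel <- build_reference_panel(..., seed = seed_child(seed, 9000 + k))
    configs <- lapply(specs, function(sp) {
      tryCatch(scenario_config(panel, sp, ref_pop = ref_pop,
                               window_pops = window_pops,
                               window_tol = window_tol),
               error = function(e) NULL)
    })
    if (!any(vapply(configs, is.null, logical(1)))) {
      return(list(panel = panel, configs = configs, attempts = k))
    }
  }
  stop("no panel with eligible causal variants after ", max_tries,
       " attempts", call. = FALSE)
}

#' Run a replicated simulation scenario
#'
#' For each replicate: sample every cohort of the design (each with its own
#' derived seed), compute per-cohort association statistics, meta-analyse
#' (fixed or random effects), and -- in `"full"` mode -- build the gated 95%
#' credible set. Replicates whose meta-analysis lacks the causal variant c1
#' entirely (degenerate cohorts) are regenerated with the next derived seed
#' and counted in the `regenerated` attribute.
#'
#' @param panel an `fm_panel`.
#' @param config an [causal_config()]; defaults to [scenario_config()] on the
#'   fly.
#' @param spec an [scenario_spec()].
#' @param mode `"full"` (association at every variant plus credible set) or
#'   `"power"` (association at c1 only; no credible set -- much faster for
#'   power studies).
#' @return a tibble of class `fm_scenario`, one row per replicate:
#'   `replicate`, `p_c1` (meta P at c1), `constructed`, `set_size`,
#'   `contains_causal`, `lead_p`, `lead_variant`. In `"power"` mode the
#'   credible-set columns are `NA`. Attributes: `spec`, `config`,
#'   `regenerated`.
#' @export
run_scenario <- function(panel, spec, config = scenario_config(panel, spec),
                         mode = c("full", "power")) {
  mode <- match.arg(mode)
  cohorts <- design_cohorts(spec$design)
  n_cohort <- nrow(cohorts)
  variants <- if (mode == "power") config$c1 else NULL

  one_rep <- function(rep_seed) {
    stats <- vector("list", n_cohort)
    for (i in seq_len(n_cohort)) {
      co <- sample_cohort(panel, cohorts$pops[[i]], config, cohorts$cohort[i],
                          n_case = spec$n_case, n_ctrl = spec$n_ctrl,
                          prevalence = spec$prevalence,
                          seed = seed_child(rep_seed, i),
                          variants = variants)
      stats[[i]] <- suppressWarnings(single_snp_association(co))
    }
    stats <- stats[vapply(stats, nrow, 1L) > 0]
    if (length(stats) == 0) return(NULL)
    meta <- if (spec$meta_model == "random") random_effects_meta(stats)
            else fixed_effects_meta(stats)
    if (!config$c1 %in% meta$variant) return(NULL)
    p_c1 <- meta$p_value[match(config$c1, meta$variant)]
    if (mode == "power") {
      return(tibble::tibble(p_c1 = p_c1, constructed = NA, set_size = NA_integer_,
                            contains_causal = NA, lead_p = NA_real_,
                            lead_variant = NA_integer_))
    }
    cs <- build_credible_set(meta, w = spec$w, level = spec$level,
                             gate_threshold = spec$gate_threshold)
    tibble::tibble(p_c1 = p_c1,
                   constructed = cs$constructed,
                   set_size = if (cs$constructed) length(cs$members) else NA_integer_,
                   contains_causal = if (cs$constructed) config$c1 %in% cs$members else NA,
                   lead_p = cs$lead_p,
                   lead_variant = cs$lead_variant)
  }

  rows <- vector("list", spec$n_reps)
  regenerated <- 0L
  for (r in seq_len(spec$n_reps)) {
    attempt <- 0L
    res <- NULL
    while (is.null(res) && attempt < 20L) {
      res <- one_rep(seed_child(spec$seed, r + attempt * (spec$n_reps + 1L)))
      if (is.null(res)) {
        attempt <- attempt + 1L
        regenerated <- regenerated + 1L
      }
    }
    if (is.null(res)) {
      stop("replicate ", r, " degenerate after 20 regenerations", call. = FALSE)
    }
    rows[[r]] <- res
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, replicate = dplyr::row_number(), .before = 1)
  class(out) <- c("fm_scenario", class(out))
  attr(out, "spec") <- spec
  attr(out, "config") <- config
  attr(out, "regenerated") <- regenerated
  out
}

#' @export
tidy.fm_scenario <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fm_scenario")
  out
}

#' Scenario-level summary
#'
#' @param x an `fm_scenario` tibble.
#' @param alpha significance level for the power column (default 0.05).
#' @param ... unused.
#' @return a one-row tibble: design, heterogeneity, MAF class, replication
#'   count, power at c1, proportion of replicates with a constructed set,
#'   coverage among constructed sets, and the median size of
#'   causal-containing sets.
#' @export
glance.fm_scenario <- function(x, alpha = 0.05, ...) {
  spec <- attr(x, "spec")
  tibble::tibble(design = spec$design,
                 heterogeneity = spec$heterogeneity,
                 maf_class = spec$maf_class,
                 n_reps = nrow(x),
                 power_c1 = mean(x$p_c1 < alpha),
                 prop_constructed = mean(x$constructed %in% TRUE),
                 coverage = if (any(x$constructed %in% TRUE))
                   mean(x$contains_causal[x$constructed %in% TRUE]) else NA_real_,
                 median_set_size = median_set_size(x))
}
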