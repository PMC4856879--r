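default_config <- function() {
  list(
    output_dir = "finemapsim_out",
    panel = list(n_regions = 5, n_variants = 1000, n_haplotypes = 2000,
                 region_length = 1e6, seed = 42),
    cohort = list(n_case = 1000, n_ctrl = 1000, prevalence = 0.01),
    finemap = list(w = 0.04, level = 0.95, gate_threshold = 5e-8),
    alpha = 0.05,
    scenarios = list(list(design = "single_eu", heterogeneity = "none",
                          maf_class = 0.05, n_reps = 1000,
                          meta_model = "fixed"))
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && nm != "scenarios") {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Fills defaults and checks every field, failing with a message that names
#' the offending field.
#'
#' @param config a list (e.g. from [yaml::read_yaml()]) or a YAML file path.
#' @return the completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path", call. = FALSE)
  cfg <- merge_config(default_config(), config)

  chk <- function(ok, field, what) {
    if (!ok) stop("invalid config field '", field, "': ", what, call. = FALSE)
  }
  p <- cfg$panel
  chk(is.numeric(p$n_regions) && p$n_regions >= 1, "panel.n_regions", ">= 1")
  chk(is.numeric(p$n_variants) && p$n_variants >= 2, "panel.n_variants", ">= 2")
  chk(is.numeric(p$n_haplotypes) && p$n_haplotypes >= 4 &&
        p$n_haplotypes %% 2 == 0, "panel.n_haplotypes", "even and >= 4")
  chk(is.numeric(p$region_length) && p$region_length >= p$n_variants,
      "panel.region_length", "must fit n_variants")
  chk(is.numeric(p$seed) && p$seed == round(p$seed) && p$seed >= 0 &&
        p$seed < 2^31, "panel.seed", "integer in [0, 2^31)")
  f <- cfg$finemap
  chk(is.numeric(f$w) && f$w > 0, "finemap.w", "> 0")
  chk(is.numeric(f$level) && f$level > 0 && f$level < 1, "finemap.level",
      "in (0, 1)")
  chk(is.numeric(f$gate_threshold) && f$gate_threshold > 0 &&
        f$gate_threshold <= 1, "finemap.gate_threshold", "in (0, 1]")
  co <- cfg$cohort
  chk(is.numeric(co$n_case) && co$n_case >= 2, "cohort.n_case", ">= 2")
  chk(is.numeric(co$n_ctrl) && co$n_ctrl >= 2, "cohort.n_ctrl", ">= 2")
  chk(is.numeric(co$prevalence) && co$prevalence > 0 && co$prevalence < 1,
      "cohort.prevalence", "in (0, 1)")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1, "alpha",
      "in (0, 1)")
  chk(length(cfg$scenarios) >= 1, "scenarios", "need at least one scenario")
  for (i in seq_along(cfg$scenarios)) {
    s <- cfg$scenarios[[i]]
    fld <- function(x) paste0("scenarios[", i, "].", x)
    chk(!is.null(s$design) &&
          s$design %in% c("single_eu", "moderate", "high", "single_af"),
        fld("design"), "unknown design")
    het <- s$heterogeneity %||% "none"
    chk(het %in% c("none", "allelic", "locus", "allelic_and_locus"),
        fld("heterogeneity"), "unknown heterogeneity mode")
    chk(!is.null(s$maf_class) && s$maf_class %in% c(0.05, 0.10, 0.20),
        fld("maf_class"), "one of 0.05, 0.10, 0.20")
    chk((s$n_reps %||% 1000) >= 1, fld("n_reps"), ">= 1")
    chk((s$meta_model %||% "fixed") %in% c("fixed", "random"),
        fld("meta_model"), "fixed or random")
    cfg$scenarios[[i]]$heterogeneity <- het
    cfg$scenarios[[i]]$n_reps <- s$n_reps %||% 1000
    cfg$scenarios[[i]]$meta_model <- s$meta_model %||% "fixed"
  }
  cfg
}

#' Run the full simulation pipeline
#'
#' Generates `panel.n_regions` independently seeded haplotype panels (the
#' simulated regions), runs every configured scenario on each region, and
#' writes: per-replicate credible-set records (`replicates.tsv`), per-scenario
#' metrics in tidy long form (`metrics.tsv`), design-comparison tests
#' (`comparisons.tsv`, produced when at least two no-heterogeneity scenarios
#' at the same MAF class differ only in design), a JSON run manifest
#' (`manifest.json`), and a plain-text summary (`summary.txt`). Idempotent
#' given the seeds in the config.
#'
#' @param config a configuration list or YAML file path; see
#'   [validate_config()].
#' @return (invisibly) a list with `metrics`, `replicates`, `comparisons`
#'   tibbles and the output directory.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  # one panel per region, regenerated until every configured scenario can
  # select its causal variant(s) on it, so designs are compared on shared loci
  all_specs <- lapply(cfg$scenarios, function(sc) {
    scenario_spec(design = sc$design, heterogeneity = sc$heterogeneity,
                  maf_class = sc$maf_class, n_reps = 1, seed = 1L)
  })
  panels <- lapply(seq_len(cfg$panel$n_regions), function(r) {
    find_eligible_panel(all_specs, seed = seed_child(cfg$panel$seed, r),
                        n_variants = cfg$panel$n_variants,
                        n_haplotypes = cfg$panel$n_haplotypes,
                        region_length = cfg$panel$region_length)$panel
  })
  names(panels) <- paste0("region", seq_along(panels))

  reps <- list()
  metrics <- list()
  for (i in seq_along(cfg$scenarios)) {
    sc <- cfg$scenarios[[i]]
    sc_label <- paste0(sc$design, "/", sc$heterogeneity, "/maf",
                       sc$maf_class, "/", sc$meta_model)
    region_rows <- list()
    for (r in seq_along(panels)) {
      spec <- scenario_spec(design = sc$design, heterogeneity = sc$heterogeneity,
                            maf_class = sc$maf_class, n_reps = sc$n_reps,
                            meta_model = sc$meta_model,
                            seed = seed_child(cfg$panel$seed, 1000 * i + r),
                            n_case = cfg$cohort$n_case,
                            n_ctrl = cfg$cohort$n_ctrl,
                            prevalence = cfg$cohort$prevalence,
                            w = cfg$finemap$w, level = cfg$finemap$level,
                            gate_threshold = cfg$finemap$gate_threshold)
      res <- run_scenario(panels[[r]], spec)
      res$region <- names(panels)[r]
      res$scenario <- sc_label
      region_rows[[r]] <- tibble::as_tibble(res)
    }
    all_rows <- dplyr::bind_rows(region_rows)
    reps[[sc_label]] <- all_rows

    cov <- tryCatch(coverage_probability(all_rows), error = function(e) NULL)
    med <- all_rows |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(value = median_set_size(dplyr::pick(dplyr::everything())),
                       .groups = "drop")
    metric_rows <- dplyr::bind_rows(
      tibble::tibble(metric = "power_c1", region = "summary",
                     value = power_at_variant(all_rows, cfg$alpha),
                     se = NA_real_),
      if (!is.null(cov)) tibble::tibble(metric = "coverage", region = cov$region,
                                        value = cov$coverage, se = cov$se),
      tibble::tibble(metric = "median_set_size", region = med$region,
                     value = med$value, se = NA_real_),
      tibble::tibble(metric = "median_set_size", region = "summary",
                     value = if (any(!is.na(med$value)))
                       summary_over_regions(med$value[!is.na(med$value)])
                     else NA_real_,
                     se = NA_real_)
    )
    metric_rows$scenario <- sc_label
    metric_rows$design <- sc$design
    metric_rows$heterogeneity <- sc$heterogeneity
    metric_rows$maf_class <- sc$maf_class
    metrics[[sc_label]] <- metric_rows
  }
  replicates <- dplyr::bind_rows(reps)
  metrics <- dplyr::bind_rows(metrics)

  comparisons <- design_comparisons(replicates, metrics)

  write_credible_set_records(
    dplyr::relocate(replicates, "scenario", "region"),
    file.path(cfg$output_dir, "replicates.tsv"))
  readr::write_tsv(metrics, file.path(cfg$output_dir, "metrics.tsv"))
  if (nrow(comparisons) > 0) {
    readr::write_tsv(comparisons, file.path(cfg$output_dir, "comparisons.tsv"))
  }
  manifest <- list(package = "finemapsim",
                   version = as.character(utils::packageVersion("finemapsim")),
                   r_version = as.character(getRversion()),
                   config = cfg,
                   config_hash = rlang::hash(cfg))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(pipeline_summary_text(metrics, comparisons),
             file.path(cfg$output_dir, "summary.txt"))
  invisible(list(metrics = metrics, replicates = replicates,
                 comparisons = comparisons, output_dir = cfg$output_dir))
}

# rank/paired comparisons between designs, within no-heterogeneity scenarios
# sharing a MAF class and meta model
design_comparisons <- function(replicates, metrics) {
  sets <- metrics |>
    dplyr::filter(.data$heterogeneity == "none") |>
    dplyr::distinct(.data$scenario, .data$design, .data$maf_class)
  out <- list()
  for (maf in unique(sets$maf_class)) {
    designs <- sets[sets$maf_class == maf, ]
    if (nrow(designs) < 2) next
    sizes <- replicates |>
      dplyr::filter(.data$scenario %in% designs$scenario,
                    .data$constructed %in% TRUE,
                    .data$contains_causal %in% TRUE) |>
      dplyr::left_join(designs, by = "scenario")
    if (dplyr::n_distinct(sizes$design) < 2) next
    kw <- kruskal_wallis(sizes, value = "set_size", group = "design")
    dunn <- dunns_test(sizes, value = "set_size", group = "design")
    out[[length(out) + 1]] <- dplyr::bind_rows(
      tibble::tibble(maf_class = maf, test = "kruskal_wallis", pair = "all",
                     statistic = kw$statistic, p_value = kw$p_value),
      tibble::tibble(maf_class = maf, test = "dunn",
                     pair = paste(dunn$group1, dunn$group2, sep = " vs "),
                     statistic = dunn$z, p_value = dunn$p_value))
    med <- metrics |>
      dplyr::filter(.data$maf_class == maf, .data$heterogeneity == "none",
                    .data$metric == "median_set_size", .data$region != "summary")
    wide <- tidyr::pivot_wider(med[, c("region", "design", "value")],
                               names_from = "design", values_from = "value")
    rank_order <- c("single_eu", "moderate", "high", "single_af")
    present <- intersect(rank_order, names(wide))
    if (length(present) >= 2) {
      pairs <- utils::combn(present, 2)
      for (k in seq_len(ncol(pairs))) {
        lo <- pairs[1, k]; hi <- pairs[2, k]
        pt <- tryCatch(paired_t_by_region(wide[[lo]], wide[[hi]]),
                       error = function(e) NULL)
        if (!is.null(pt)) {
          out[[length(out) + 1]] <- tibble::tibble(
            maf_class = maf, test = "paired_t",
            pair = paste(lo, ">", hi), statistic = pt$t, p_value = pt$p_value)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(maf_class = numeric(0), test = character(0),
                          pair = character(0), statistic = numeric(0),
                          p_value = numeric(0)))
  }
  dplyr::bind_rows(out)
}

pipeline_summary_text <- function(metrics, comparisons) {
  lines <- c("finemapsim pipeline summary", "")
  summ <- metrics[metrics$region == "summary", ]
  for (i in seq_len(nrow(summ))) {
    lines <- c(lines, sprintf("%-45s %-16s %.4g", summ$scenario[i],
                              summ$metric[i], summ$value[i]))
  }
  if (nrow(comparisons) > 0) {
    lines <- c(lines, "", "design comparisons:")
    for (i in seq_len(nrow(comparisons))) {
      lines <- c(lines, sprintf("maf %.2f  %-15s %-28s stat=%.4g p=%.3g",
                                comparisons$maf_class[i], comparisons$test[i],
                                comparisons$pair[i], comparisons$statistic[i],
                                comparisons$p_value[i]))
    }
  }
  lines
}
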