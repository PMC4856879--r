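# small panels and hand-built objects shared across tests

# a two-population panel small enough for exhaustive checks
tiny_panel <- function(seed = 7, n_variants = 60, n_haplotypes = 200,
                       fst = c(0.05, 0.12), ld = c(0.9, 0.5)) {
  specs <- population_specs(labels = c("P1", "P2"), group = c("A", "B"),
                            fst = fst, fst_within = c(0, 0),
                            ld_strength = ld)
  build_reference_panel(specs, n_variants = n_variants,
                        n_haplotypes = n_haplotypes, region_length = 1e5,
                        seed = seed)
}

# panel wrapping explicit haplotype matrices (shared variant list)
manual_panel <- function(haplotypes) {
  m <- ncol(haplotypes[[1]])
  structure(list(positions = seq_len(m) * 100L,
                 ancestral_freqs = rep(0.25, m),
                 haplotypes = haplotypes,
                 freqs = lapply(haplotypes, colMeans),
                 pop_specs = NULL, n_founders = NA_integer_,
                 seed = NA_integer_),
            class = "fm_panel")
}

# cohort built from explicit genotype count vectors (g = 0/1/2)
cohort_from_counts <- function(case_counts, ctrl_counts) {
  g <- c(rep(0:2, case_counts), rep(0:2, ctrl_counts))
  structure(list(genotypes = matrix(g, ncol = 1),
                 status = rep(c(1L, 0L), c(sum(case_counts), sum(ctrl_counts))),
                 variants = 1L, pop = "manual", effect_variant = "c1",
                 n_case = sum(case_counts), n_ctrl = sum(ctrl_counts),
                 seed = NA_integer_),
            class = "fm_cohort")
}

# a small default-population panel reused by scenario-level tests
default_mini_panel <- function(seed = 42) {
  build_reference_panel(n_variants = 150, n_haplotypes = 400,
                        region_length = 3e5, seed = seed)
}

# small panel guaranteed to carry a causal variant in the requested MAF window
mini_causal <- function(maf_class = 0.05, seed = 42) {
  sp <- scenario_spec(design = "single_eu", maf_class = maf_class, n_reps = 1,
                      seed = seed)
  fe <- find_eligible_panel(sp, seed = seed, n_variants = 150,
                            n_haplotypes = 400, region_length = 3e5)
  list(panel = fe$panel, c1 = fe$configs[[1]]$c1)
}

# fm_meta tibble from explicit per-variant values
meta_from_values <- function(variant, beta, var) {
  out <- tibble::tibble(variant = variant, pooled_beta = beta,
                        pooled_var = var, se = sqrt(var),
                        p_value = 2 * stats::pnorm(-abs(beta / sqrt(var))),
                        q_stat = 0, tau2 = 0, k = 1L,
                        log_p = log(2) + stats::pnorm(-abs(beta / sqrt(var)),
                                                      log.p = TRUE))
  class(out) <- c("fm_meta", class(out))
  out
}
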