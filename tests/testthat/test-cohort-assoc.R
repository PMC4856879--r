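make_config <- function(c1, maf_class = 0.05, effects = c(coh = "c1"), ...) {
  causal_config(c1 = c1, maf_class = maf_class, cohort_effects = effects, ...)
}

test_that("cohort sampling is reproducible and exact in its counts", {
  mc <- mini_causal(0.05)
  pan <- mc$panel
  cfg <- make_config(mc$c1)
  co1 <- sample_cohort(pan, "EU1", cfg, "coh", n_case = 50, n_ctrl = 60,
                       seed = 5)
  co2 <- sample_cohort(pan, "EU1", cfg, "coh", n_case = 50, n_ctrl = 60,
                       seed = 5)
  expect_identical(co1, co2)
  expect_identical(sum(co1$status), 50L)
  expect_identical(sum(co1$status == 0), 60L)
  expect_true(all(co1$genotypes %in% 0:2))

  # genotype draws do not depend on which variants are materialised
  co_sub <- sample_cohort(pan, "EU1", cfg, "coh", n_case = 50, n_ctrl = 60,
                          seed = 5, variants = cfg$c1)
  expect_identical(co_sub$genotypes[, 1], co1$genotypes[, cfg$c1])

  # pooled-pair cohorts draw from the stacked haplotypes
  co_pool <- sample_cohort(pan, c("EU1", "EU2"), cfg, "coh", n_case = 20,
                           n_ctrl = 20, seed = 5)
  expect_identical(co_pool$pop, "EU1+EU2")
})

test_that("cohort sampling validates the disease model", {
  pan <- default_mini_panel()
  cfg <- make_config(1L)
  cfg_bad <- cfg
  cfg_bad$rr <- -1
  expect_error(sample_cohort(pan, "EU1", cfg_bad, "coh", 10, 10, seed = 1),
               "relative risk")
  expect_error(sample_cohort(pan, "EU1", cfg, "coh", 10, 10,
                             prevalence = 1.5, seed = 1), "prevalence")
  # P(disease | g = 2) = K * rr^2 above 1 is rejected
  cfg_hot <- make_config(1L, rr = 3)
  expect_error(sample_cohort(pan, "EU1", cfg_hot, "coh", 10, 10,
                             prevalence = 0.5, seed = 1), "g = 2")
  expect_error(sample_cohort(pan, "EU1", cfg, "unknown", 10, 10, seed = 1),
               "effect assignment")
})

test_that("null cohorts show no case/control frequency difference at c1", {
  mc <- mini_causal(0.20)
  pan <- mc$panel; c1 <- mc$c1
  cfg <- make_config(c1, maf_class = 0.20, effects = c(coh = "null"))
  diffs <- vapply(1:60, function(s) {
    co <- sample_cohort(pan, "EU1", cfg, "coh", n_case = 300, n_ctrl = 300,
                        seed = s, variants = c1)
    mean(co$genotypes[co$status == 1, 1]) / 2 -
      mean(co$genotypes[co$status == 0, 1]) / 2
  }, numeric(1))
  p <- pan$freqs$EU1[c1]
  se <- sqrt(2 * p * (1 - p) / 4) * sqrt(1 / 600 + 1 / 600) # rough per-rep SE
  expect_lt(abs(mean(diffs)), 3 * se / sqrt(60))
})

test_that("causal cohorts enrich the risk allele in cases", {
  mc <- mini_causal(0.05)
  pan <- mc$panel; c1 <- mc$c1
  cfg <- make_config(c1, maf_class = 0.05) # rr = 1.4
  pos <- vapply(1:100, function(s) {
    co <- sample_cohort(pan, "EU1", cfg, "coh", n_case = 1000, n_ctrl = 1000,
                        seed = 1000 + s, variants = c1)
    mean(co$genotypes[co$status == 1, 1]) >
      mean(co$genotypes[co$status == 0, 1])
  }, logical(1))
  expect_gt(mean(pos), 0.95)
})

test_that("large-sample log-odds at the causal variant recovers log(rr)", {
  mc <- mini_causal(0.10)
  pan <- mc$panel; c1 <- mc$c1
  cfg <- make_config(c1, maf_class = 0.10) # rr = 1.3
  co <- sample_cohort(pan, "EU1", cfg, "coh", n_case = 10000, n_ctrl = 10000,
                      seed = 77, variants = c1)
  st <- single_snp_association(co)
  expect_equal(st$beta_hat, log(1.3), tolerance = 0.05 / log(1.3))
})

test_that("association matches a maximum-likelihood logistic fit", {
  # symmetric table: identical genotype distributions -> beta 0, p 1
  co <- cohort_from_counts(c(250, 500, 250), c(250, 500, 250))
  st <- single_snp_association(co)
  expect_equal(st$beta_hat, 0, tolerance = 1e-10)
  expect_equal(st$p_value, 1, tolerance = 1e-10)

  # spec'd count example against glm on the expanded data
  co2 <- cohort_from_counts(c(300, 500, 200), c(400, 450, 150))
  st2 <- single_snp_association(co2)
  fit <- stats::glm(co2$status ~ co2$genotypes[, 1], family = binomial,
                    control = list(epsilon = 1e-12))
  expect_equal(st2$beta_hat, unname(coef(fit)[2]), tolerance = 1e-7)
  expect_equal(st2$se, sqrt(vcov(fit)[2, 2]), tolerance = 1e-7)
  z <- coef(fit)[2] / sqrt(vcov(fit)[2, 2])
  expect_equal(st2$p_value, unname(2 * pnorm(-abs(z))), tolerance = 1e-7)
  expect_equal(st2$eaf, (500 + 2 * 200 + 450 + 2 * 150) / (2 * 2000))

  # random cohorts: agreement at several variants
  mc <- mini_causal(0.10, seed = 43)
  pan <- mc$panel
  cfg <- make_config(mc$c1, maf_class = 0.10)
  co3 <- sample_cohort(pan, "EU1", cfg, "coh", n_case = 400, n_ctrl = 400,
                       seed = 12)
  st3 <- suppressWarnings(single_snp_association(co3))
  for (v in st3$variant[c(1, 25, 50, nrow(st3))]) {
    g <- co3$genotypes[, v]
    fit <- stats::glm(co3$status ~ g, family = binomial,
                      control = list(epsilon = 1e-12))
    j <- match(v, st3$variant)
    expect_equal(st3$beta_hat[j], unname(coef(fit)[2]), tolerance = 1e-6)
    expect_equal(st3$var[j], unname(vcov(fit)[2, 2]), tolerance = 1e-6)
  }
})

test_that("monomorphic and separated variants are filtered, not emitted", {
  g <- cbind(rep(1, 40),                       # monomorphic
             rep(c(0, 1, 2, 1), 10),             # clean, balanced
             c(rep(1, 5), rep(0, 35)))           # allele only in cases: separated
  co <- structure(list(genotypes = g, status = rep(c(1L, 0L), each = 20),
                       variants = 1:3, pop = "m", effect_variant = "null",
                       n_case = 20L, n_ctrl = 20L, seed = NA_integer_),
                  class = "fm_cohort")
  expect_warning(st <- single_snp_association(co), "separated")
  expect_identical(st$variant, 2L)

  co_small <- structure(list(genotypes = g[1:2, , drop = FALSE],
                             status = c(1L, 0L), variants = 1:3, pop = "m",
                             effect_variant = "null", n_case = 1L, n_ctrl = 1L,
                             seed = NA_integer_), class = "fm_cohort")
  expect_error(single_snp_association(co_small), "at least 2")
})

test_that("null Wald p-values are uniform and type-I error is nominal", {
  mc <- mini_causal(0.20, seed = 44)
  pan <- mc$panel; c1 <- mc$c1
  cfg <- make_config(c1, maf_class = 0.20, effects = c(coh = "null"))
  pvals <- vapply(1:1000, function(s) {
    co <- sample_cohort(pan, "EU1", cfg, "coh", n_case = 250, n_ctrl = 250,
                        seed = 5000 + s, variants = c1)
    single_snp_association(co)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(pvals < 0.05), 0.05, tolerance = 0.02 / 0.05)
})

test_that("cohort tables round-trip through the GWAMA-style format", {
  mc <- mini_causal(0.05, seed = 45)
  pan <- mc$panel
  cfg <- make_config(mc$c1)
  co <- sample_cohort(pan, "EU1", cfg, "coh", n_case = 100, n_ctrl = 100,
                      seed = 3)
  st <- suppressWarnings(single_snp_association(co))
  path <- withr::local_tempfile(fileext = ".txt")
  write_cohort_stats(st, path)
  back <- read_cohort_stats(path)
  expect_identical(back$variant, st$variant)
  expect_equal(back$beta_hat, st$beta_hat, tolerance = 1e-12)
  expect_equal(back$se, st$se, tolerance = 1e-12)
  expect_equal(back$p_value, st$p_value, tolerance = 1e-12)
  expect_identical(back$n, as.numeric(st$n))
  # swapped-allele rows are flipped back to the canonical orientation
  tab <- utils::read.table(path, header = TRUE,
                           colClasses = c(MARKER = "character",
                                          EA = "character", NEA = "character"))
  tab$EA[1] <- "A"; tab$NEA[1] <- "B"
  tab$BETA[1] <- -tab$BETA[1]; tab$EAF[1] <- 1 - tab$EAF[1]
  path2 <- withr::local_tempfile(fileext = ".txt")
  readr::write_delim(tab, path2, delim = " ")
  back2 <- read_cohort_stats(path2)
  expect_equal(back2$beta_hat[1], st$beta_hat[1], tolerance = 1e-12)
  expect_error(suppressWarnings(
    read_cohort_stats(withr::local_tempfile(fileext = ".txt"))),
    "cannot parse|lacks columns")
})
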