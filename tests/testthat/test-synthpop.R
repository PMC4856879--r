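test_that("panel generation is deterministic and internally consistent", {
  p1 <- tiny_panel(seed = 11)
  p2 <- tiny_panel(seed = 11)
  expect_identical(p1, p2)
  p3 <- tiny_panel(seed = 12)
  expect_false(identical(p1$haplotypes, p3$haplotypes))

  # shared variant list, strictly increasing positions, binary entries
  expect_true(all(diff(p1$positions) > 0))
  for (h in p1$haplotypes) {
    expect_equal(ncol(h), length(p1$positions))
    expect_true(all(h %in% c(0L, 1L)))
  }
  # no variant monomorphic in the pooled panel
  tot <- Reduce(`+`, lapply(p1$haplotypes, colSums))
  n_tot <- sum(vapply(p1$haplotypes, nrow, 1L))
  expect_true(all(tot > 0 & tot < n_tot))
  # frequency bookkeeping matches a direct recount
  expect_identical(p1$freqs$P1, colMeans(p1$haplotypes$P1))
})

test_that("panel builder validates its inputs", {
  expect_error(build_reference_panel(n_variants = 1), "n_variants")
  expect_error(build_reference_panel(n_variants = 10, n_haplotypes = 5),
               "n_haplotypes")
  expect_error(build_reference_panel(n_variants = 100, n_haplotypes = 10,
                                     region_length = 50), "region")
  expect_error(population_specs(fst = c(1.2, 0, 0, 0, 0, 0)), "fst")
  expect_error(population_specs(ld_strength = c(1, 0, 0, 0, 0, 0)),
               "ld_strength")
})

test_that("zero divergence: sample frequencies approach ancestral frequencies", {
  mad_at <- function(n_hap, seed) {
    specs <- population_specs(labels = "P1", group = "A", fst = 0,
                              fst_within = 0, ld_strength = 0)
    p <- build_reference_panel(specs, n_variants = 150, n_haplotypes = n_hap,
                               region_length = 1e5, seed = seed)
    mean(abs(p$freqs$P1 - p$ancestral_freqs))
  }
  small <- mean(vapply(1:3, function(s) mad_at(200, s), numeric(1)))
  large <- mean(vapply(1:3, function(s) mad_at(4000, s), numeric(1)))
  expect_lt(large, small)
  expect_lt(large, 0.04)
})

test_that("ld_strength = 0 gives linkage equilibrium between adjacent markers", {
  specs <- population_specs(labels = "P1", group = "A", fst = 0.05,
                            fst_within = 0, ld_strength = 0)
  p <- build_reference_panel(specs, n_variants = 501, n_haplotypes = 2000,
                             region_length = 1e6, seed = 3)
  expect_lt(mean_adjacent_r2(p, "P1"), 0.02)
})

test_that("Hudson Fst estimator recovers the divergence parameter", {
  specs <- population_specs(labels = c("P1", "P2"), group = c("A", "B"),
                            fst = c(0.15, 0.15), fst_within = c(0, 0),
                            ld_strength = c(0, 0))
  p <- build_reference_panel(specs, n_variants = 800, n_haplotypes = 5000,
                             region_length = 1e6, seed = 5)
  expect_equal(fst_hudson(p, "P1", "P2"), 0.15, tolerance = 0.03 / 0.15)
})

test_that("default panels order LD extent AF < EU and divergence AF > EU", {
  r2_eu <- r2_af <- numeric(20)
  for (s in 1:20) {
    p <- build_reference_panel(n_variants = 80, n_haplotypes = 300,
                               region_length = 1e5, seed = 100 + s)
    r2_eu[s] <- mean_adjacent_r2(p, "EU1")
    r2_af[s] <- mean_adjacent_r2(p, "AF1")
  }
  expect_lt(mean(r2_af), mean(r2_eu))
  spec <- population_specs()
  expect_true(all(spec$fst[spec$group == "AF"] > spec$fst[spec$group != "AF"]))
  expect_true(all(spec$ld_strength[spec$group == "AF"] <
                    spec$ld_strength[spec$group != "AF"]))
})

test_that("ld_r2 matches the 2x2 haplotype-table formula", {
  # hand case: alleles (0,0),(0,1),(1,0),(1,1) -> D = 0, r^2 = 0
  h <- matrix(c(0, 0, 1, 1,
                0, 1, 0, 1), ncol = 2)
  p <- manual_panel(list(P1 = h))
  expect_equal(ld_r2(p, "P1", 1, 2), 0)

  # duplicated column -> r^2 = 1
  h2 <- cbind(c(0, 1, 1, 0, 1, 0), c(0, 1, 1, 0, 1, 0))
  p2 <- manual_panel(list(P1 = h2))
  expect_equal(ld_r2(p2, "P1", 1, 2), 1)

  # brute-force check on generated data: D^2 / (p1 q1 p2 q2)
  pan <- tiny_panel(seed = 21)
  h3 <- pan$haplotypes$P1
  for (pair in list(c(1, 2), c(5, 30), c(10, 11))) {
    a <- h3[, pair[1]]; b <- h3[, pair[2]]
    d <- mean(a == 1 & b == 1) - mean(a) * mean(b)
    expected <- d^2 / (mean(a) * (1 - mean(a)) * mean(b) * (1 - mean(b)))
    expect_equal(ld_r2(pan, "P1", pair[1], pair[2]), expected)
    expect_equal(ld_r2(pan, "P1", pair[2], pair[1]),
                 ld_r2(pan, "P1", pair[1], pair[2]))
  }

  # independently generated columns at large n: near-zero r^2
  set.seed(9)
  h4 <- cbind(rbinom(20000, 1, 0.3), rbinom(20000, 1, 0.4))
  expect_lt(ld_r2(manual_panel(list(P1 = h4)), "P1", 1, 2), 0.001)

  expect_error(ld_r2(pan, "P1", 3, 3), "differ")
  mono <- manual_panel(list(P1 = cbind(rep(1, 4), c(0, 1, 0, 1))))
  expect_error(ld_r2(mono, "P1", 1, 2), "monomorphic")
})

test_that("causal variant selection honours the MAF window and polymorphism", {
  # unique candidate is returned regardless of tie-break seed
  h_yes <- c(rep(1, 5), rep(0, 95))                 # MAF 0.05
  h_no <- c(rep(1, 30), rep(0, 70))                 # MAF 0.30
  p1 <- matrix(rep(h_no, 8), ncol = 8)
  p1[, 7] <- h_yes
  p2 <- matrix(rep(h_no, 8), ncol = 8)
  p2[, 7] <- c(rep(1, 6), rep(0, 94))
  pan <- manual_panel(list(A = p1, B = p2))
  expect_identical(select_causal_variant(pan, "A", 0.05), 7L)
  expect_identical(select_causal_variant(pan, "A", 0.05, seed = 99), 7L)

  # only window variant monomorphic elsewhere -> explicit no-candidate error
  p2_mono <- p2
  p2_mono[, 7] <- 0
  pan2 <- manual_panel(list(A = p1, B = p2_mono))
  expect_error(select_causal_variant(pan2, "A", 0.05), "no candidate")

  # random panel: recount the returned variant's MAF from raw haplotypes
  pan3 <- tiny_panel(seed = 31, n_variants = 300, n_haplotypes = 1000)
  v <- tryCatch(select_causal_variant(pan3, "P1", 0.10, seed = 2),
                error = function(e) NULL)
  if (!is.null(v)) {
    maf <- min(mean(pan3$haplotypes$P1[, v]), 1 - mean(pan3$haplotypes$P1[, v]))
    expect_true(maf >= 0.095 && maf <= 0.105)
    expect_true(all(vapply(pan3$haplotypes,
                           function(h) mean(h[, v]) > 0 && mean(h[, v]) < 1,
                           logical(1))))
  } else {
    succeed("panel had no eligible variant; selection error path exercised")
  }
})

test_that("secondary causal selection enforces similar MAF and low LD", {
  pan <- tiny_panel(seed = 41, n_variants = 300, n_haplotypes = 1000)
  fe <- find_eligible_panel(
    scenario_spec(design = "single_eu", maf_class = 0.10, n_reps = 1, seed = 1),
    seed = 41, pop_specs = population_specs(
      labels = c("EU1", "P2"), group = c("EU", "B"), fst = c(0.05, 0.12),
      fst_within = c(0, 0), ld_strength = c(0.985, 0.5)),
    n_variants = 300, n_haplotypes = 1000, region_length = 3e5)
  pan <- fe$panel
  c1 <- fe$configs[[1]]$c1
  c2 <- select_secondary_causal(pan, c1, "EU1", seed = 5)
  expect_true(c2 != c1)
  h <- pan$haplotypes$EU1
  maf <- function(v) min(mean(h[, v]), 1 - mean(h[, v]))
  expect_lte(abs(maf(c2) - maf(c1)), 0.005)
  # brute-force r^2 from the 2x2 haplotype table
  a <- h[, c1]; b <- h[, c2]
  d <- mean(a * b) - mean(a) * mean(b)
  r2 <- d^2 / (mean(a) * (1 - mean(a)) * mean(b) * (1 - mean(b)))
  expect_lt(r2, 0.2)

  # unconstrained case: every ref-pop-polymorphic variant except c1 is
  # eligible and the tie-break (smallest index) wins
  f <- pan$freqs$EU1
  first_eligible <- min(setdiff(which(f > 0 & f < 1), c1))
  expect_identical(select_secondary_causal(pan, c1, "EU1", maf_tol = 0.5,
                                           r2_max = 1.0),
                   as.integer(first_eligible))
  # impossible constraint -> no-candidate error
  expect_error(select_secondary_causal(pan, c1, "EU1", maf_tol = 0, r2_max = 0),
               "no candidate")
})

test_that("hap/legend export round-trips the panel", {
  pan <- tiny_panel(seed = 51, n_variants = 40, n_haplotypes = 50)
  dir <- withr::local_tempdir()
  write_hap_legend(pan, dir)
  for (pop in names(pan$haplotypes)) {
    back <- read_hap_legend(dir, pop)
    expect_identical(unname(back$haplotypes), unname(pan$haplotypes[[pop]]))
    expect_identical(back$legend$position, as.integer(pan$positions))
  }
})
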