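#' Population specification table
#'
#' Builds the tibble of population parameters used by [build_reference_panel()].
#' Each population has a divergence parameter `fst` (Balding-Nichols, relative
#' to the shared ancestral allele-frequency pool, applied at the continental
#' group level), a small `fst_within` separating the two populations of a
#' continental pair, and an `ld_strength` in [0, 1) controlling the extent of
#' linkage disequilibrium (the adjacent-marker correlation of the latent
#' haplotype-copying process).
#'
#' The defaults emulate six reference panels in three continental pairs --
#' European (EU1, EU2), East Asian (EA1, EA2) and African (AF1, AF2) -- with
#' the two features the study design turns on: African populations have
#' strictly larger divergence from the pool and strictly shorter-range LD than
#' the European/East Asian populations, and within-pair divergence is much
#' smaller than between-pair divergence.
#'
#' @param labels character vector of population labels.
#' @param group continental group per population.
#' @param fst ancestral-to-group divergence per population, in [0, 1).
#' @param fst_within group-to-population divergence, in [0, 1).
#' @param ld_strength latent adjacent-marker copying correlation, in [0, 1).
#' @return a tibble with one row per population.
#' @export
#' @examples
#' population_specs()
population_specs <- function(labels = c("EU1", "EU2", "EA1", "EA2", "AF1", "AF2"),
                             group = c("EU", "EU", "EA", "EA", "AF", "AF"),
                             fst = c(0.05, 0.05, 0.06, 0.06, 0.12, 0.12),
                             fst_within = c(0.004, 0.004, 0.007, 0.007, 0.008, 0.008),
                             ld_strength = c(0.985, 0.985, 0.985, 0.985, 0.8, 0.8)) {
  n <- length(labels)
  stopifnot(n >= 1, length(group) == n, length(fst) == n,
            length(fst_within) == n, length(ld_strength) == n)
  if (any(fst < 0 | fst >= 1) || any(fst_within < 0 | fst_within >= 1)) {
    stop("fst values must lie in [0, 1)", call. = FALSE)
  }
  if (any(ld_strength < 0 | ld_strength >= 1)) {
    stop("ld_strength must lie in [0, 1)", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("population labels must be unique", call. = FALSE)
  tibble::tibble(label = as.character(labels), group = as.character(group),
                 fst = fst, fst_within = fst_within, ld_strength = ld_strength)
}

# Balding-Nichols draw: Beta(p(1-F)/F, (1-p)(1-F)/F); F = 0 returns p unchanged
rbeta_bn <- function(p, fst) {
  if (fst <= 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  stats::rbeta(length(p), a, b)
}

# n_hap x m binary matrix: latent Gaussian AR(1) (parameter rho) thresholded
# column-wise at qnorm(freq). rho = 0 gives independent columns. Used to give
# the founder pool its own short-range allelic correlation.
sim_latent_ar1 <- function(n_hap, freqs, rho) {
  m <- length(freqs)
  z <- matrix(0, n_hap, m)
  z[, 1] <- stats::rnorm(n_hap)
  if (m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + s * stats::rnorm(n_hap)
  }
  thr <- stats::qnorm(freqs)
  storage.mode(z) <- "double"
  (sweep(z, 2, thr, "<")) * 1L
}

# First-order copying process: each output haplotype is a Markov mosaic of a
# finite founder pool (switch probability 1 - rho per adjacent marker), the
# mechanism behind haplotype-resampling simulators. The founder pool carries
# latent AR(1) correlation rho, and founder columns flagged in `dup_cols` are
# exact copies of their left neighbour -- variant pairs that arose on the
# same haplotype background and were never separated by recombination in this
# population's history, the source of the near-perfect proxies (r^2 ~ 1) that
# real reference panels show. Both the copying tract length and (via the
# retention of ancestral proxy pairs, decided in build_reference_panel) the
# proxy rate increase with rho.
sim_haplotypes <- function(n_hap, freqs, rho, n_founders, dup_cols = NULL) {
  m <- length(freqs)
  founders <- sim_latent_ar1(n_founders, freqs, rho)
  if (!is.null(dup_cols)) {
    # members of a retained proxy run copy the run-head column (not their
    # neighbour), so within-run allelic identity does not decay with distance;
    # gene-conversion-like breakage flips each founder with probability
    # 1 - rho, giving the run a graded r^2 spectrum around the head
    head <- seq_len(m)
    for (j in which(dup_cols)) head[j] <- head[j - 1]
    for (j in which(dup_cols)) {
      keep <- stats::runif(n_founders) < rho
      founders[keep, j] <- founders[keep, head[j]]
    }
  }
  switch_p <- 1 - rho
  x <- matrix(0L, n_hap, m)
  u <- sample.int(n_founders, n_hap, replace = TRUE)
  x[, 1] <- founders[u]
  if (m > 1) {
    for (j in 2:m) {
      sw <- stats::runif(n_hap) < switch_p
      n_sw <- sum(sw)
      if (n_sw > 0) u[sw] <- sample.int(n_founders, n_sw, replace = TRUE)
      x[, j] <- founders[u + (j - 1L) * n_founders]
    }
  }
  x
}

#' Generate a multi-population haplotype reference panel
#'
#' Simulates a genomic region shared by several populations. Ancestral minor
#' allele frequencies are drawn Uniform(0.02, 0.5); each continental group's
#' frequencies diverge from the ancestral pool by a Balding-Nichols draw with
#' parameter `fst`, and each population diverges from its group by a second
#' draw with parameter `fst_within`. Haplotypes are then generated by a
#' first-order copying process: each population has a finite founder pool
#' (itself carrying latent AR(1) allelic correlation `ld_strength`), and every
#' haplotype is a Markov mosaic of founders with per-marker switch probability
#' `1 - ld_strength`. Adjacent variants form ancestral proxy pairs (shared
#' ancestral frequency, identical founder columns) with rate 0.9; each
#' continental group retains a pair intact with probability
#' `ld_strength^5`, so long-LD panels keep many near-perfect proxies while
#' short-LD (African-like) panels break most of them. Both the founder
#' correlation and the copying tract length -- hence LD extent -- increase
#' with `ld_strength`. Columns monomorphic across the
#' pooled panel are resampled (fresh frequency and independent founders) and
#' dropped if still monomorphic after ten attempts.
#'
#' @param pop_specs tibble from [population_specs()].
#' @param n_variants number of variants (>= 2).
#' @param n_haplotypes haplotypes per population (even, >= 4).
#' @param region_length region size in base pairs; positions are drawn
#'   uniformly without replacement and sorted.
#' @param n_founders founder haplotypes per population copying pool; the
#'   default grows with the panel so that sample frequencies converge to the
#'   ancestral frequencies as the panel grows.
#' @param seed integer seed; identical seeds give bit-identical panels.
#' @return an object of class `fm_panel`: a list with `positions`,
#'   `ancestral_freqs`, `haplotypes` (named list of n_haplotypes x n_variants
#'   0/1 matrices), `freqs` (per-population allele-1 frequencies recomputed
#'   from the haplotypes), `pop_specs` and `seed`.
#' @export
#' @examples
#' p <- build_reference_panel(n_variants = 50, n_haplotypes = 100, seed = 1)
#' tidy(p)
build_reference_panel <- function(pop_specs = population_specs(),
                                  n_variants = 1000,
                                  n_haplotypes = 2000,
                                  region_length = 1e6,
                                  n_founders = max(20, round(n_haplotypes / 12)),
                                  seed = 1L) {
  if (!is.data.frame(pop_specs) || nrow(pop_specs) == 0) {
    stop("pop_specs must be a nonempty data frame", call. = FALSE)
  }
  pop_specs <- population_specs(pop_specs$label, pop_specs$group, pop_specs$fst,
                                pop_specs$fst_within, pop_specs$ld_strength)
  if (n_variants < 2) stop("n_variants must be >= 2", call. = FALSE)
  if (n_haplotypes < 4 || n_haplotypes %% 2 != 0) {
    stop("n_haplotypes must be even and >= 4", call. = FALSE)
  }
  if (region_length < n_variants) {
    stop("region too short for the requested number of variants", call. = FALSE)
  }

  with_seed(seed, {
    positions <- sort(sample.int(region_length, n_variants))
    anc <- stats::runif(n_variants, 0.02, 0.5)

    # Ancestral proxy pairs: adjacent variants that arose on one haplotype
    # background share an ancestral frequency; each continental group retains
    # the pair intact (founder columns identical, r^2 ~ 1) unless its
    # recombination history broke it -- retention rises steeply with
    # ld_strength, so short-LD (African-like) panels keep far fewer proxies.
    dup <- c(FALSE, stats::runif(n_variants - 1) < 0.9)
    for (j in which(dup)) anc[j] <- anc[j - 1]
    groups <- unique(pop_specs$group)
    retain <- lapply(groups, function(g) {
      ld_g <- pop_specs$ld_strength[match(g, pop_specs$group)]
      dup & stats::runif(n_variants) < ld_g^5
    })
    names(retain) <- groups

    draw_pop_freqs <- function(anc) {
      groups <- unique(pop_specs$group)
      gfreq <- lapply(groups, function(g) {
        f <- pop_specs$fst[match(g, pop_specs$group)]
        pmin(pmax(rbeta_bn(anc, f), 1e-6), 1 - 1e-6)
      })
      names(gfreq) <- groups
      out <- lapply(seq_len(nrow(pop_specs)), function(i) {
        pmin(pmax(rbeta_bn(gfreq[[pop_specs$group[i]]], pop_specs$fst_within[i]),
                  1e-6), 1 - 1e-6)
      })
      names(out) <- pop_specs$label
      out
    }

    target <- draw_pop_freqs(anc)
    haps <- lapply(seq_len(nrow(pop_specs)), function(i) {
      sim_haplotypes(n_haplotypes, target[[i]], pop_specs$ld_strength[i],
                     n_founders, dup_cols = retain[[pop_specs$group[i]]])
    })
    names(haps) <- pop_specs$label

    # resample pooled-monomorphic columns, drop stubborn ones
    pooled_poly <- function() {
      tot <- Reduce(`+`, lapply(haps, colSums))
      tot > 0 & tot < n_haplotypes * nrow(pop_specs)
    }
    for (attempt in 1:10) {
      bad <- which(!pooled_poly())
      if (length(bad) == 0) break
      anc_new <- stats::runif(length(bad), 0.02, 0.5)
      tnew <- draw_pop_freqs(anc_new)
      for (i in seq_len(nrow(pop_specs))) {
        haps[[i]][, bad] <- sim_haplotypes(n_haplotypes, tnew[[i]], 0, n_founders)
      }
      anc[bad] <- anc_new
    }
    keep <- pooled_poly()
    if (!all(keep)) {
      positions <- positions[keep]
      anc <- anc[keep]
      haps <- lapply(haps, function(h) h[, keep, drop = FALSE])
    }

    freqs <- lapply(haps, colMeans)
    structure(
      list(positions = positions, ancestral_freqs = anc, haplotypes = haps,
           freqs = freqs, pop_specs = pop_specs,
           n_founders = as.integer(n_founders), seed = as.integer(seed)),
      class = "fm_panel"
    )
  })
}

#' @export
print.fm_panel <- function(x, ...) {
  cat("<fm_panel> ", length(x$positions), " variants, ",
      nrow(x$haplotypes[[1]]), " haplotypes x ", length(x$haplotypes),
      " populations (", paste(names(x$haplotypes), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-variant summary of a haplotype panel
#'
#' @param x an `fm_panel`.
#' @param ... unused.
#' @return a tibble with one row per variant: `variant`, `position`,
#'   `ancestral_freq`, and one `freq_<pop>` column per population (allele-1
#'   frequency recomputed from the haplotypes).
#' @export
tidy.fm_panel <- function(x, ...) {
  out <- tibble::tibble(variant = seq_along(x$positions),
                        position = x$positions,
                        ancestral_freq = x$ancestral_freqs)
  for (pop in names(x$freqs)) out[[paste0("freq_", pop)]] <- x$freqs[[pop]]
  out
}

# stack haplotype matrices for one or more population labels
pooled_haplotypes <- function(panel, pops) {
  miss <- setdiff(pops, names(panel$haplotypes))
  if (length(miss) > 0) {
    stop("unknown population(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(pops) == 1) return(panel$haplotypes[[pops]])
  do.call(rbind, panel$haplotypes[pops])
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Computes r^2 = D^2 / (p_i q_i p_j q_j) from the phased haplotypes of one
#' population, where D is the covariance of the allele indicators at the two
#' sites.
#'
#' @param panel an `fm_panel`.
#' @param pop population label.
#' @param i,j distinct variant indices.
#' @return r^2 in [0, 1].
#' @export
ld_r2 <- function(panel, pop, i, j) {
  if (i == j) stop("i and j must differ", call. = FALSE)
  h <- pooled_haplotypes(panel, pop)
  hap_r2(h[, i], h[, j])
}

hap_r2 <- function(a, b) {
  pa <- mean(a); pb <- mean(b)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) {
    stop("r^2 undefined: variant monomorphic in this population", call. = FALSE)
  }
  d <- mean(a * b) - pa * pb
  (d * d) / (pa * (1 - pa) * pb * (1 - pb))
}

#' Hudson's two-population Fst estimator
#'
#' Ratio-of-averages Hudson estimator from per-variant sample frequencies,
#' with the finite-sample correction in the numerator. Used to verify that
#' generated panels recover the divergence parameter they were built with.
#'
#' @param panel an `fm_panel`.
#' @param pop_a,pop_b population labels.
#' @return a single Fst estimate.
#' @export
fst_hudson <- function(panel, pop_a, pop_b) {
  ha <- pooled_haplotypes(panel, pop_a)
  hb <- pooled_haplotypes(panel, pop_b)
  p1 <- colMeans(ha); p2 <- colMeans(hb)
  n1 <- nrow(ha); n2 <- nrow(hb)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}

# mean adjacent-pair r^2 within a population, skipping monomorphic pairs
mean_adjacent_r2 <- function(panel, pop) {
  h <- pooled_haplotypes(panel, pop)
  p <- colMeans(h)
  m <- ncol(h)
  vals <- vapply(seq_len(m - 1), function(j) {
    if (p[j] <= 0 || p[j] >= 1 || p[j + 1] <= 0 || p[j + 1] >= 1) return(NA_real_)
    hap_r2(h[, j], h[, j + 1])
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}
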