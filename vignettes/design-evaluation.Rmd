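---
title: "Evaluating trans-ethnic meta-analysis designs for fine-mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating trans-ethnic meta-analysis designs for fine-mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finemapsim)
```

## The question and the pipeline

Linkage disequilibrium (LD) helps genome-wide association studies detect loci
— a typed variant correlated with an untyped causal variant still shows
association — but the same correlation prevents fine-mapping from telling the
causal variant apart from its proxies. Populations differ in LD structure:
African-ancestry genomes carry shorter-range LD than European or East Asian
genomes, so a proxy that is indistinguishable from the causal variant in a
European panel may be clearly separable in an African one. This suggests
that, for a fixed total sample size, a meta-analysis spread across diverse
ancestries could localise causal variants better than one drawn from a single
ancestry.

`finemapsim` evaluates that design question by simulation. One replicate runs:

1. **Panel** — a synthetic multi-population haplotype region
   (`build_reference_panel()`).
2. **Cohorts** — six case/control cohorts drawn from the panel under a
   multiplicative per-allele disease model (`sample_cohort()`).
3. **Association** — per-SNP additive logistic regression in each cohort
   (`single_snp_association()`).
4. **Meta-analysis** — fixed-effects inverse-variance pooling, optionally
   DerSimonian–Laird random effects (`fixed_effects_meta()`,
   `random_effects_meta()`).
5. **Fine-mapping** — Wakefield approximate Bayes factors, posterior
   probabilities, and a gated 95% credible set (`build_credible_set()`).

`run_scenario()` replicates this, and `run_pipeline()` organises replicated
scenarios across regions and designs, computing coverage, median set size,
power, and the rank/paired design-comparison tests.

## The synthetic haplotype generator

No real reference haplotypes ship with the package; the generator has to
reproduce the two population-genetic features the design comparison depends
on, and the credible-set machinery is sensitive to a third:

* **Allele-frequency divergence.** Ancestral minor allele frequencies are
  drawn Uniform(0.02, 0.5) — bounded away from 0 so that candidate causal
  variants exist in each MAF class — and diverge by a two-level
  Balding–Nichols hierarchy: ancestral → continental group with `fst`
  (defaults 0.05 EU, 0.06 EA, 0.12 AF), group → population with a small
  `fst_within` (0.004–0.008, mirroring pairs of closely related reference
  panels). African-like populations diverge most, and within-pair divergence
  is an order of magnitude below between-pair divergence.

* **LD extent.** Haplotypes are built by a first-order copying process: each
  population has a finite founder pool (default `n_haplotypes / 12`), and
  every haplotype is a Markov mosaic over founders with switch probability
  `1 - ld_strength` per marker, so copying tracts — hence LD range — grow
  with `ld_strength` (defaults 0.985 for EU/EA, 0.80 for AF). The founder
  pool itself carries latent AR(1) allelic correlation at the same parameter.

* **Near-perfect proxies.** Real panels contain variant groups in almost
  complete LD (r² near 1): alleles that arose on one haplotype background and
  were never separated by recombination. Without them, 95% credible sets
  collapse to a single SNP and their coverage is driven to 1 regardless of
  design. The generator therefore creates *ancestral proxy runs*: adjacent
  variants share an ancestral frequency with probability 0.9, and each
  continental group retains a run link with probability `ld_strength^5`,
  copying retained founder columns from the run head with a per-founder
  breakage probability `1 - ld_strength`. Long-LD populations keep runs of
  several near-identical variants; African-like populations break most links.
  These constants were fixed by inspecting generated panels (proxy counts per
  causal variant, adjacent-pair r², Hudson Fst between population pairs) and
  the resulting credible-set behaviour — European regions yield
  causal-containing sets of a few SNPs while African-only designs localise to
  1–2 — before any benchmark quantities were computed.

What the generator does **not** emulate: recombination hotspot maps or any
specific real locus's LD; shared haplotype backgrounds *across* continental
groups beyond frequency sharing (each group's founder pool is drawn
independently, so cross-ancestry proxies are rarer than in real data — the
trans-ethnic designs' advantage is, if anything, amplified); site frequency
spectra with a realistic rare-variant tail; and pooled within-continent
panels (`EU1+EU2`) share frequencies but not haplotype backgrounds, so the
moderate-diversity design dilutes proxies somewhat more than a real
combined-panel cohort would. Passing tests therefore demonstrate the
pipeline's behaviour under controlled frequency-divergence and LD-extent
contrasts, not quantitative agreement with any particular real locus.

## The disease and association model

A cohort's individuals are formed by drawing two whole haplotypes with
replacement (no within-region recombination, preserving panel LD exactly).
Disease probability is multiplicative per allele, K·rr^g at the cohort's
assigned causal variant, with K set so the population prevalence matches the
configured value; cases and controls are accumulated by rejection sampling to
exact counts (default 1000/1000). MAF classes pair with relative risks:
(5%, 1.4), (10%, 1.3), (20%, 1.2).

**Prevalence** defaults to 0.01. The per-allele odds ratio implied by the
risk model is rr·(1−K)/(1−K·rr); at K = 0.1 this inflates the log-odds by
about 12% over log(rr), which materially shifts power in the
partially-powered heterogeneity scenarios, whereas at K = 0.01 the odds ratio
and the relative risk coincide to under 1% and the estimated effect matches
the analytic power calculations built on log(rr). The rare-disease regime is
therefore the default; prevalence is configurable everywhere it appears.

Association is the additive logistic model of status on dosage, fit by
Newton–Raphson on the 2×3 genotype-by-status count table (the sufficient
statistic), vectorised across variants; estimates agree with
`glm(family = binomial)` to the convergence tolerance. Monomorphic variants
are omitted; separated fits (an allele observed in only one status class) are
omitted with a warning. On fully typed data this Wald test is the standard
single-SNP frequentist association.

## Fine-mapping choices

* ABFs are computed from the *meta-level* estimate and variance, after
  pooling — not per cohort — and in log space, so regions with z² in the
  thousands normalise safely through log-sum-exp.
* Posterior probabilities are normalised over **all** variants present in the
  meta-analysis result.
* The credible set adds variants in decreasing posterior order (ties broken
  by genomic position, ascending, for determinism) until the cumulative mass
  *strictly* exceeds the level: 100 equal posteriors of 0.01 give a
  96-member 95% set. An epsilon of 1e-12 guards the strict comparison
  against floating-point noise in the cumulative sum.
* Sets are built only when the lead SNP's P-value is strictly below the gate
  (default 5×10⁻⁸); gated-off replicates count toward neither coverage nor
  set-size metrics, which is why designs whose lead signals hover near the
  gate report fewer constructed sets and larger coverage standard errors.
* Meta-analysis P-values are computed on the log scale; `p_value` may
  underflow to 0 in linear space for extreme signals, and the `log_p` column
  remains exact for gating and lead-SNP ranking.

## Scenario orchestration and reproducibility

The four designs place six cohorts as: `single_eu` — six from the first
European population; `moderate` — three from the pooled European pair and
three from the pooled East Asian pair; `high` — one from each population;
`single_af` — three from each African population. Heterogeneity modes assign
cohort effects: `allelic` moves East Asian cohorts to a secondary causal
variant c2 (similar MAF, r² < 0.2 with c1 in the reference population);
`locus` makes East Asian and African cohorts entirely null;
`allelic_and_locus` combines the two.

All randomness flows through one splitting scheme (`seed_child()`): scenario
seed → per-replicate seed → per-cohort seed, so any replicate or cohort can
be regenerated in isolation, and identical seeds give bit-identical results.
Panels whose frequency spectrum offers no eligible causal variant are
regenerated with the next derived seed (`find_eligible_panel()`); replicates
whose meta-analysis lacks c1 entirely are likewise regenerated and counted.

For scenarios whose power depends on the causal variant's frequency in the
*null* cohorts (locus heterogeneity), the causal variant can additionally be
required to sit near the target MAF in every population
(`window_pops`/`window_tol`, default tolerance 0.035 when used). Without
that constraint the null cohorts' inverse-variance weights — proportional to
2pq — vary widely, and region-average power drifts upward relative to the
equal-weight analytic approximation.

## Evaluation metrics and comparisons

Coverage is the proportion of *constructed* sets containing the causal
variant (binomial SE); region summaries are unweighted means over regions,
reporting both the mean of region SEs and the empirical SD across regions,
labelled separately, since the exact propagation rule is a reporting choice.
Resolution is the median size of causal-containing sets per region, averaged
over regions. Designs are compared within regions by the tie-corrected
Kruskal–Wallis test (via `stats::kruskal.test`) with Dunn's pairwise z tests
(implemented here from the joint tie-corrected ranking; P-values unadjusted),
and across regions by one-sided paired t-tests of per-region medians, with
the conventional multiplicity-corrected threshold α = 0.011 for the family
of three design comparisons reported alongside.

## Problem sizes

Defaults are 1000 variants per 1 Mb region, 2000 haplotypes per population,
1000 cases/1000 controls per cohort, and 1000 replicates per scenario. The
package's own test and benchmark runs use 500-variant regions with 200–500
replicates per scenario and five regions per estimate: at these sizes the
Monte-Carlo standard error of a power or coverage estimate is below 0.02,
comfortably inside the tolerances being checked, and a full evaluation runs
on a single CPU in minutes.

## Known limitations

* Coverage of the 95% sets on this substrate runs slightly above the nominal
  level for the low-LD (African-only, high-diversity) designs — their panels
  leave the causal variant nearly unambiguous, so almost every constructed
  set contains it. Real-panel analyses report coverage a few points below
  0.95 for every design; reproducing that for the African-only design would
  require denser proxy structure than short-LD panels generate.
* Only single-causal-variant fine-mapping is implemented (no conditional or
  stochastic-search multi-SNP sets) and effects are homogeneous within a
  design except through the discrete heterogeneity modes.
* Genotypes are fully typed; array thinning, imputation and
  information-score filtering are out of scope.
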