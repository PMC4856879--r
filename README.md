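# finemapsim

Simulation tools for a question that matters when planning a genome-wide
association meta-analysis with a fixed genotyping budget: **given six
case/control cohorts, does spreading them across ancestries improve the
fine-mapping of causal variants?** The package simulates multi-population
haplotype panels, runs replicated case/control GWAS under single-ancestry
(European-only or African-only), moderate-diversity (European + East Asian)
and high-diversity (European + East Asian + African) designs, and measures the
resolution of Bayesian fine-mapping under each, with and without allelic or
locus heterogeneity.

## The model

Each cohort contributes, per SNP *j*, an additive logistic association
estimate *B̂<sub>j</sub>* with variance *V<sub>j</sub>*. Cohorts are combined
by inverse-variance meta-analysis with weights *w<sub>i</sub> = 1/V<sub>i</sub>*
(fixed effects), or with DerSimonian–Laird weights
*1/(V<sub>i</sub> + τ²)* (random effects), where
τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw)) and Q is Cochran's statistic.

Fine-mapping converts each pooled estimate to the Wakefield approximate Bayes
factor against the null, with a Normal(0, W) prior on the allelic log-odds
effect (W = 0.04 for case/control additive models):

    ABF = sqrt(V / (V + W)) · exp( z² W / (2 (V + W)) ),   z = B̂ / √V

ABFs are normalised over the region to per-SNP posterior probabilities of
being causal, ranked, and accumulated into a **95% credible set** — the
smallest ranked set whose posterior mass first strictly exceeds 0.95 —
constructed only when the lead SNP's meta-analysis P-value is below 5×10⁻⁸.
The evaluation metrics are the probability that the credible set contains the
true causal variant (coverage), the median size of the causal-containing sets
per region (resolution), and the power to detect the causal variant at
α = 0.05, compared across designs with Kruskal–Wallis/Dunn rank tests and
paired one-sided t-tests on per-region medians.

Synthetic panels give each of six populations (two European-like, two East
Asian-like, two African-like) Balding–Nichols allele-frequency divergence and
a first-order founder-copying haplotype model whose LD extent is shorter in
the African-like populations — the two features the design comparison turns
on. Causal variants are selected at MAF 5, 10 or 20% (±0.5%) in the reference
European population, with per-allele relative risks 1.4, 1.3 and 1.2
respectively, and must be polymorphic in every population; a secondary causal
variant (allelic heterogeneity) has similar MAF but r² < 0.2 with the first.

## A worked example

```r
library(finemapsim)

# a 500-variant region shared by the six default populations, plus a causal
# variant at MAF 5% (RR 1.4) usable by the single-EU design
spec <- scenario_spec(design = "single_eu", maf_class = 0.05,
                      n_reps = 200, seed = 7)
region <- find_eligible_panel(spec, seed = 1, n_variants = 500,
                              n_haplotypes = 2000)

res <- run_scenario(region$panel, spec, region$configs[[1]])
glance(res)
#> # A tibble: 1 × 8
#>   design    heterogeneity maf_class n_reps power_c1 prop_constructed coverage
#>   <chr>     <chr>             <dbl>  <int>    <dbl>            <dbl>    <dbl>
#> 1 single_eu none               0.05    200        1            0.875    0.994
#> # ℹ 1 more variable: median_set_size <dbl>
```

Power to detect the causal variant is 1 (every replicate's meta-analysis
P-value at the causal variant is below 0.05); 87.5% of replicates pass the
5×10⁻⁸ gate and get a credible set; 99.4% of those sets contain the causal
variant; and the median causal-containing set holds 5 SNPs. Running the same
region and causal variant under `design = "single_af"` (three cohorts from
each African population) gives a median set size of 1 — the African-ancestry
design localises the signal to the causal variant itself, the study's
central observation.

A full experiment (several regions × several scenarios, with metric tables,
design-comparison tests and a run manifest) is driven by a YAML or list
configuration:

```r
run_pipeline(list(
  output_dir = "out",
  panel = list(n_regions = 5, n_variants = 500, n_haplotypes = 2000, seed = 1),
  scenarios = list(
    list(design = "single_eu", maf_class = 0.10, n_reps = 200),
    list(design = "high",      maf_class = 0.10, n_reps = 200),
    list(design = "single_af", maf_class = 0.10, n_reps = 200))))
```

A thin command-line front end (`exec/finemapsim`) exposes the stages —
`simulate`, `assoc`, `meta`, `finemap`, `evaluate` — on files (IMPUTE
hap/legend panels, whitespace-delimited per-cohort summary tables, TSV meta
and credible-set records), so the meta-analysis and fine-mapping steps can be
run standalone on summary statistics from any source.

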