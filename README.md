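# aasig

Screening for the aristolochic acid (AA) mutational signature in upper tract
urothelial carcinoma (UTUC).

Dietary exposure to aristolochic acids — mutagens found in several
traditional herbal remedies — drives a large share of UTUC in East Asia and
leaves a distinctive genomic imprint: an excess of A:T>T:A transversions,
catalogued as COSMIC signature 22. Tumours carrying this imprint form an
etiologically distinct subtype with different clinical behaviour, and the
imprint is a *proportion* (the AA-attributed share of all somatic mutations),
so it survives shallow sequencing and can be read noninvasively from urinary
cell-free DNA (cfDNA). `aasig` is for analysts who want to run or study that
screening pipeline end to end.

## What it computes

Given a sample's 96-trinucleotide-context mutation catalog
*m* ∈ ℕ⁹⁶ and a column-stochastic reference signature matrix
*S* ∈ [0,1]⁹⁶ˣᴷ, exposures are fitted by non-negative least squares

&nbsp;&nbsp;&nbsp;&nbsp;*ê* = argmin₍ₑ ≥ ₀₎ ‖*m* − *S e*‖₂ ,

summed over an etiology merge map (AA = signature 22), and the screening
statistic is the AA proportion *ê*₍AA₎ / Σ *ê*. Subtypes are called by
hierarchical clustering of cohort exposures, or per sample by thresholds
(tumour: AA Sig above 50%; cfDNA: AA Sig above 15%, No-AA Sig below 5%,
indeterminate between). Around this core the package provides:

* the post-calling somatic SNV filter (caller intersection, eight read-level
  artifact rules, strict 0.25–0.75 allele-frequency window, population-
  frequency removal at 0.001 with ClinVar/COSMIC rescue) — `filter_variants()`;
* catalog construction from VCF + FASTA with strand collapsing —
  `build_catalog()`, and binomial thinning to emulate low-coverage calling —
  `downsample_catalog()`;
* a hand-rolled Lawson–Hanson NNLS solver — `nnls_fit()` — behind
  `fit_exposures()` / `merge_exposures()` / `aa_proportion()`;
* clinical association tables (chi-square without continuity correction,
  rendered table-one style) and Kaplan–Meier / log-rank survival
  comparisons — `build_table_one()`, `km_estimate()`, `logrank_test()`;
* seed-deterministic generators for every input (`simulate_catalog()`,
  `simulate_variant_records()`, `simulate_variant_vcf()`,
  `simulate_tumor_cfdna_pair()`, `simulate_cohort()`), each returning its
  ground truth;
* a one-call orchestrator with a reproducibility manifest — `run_pipeline()`.

All user-facing functions take a data frame first and return tibbles, so
stages compose with the pipe; fitted objects have `tidy()`/`glance()`
methods and `plot_spectrum()` / `plot_exposures()` / `plot_km()` ggplot
helpers.

The package ships `synthetic_signatures()`, a deterministic synthetic
stand-in for the COSMIC v2 matrix (signature 22 is T>A-dominated); load the
genuine COSMIC file with `read_signature_matrix()` for real data.

## Worked example

A tumour with 60% of its mutations caused by AA, and its matched urinary
cfDNA at 5% mutation recovery:

```r
library(aasig)
sig <- synthetic_signatures()

tumour <- simulate_catalog(20000, c("Signature 22" = 0.6, "Signature 1" = 0.4),
                           sig, seed = 11)
fit <- fit_exposures(tumour, sig)
glance(fit)
#> # A tibble: 1 × 5
#>   sample_id total fitted_total residual_norm reconstruction_cosine
#>   <chr>     <dbl>        <dbl>         <dbl>                 <dbl>
#> 1 sim       20000       20090.          103.                 1.000

aa_proportion(merge_exposures(fit))
#> # A tibble: 1 × 2
#>   sample_id aa_proportion
#>   <chr>             <dbl>
#> 1 sim               0.594
```

The fitted AA proportion (59.4%) recovers the simulated truth (60%) from
multinomial counting noise alone. Thinning to cfDNA scale (~1,000 SNVs)
preserves it, and the screening rule calls the subtype:

```r
pair <- simulate_tumor_cfdna_pair(20000,
                                  c("Signature 22" = 0.6, "Signature 1" = 0.4),
                                  cfdna_fraction = 0.05, signatures = sig,
                                  seed = 12)
sum(pair$cfdna$count)
#> [1] 1016

aa_proportion(merge_exposures(fit_exposures(pair$cfdna, sig))) |>
  classify_threshold(context = "cfdna")
#> # A tibble: 1 × 6
#>   sample_id label  aa_proportion method    threshold_used indeterminate
#>   <chr>     <chr>          <dbl> <chr>              <dbl> <lgl>
#> 1 cfdna     AA Sig         0.551 threshold           0.15 FALSE
```

Clinical characterisation of a simulated 90-patient cohort:

```r
cohort <- simulate_cohort(n_per_group = 45, seed = 13)
head(build_table_one(cohort, covariates = c("female", "aa_intake",
                                            "multifocality")))
#> # A tibble: 6 × 6
#>   variable      level   overall  `AA Sig` `No-AA Sig` p_value
#>   <chr>         <chr>   <chr>    <chr>    <chr>       <chr>
#> 1 female        Absent  23(25.6) 8(17.8)  15(33.3)    "0.091"
#> 2 female        Present 67(74.4) 37(82.2) 30(66.7)    ""
#> 3 aa_intake     Absent  58(64.4) 21(46.7) 37(82.2)    "<0.001"
#> 4 aa_intake     Present 32(35.6) 24(53.3) 8(17.8)     ""
#> 5 multifocality Absent  75(83.3) 33(73.3) 42(93.3)    "0.011"
#> 6 multifocality Present 15(16.7) 12(26.7) 3(6.7)      ""

logrank_test(cohort)
#> # A tibble: 1 × 2
#>   statistic p_value
#>       <dbl>   <dbl>
#> 1      8.08 0.00446
```

Each cell shows `count(within-subtype %)`; the log-rank test compares the
AA Sig and No-AA Sig survival curves (the simulated No-AA group has
three-fold the event hazard).

## Documentation

The methods vignette (`vignettes/aa-signature-screening.Rmd`) describes the
model and its assumptions, the filter rules and their boundary semantics,
what the generators emulate (and what real data adds that they do not), the
default study conditions, and known limitations.
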