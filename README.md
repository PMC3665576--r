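# mutsel

Quantifying evolutionary selection of somatic mutations in tumor cohorts.

Cancer genomes accumulate thousands of somatic mutations, almost all of them
passengers. Mutations that drive tumor growth are *selected* during tumor
evolution, and selection leaves a statistical footprint: many mutations
concentrated in few genes, preferentially at evolutionarily conserved protein
positions, concurrent with other inactivating events in the same genes.
`mutsel` turns that footprint into a tested analysis pipeline for MAF-like
somatic mutation tables:

1. **Functional impact scoring.** Each missense substitution α→β at protein
   position *i* is scored against the residue conservation of its protein
   family and subfamily alignments:

   FIS = −½ [ ln (nᵢ(β)+1)/nᵢ(α) + ln (nᵢₚ(β)+1)/nᵢₚ(α) ]

   where nᵢ(·) counts residue types (20 amino acids + gap) in alignment
   column *i* over the family and nᵢₚ(·) within the query's subfamily *p*
   (natural log; the pseudocount applies to the alternate-residue counts
   only). High FIS = substitution to a residue rarely tolerated at a
   conserved position.

2. **Non-uniformity of mutation distributions.** For per-gene mutation
   counts Nᵢ with shares pᵢ = Nᵢ/M, the Simpson diversity λ = Σ pᵢ², the
   effective number of mutated genes K = 1/λ, and the non-uniformity
   **μ = λ·Q = Q/K** (Q = number of mutated genes). μ ≈ 1 means mutations
   fall evenly across genes (no selection); μ ≫ 1 means a few genes soak up
   most mutations. Selection shows up as μ rising with the FIS threshold.

3. **Concurrency statistics.** Per-FIS-bin fractions of mutations hitting
   annotated cancer genes; gene-level concurrency of high-FIS missense with
   truncating mutations from different tumors; mutation distributions over
   discretized copy-number states with Fisher exact comparisons against the
   silent-mutation control.

4. **Driver nomination.** Genes ranked by high-functional burden (FIS > 2.5
   missense + truncating); the top round(K) genes form the *effective gene
   set* of candidate common drivers; genes with at least as many
   low-functional (FIS < 1) as high-functional mutations are flagged as
   probable passengers; long genes (> 15,000 nt coding) are flagged.

5. **Synthetic cohorts.** A generator that emulates all pipeline inputs —
   family alignments with conserved/subfamily/variable columns, mutation
   tables with planted drivers whose mutations concentrate at conserved
   positions, copy-number matrices with loss-enriched truncating mutations,
   gene lengths — with ground truth, so every stage is testable end to end
   without external data.

Everything is tibble-first: readers return tibbles, statistics accept and
return data frames, results have `autoplot()` methods, and the
`non_uniformity` fit object has `tidy()`/`glance()` methods.

## Worked example

```r
library(mutsel)

co <- gen_cohort(cohort_spec(seed = 42))   # 1000 genes, 10 planted drivers

non_uniformity_profile(co$mutations, fis_bins(thresholds = c(1, 2, 2.5)),
                       gene_groups = "all")
#> # A tibble: 6 × 8
#>   group class      bin        min_fis     q  k_eff    mu     m
#>   <chr> <chr>      <chr>        <dbl> <int>  <dbl> <dbl> <int>
#> 1 all   missense   all         -Inf     855  89.2   9.59  3382
#> 2 all   missense   FIS>1          1     464  19.3  24.1   1118
#> 3 all   missense   FIS>2          2      76   3.14 24.2    379
#> 4 all   missense   FIS>2.5        2.5    73   3.09 23.6    373
#> 5 all   silent     silent        NA     637 440.    1.45  1229
#> 6 all   truncating truncating    NA     128  11.8  10.8    389
```

Silent mutations spread almost evenly across genes (μ = 1.45, close to the
gene-length null below), while missense non-uniformity climbs from 9.6 to
~24 as the FIS threshold rises — the planted selection signal. Truncating
mutations are concentrated too (μ = 10.8), as expected for loss-of-function
drivers.

```r
eff <- effective_gene_set(co$mutations, basis = "fis_tm")
attr(eff, "k_eff")
#> [1] 5.715563
eff$gene
#> [1] "G0004" "G0066" "G0367" "G0284" "G0396" "G0223"
co$drivers
#>  [1] "G0004" "G0066" "G0223" "G0284" "G0367" "G0396" "G0412" "G0813" "G0923" "G0967"
```

The effective number of genes carrying the high-functional mutation burden
is K ≈ 5.7; the six top-ranked genes are all planted drivers (the four
missed drivers are the weakest-intensity ones).

```r
burdens <- rank_gene_burden(co$mutations)
passenger_summary(list(all_genes = burdens$gene, effective = eff$gene), burdens)
#> # A tibble: 2 × 4
#>   set        size n_flagged   pct
#>   <chr>     <int>     <int> <dbl>
#> 1 all_genes   864       831  96.2
#> 2 effective     6         3  50

length_null_non_uniformity(co$lengths)
#> Non-uniformity of mutation distribution
#>   genes mutated        Q  = 1000
#>   total mutations      M  = NA
#>   Simpson diversity    lambda = 0.001456
#>   effective genes      K  = 686.8
#>   non-uniformity       mu = 1.456
```

The passenger flag marks nearly all genes cohort-wide but far fewer inside
the FIS-based effective set, and the length-proportional null confirms that
gene-length variation alone produces only μ ≈ 1.5.

Real data enter through `read_mutation_table()` (configurable MAF dialect),
`read_alignment()` (FASTA/Stockholm) + `build_ensemble()` + `score_table()`,
`read_gene_list()`, `read_cna_matrix()` and `read_gene_lengths()`.
`make_fixture_suite()` writes a miniature bundle of all of these formats.

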