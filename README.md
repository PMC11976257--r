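# methpattern

DNA-methylation subtyping of germinal-center B-cell lymphomas (and similar
cohorts) by consensus fuzzy non-negative-matrix-factorization biclustering.

FL and DLBCL methylomes famously refuse to cluster: ordinary
dimension-reduction of array beta values yields a continuum organized by
overall methylation level. `methpattern` implements the biclustering route
around that problem, for epigenomics analysts working from a normalized
CpG × sample beta matrix:

1. select the most variable CpGs (default: top 10,000 by SD);
2. compress them by k-means to cluster-representative CpGs
   (default: 1,000 clusters → 1,938 representatives);
3. factorize the representatives' beta matrix, *V ≈ WH* with *W, H ≥ 0*,
   by multiplicative updates across a rank sweep and many restarts; turn
   each factor into a fuzzy bicluster (CpGs by loading share, samples by
   within-factor activation) and keep the biclusters that replicate across
   runs (upper-tail hypergeometric match of CpG sets), are tighter than
   random submatrices of equal size (permutation test on the
   parallel-profile coherence), and have consensus support ≥ 0.5;
4. organize the significant CpGs into modules M1..Mk and all samples into
   methylation patterns MP1..MPk by k-means (defaults k = 4 and 7), labels
   ordered by ascending median methylation;
5. embed samples by UMAP (Manhattan distance, 15 neighbors) over the
   significant CpGs, and project external cohorts into that space without
   refitting;
6. compute the downstream statistics: pairwise Wilcoxon rank-sum tests with
   Bonferroni correction, Fisher exact enrichment with Haldane–Anscombe
   odds ratios, epiCMIT mitotic-clock scores
   (max of hyper- and hypo-methylation components), and per-group
   "median [range]" beta summaries.

A synthetic-cohort generator plants module-by-pattern structure, dilutes
each sample toward a bystander (non-tumor) profile according to its
tumor-cell content, and adds Beta-distributed array noise — so every stage
is tested against ground truth. See the methods vignette
(`vignettes/methylation-patterns.Rmd`) for the model, the membership and
coherence definitions, and the generator's scope.

## Worked example

```r
library(methpattern)

sim <- simulate_cohort(n_cpgs = 1000, n_samples = 120, seed = 1)
cfg <- pipeline_config(
  beta = sim$beta, annotation = sim$annotation,
  k_top = 1000, n_clusters = 200, target_reps = 400, master_seed = 1
)
res <- run_pipeline(cfg)
res
#> <meth_pipeline>
#>   representatives: 400
#>   significant: 44 CpGs x 105 samples
#>   modules: M1=13 M2=10 M3=10 M4=11
#>   patterns: MP1=8 MP2=9 MP3=17 MP4=17 MP5=35 MP6=17 MP7=17
```

44 CpGs participate in replicating, coherent biclusters; k-means organizes
them into four modules (M1 the least methylated) and the 120 samples into
seven methylation patterns. Against the planted truth:

```r
mclust::adjustedRandIndex(as.character(res$patterns$pattern),
                          sim$truth$pattern_of_sample[res$patterns$sample_id])
#> [1] 0.7951743
```

Per-pattern methylation over the significant CpGs (the shape of the
published per-MP "median [range]" summaries):

```r
res$stats$summary
#> # A tibble: 7 × 5
#>   group median   min   max     n
#>   <chr>  <dbl> <dbl> <dbl> <int>
#> 1 MP1    0.260 0.226 0.277     8
#> 2 MP2    0.272 0.259 0.309     9
#> 3 MP3    0.378 0.265 0.432    17
#> 4 MP4    0.417 0.336 0.492    17
#> 5 MP5    0.411 0.271 0.477    35
#> 6 MP6    0.459 0.356 0.557    17
#> 7 MP7    0.555 0.478 0.655    17
```

`autoplot(res$embedding, colour = res$patterns$pattern)` draws the UMAP;
`plot_module_heatmap()` draws the module × pattern heatmap. At the default
study scale (5,000 CpGs × 180 samples) recovery is essentially exact — see
below.

A thin CLI over the same functions ships in `inst/cli/methpattern`
(`simulate | reduce | biclust | organize | embed | project | stats | run`).

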