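# introdepth

Tools for deciding whether gene-tree discordance among three closely
related lineages reflects incomplete lineage sorting (ILS) or
post-speciation introgression, plus insertion-age dating of LTR
retrotransposons. The package targets the situation common in rapid
radiations (e.g. closely related plant genera sharing a recent origin):
a concatenation tree confidently resolves the triplet, yet nearly as many
individual gene trees support the conflicting arrangement.

## What it computes

For a focal triplet A, B, C with outgroup O:

* **Alignment QC** — the sliding-window mask: any 15-bp window with more
  than six mismatching columns is masked (gaps to `N`), and any locus with
  more than 20% of columns masked is dropped.
* **Concordance** — each gene tree is classified as `AB|C`, `AC|B`, or
  `BC|A`, stratified by mean bootstrap support (cutoffs 50–90), with the
  internode certainty of the two most prevalent conflicting bipartitions:
  `IC = 1 + p log2 p + q log2 q`, `p = n1/(n1+n2)`.
* **Node-depth test** — per-locus depths under a clock,
  `T1 = d(X,Y)/2` for the cherry pair and `T2 = (d(X,Z)+d(Y,Z))/4` for
  the deep node (Jukes–Cantor-corrected divergences; loci gated by a
  minimum count of biallelic parsimony-informative sites). Because
  introgression replaces one lineage with a recently diverged copy,
  introgressed gene trees are systematically shallower; a seeded bootstrap
  over loci assigns the speciation topology to the deeper class or returns
  "ambiguous" (the expected outcome under pure ILS, where the two minority
  classes are exchangeable).
* **LTR dating** — insertion age of a full-length retrotransposon from the
  divergence `K` of its two terminal repeats, `T = K / (2 mu)` with
  `mu = 1.3e-8` substitutions/site/year by default, plus age-distribution
  histograms by superfamily.
* **Synthetic data** — a multispecies-coalescent simulator for the
  four-taxon history with an optional instantaneous introgression pulse,
  sequence evolution under the equal-rates model, and terminal-repeat
  pairs of known age, all with deterministic per-locus seed streams. Every
  downstream stage is testable against this ground truth.

## Worked example

Simulate 500 loci with a 30% introgression pulse, run the analysis chain,
and date a repeat cohort:

```r
library(introdepth)

cfg  <- sim_config(n_loci = 500, gamma = 0.3, seed = 42)
loci <- simulate_alignments(simulate_gene_trees(cfg), cfg)
loci <- mask_loci(loci)
loci$topology <- loci$topology_truth

summarize_concordance(loci, cutoffs = 50)
#>   cutoff n_retained n_ab_c n_ac_b n_bc_a n_unresolved p_ab_c p_ac_b p_bc_a       ic
#> 1     50        500    200    196    104            0    0.4  0.392  0.208 7.36e-05

test <- compare_depth_classes(estimate_depths(loci), "AB|C", "AC|B",
                              n_boot = 1000, seed = 1)
test
#> <introgression_test> node-depth comparison
#>   AB|C   n=  90  mean T1=0.01795  mean T2=0.03545
#>   AC|B   n= 115  mean T1=0.01023  mean T2=0.03099
#>   diff t1  +0.007718  [0.006023, 0.009314] (95% bootstrap CI, 1000 reps)
#>   diff t2  +0.004453  [0.001524, 0.007147] (95% bootstrap CI, 1000 reps)
#>   diff combined +0.006086  [0.00411, 0.007885] (95% bootstrap CI, 1000 reps)
#>   verdict: species topology AB|C; AC|B attributed to introgression

pairs <- simulate_ltr_pairs(200, true_age_years = 1.5e6, length = 2000, seed = 7)
mean(estimate_insertion_age(pairs, method = "as_is")$t_years)
#> [1] 1489874
```

Reading the output: the two leading topology classes are nearly tied
(40.0% vs 39.2%, internode certainty ≈ 0 — a genuinely contested branch),
yet the `AB|C` gene trees are deeper at both nodes and the bootstrap
interval of the combined depth difference excludes zero, so `AB|C` is
called the speciation topology and the `AC|B` excess is attributed to
introgression — which is exactly how the data were simulated. The repeat
cohort's mean estimated age recovers the true 1.5 Myr within ~1%.

File-based workflows use `read_locus_alignments()`, `read_gene_trees()`,
`read_ltr_pairs()` and the one-call orchestrator
`run_introgression_analysis(pipeline_config(...))`, which writes TSV
tables, a JSON verdict, an exclusion log, and a manifest. `autoplot()`
methods exist for concordance summaries, depth tests, and age
distributions; `tidy()`/`glance()` for the test object.

See the methods vignette (`vignettes/introdepth-methods.Rmd`) for the
model, the verdict rule, parameter defaults and their rationale, and known
limitations.

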