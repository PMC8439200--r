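# synchrometab

Network analysis of targeted-metabolomics dose-response studies: a sham
(healthy) group, a vehicle (diseased, untreated) group, and a ladder of
treatment doses, each profiled over the same metabolite panel. The package
answers three questions about such a design:

1. **How organized is the metabolic network in each group?** Per-group
   soft-thresholded Pearson correlation networks (power chosen by the
   scale-free topology criterion) are summarized by the degree-based
   network structure entropy

   *E* = −Σᵢ *Iᵢ* ln *Iᵢ*,  with node importance *Iᵢ* = *kᵢ* / Σⱼ *kⱼ*,

   which is maximal (ln *N*) for evenly wired networks and low for
   hub-dominated ones. `entropy_recovery()` expresses a dose group's
   entropy as the percentage of the disease-induced entropy change that
   treatment has reversed.

2. **Which direction does each metabolite move?** The two-stage signed
   changes — *v₁* (vehicle vs sham) and *v₂* (dose group vs vehicle), as
   log2 fold changes with an ε zero band — are classified into six
   transformation patterns: PT (− → +), NT (+ → −), PA (0 < *v₁* < *v₂*),
   PR (0 < *v₂* < *v₁*), NA (*v₁* < *v₂* < 0), NR (*v₂* < *v₁* < 0).
   PT/PA/NA form the upregulating Yang family, NT/PR/NR the
   downregulating Yin family. Per-group counts yield separate and overall
   Yin/Yang ratios and differences, plus dose-trend fits of any count.

3. **Which metabolites move together under treatment?** Kendall tau-a
   (concordant minus discordant sample pairs over all pairs, no tie
   correction) between every metabolite pair on a condition's pooled
   samples; edges with |τ| > 0.5, classed synchronous (τ > 0.7) or
   anti-synchronous (τ < −0.7); modules detected with an MCODE
   implementation (core-density vertex weights, seeded greedy expansion,
   haircut); and module dynamics across dose conditions — full-course,
   partial, conservative-allosteric (shared by matched low- and high-dose
   modules), and emerging modules — plus hypergeometric
   over-representation of module nodes against user-supplied GMT pathway
   sets.

A synthetic-study generator (`simulate_study()`) plants pattern labels,
tau-calibrated synchronous modules, and dose trends, so every stage is
tested against recoverable ground truth. See the methods vignette
(`vignettes/dose-response-networks.Rmd`) for the model details and design
decisions.

## Worked example

```r
library(synchrometab)

sim <- simulate_study(sim_config(seed = 1))
study <- sim$study
study
#> <expr_study> 41 metabolites x 60 samples
#> groups: DH1 (n=10), DH2 (n=10), DH3 (n=10), DH4 (n=10), sham (n=10), vehicle (n=10)

# per-group network entropy
nets <- lapply(c("sham", "vehicle", paste0("DH", 1:4)),
               function(g) build_correlation_network(study, g))
sapply(nets, function(n) network_entropy(n)$entropy)
#>  sham vehicle   DH1   DH2   DH3   DH4
#> 3.258   2.906 2.361 2.642 2.762 3.702

# six-pattern classification and Yin/Yang summary
patterns <- classify_patterns(compute_changes(study))
summarize_yinyang(patterns)[, c("group", "n_PT", "n_NT", "yang", "yin")]
#>   group n_PT n_NT yang yin
#> 1   DH1   12    8   19  22
#> 2   DH2   14    6   23  18
#> 3   DH3   16    4   27  14
#> 4   DH4   18    2   31  10

# NT counts fall monotonically with dose
summ <- summarize_yinyang(patterns)
dose_trend(data.frame(group = summ$group, count = summ$n_NT))
#>       r slope intercept dose_axis n_groups degenerate
#> 1    -1    -2        10 rank             4 FALSE

# synchronous modules of the pooled full-course network
sync_modules(study, paste0("DH", 1:4), condition = "DH1-DH4")$modules
#> <module_set> DH1-DH4 2 module(s)
#>   1. score 4.00: M01, M02, M03, M04
#>   2. score 3.00: M06, M07, M08
```

The Yang counts rise and the Yin counts fall with dose (the planted
Yin-to-Yang conversion; the NT trend fits the dose rank with r = −1), the
vehicle state is Yin-dominated (27/41 ≈ 66% of metabolites downregulated),
and the full-course network recovers the planted module M01–M04 exactly,
plus the core of the dose-pair module planted across adjacent conditions.

With three published group entropies the recovery percentage is a one-liner:

```r
entropy_recovery(3.59, 3.51, 3.52)
#> [1] 12.5
```

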