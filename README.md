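# silafkit

Downstream quantification and differential analysis for heavy-lysine
labeled fly proteomes (SILAC/SILAF) and similar two-channel designs.

Metabolic labeling with stable-isotope lysine lets two *Drosophila*
populations — e.g. a mitochondrial-disease knockdown model and its control,
or two diets, or two timepoints of a labeling pulse — be mixed, digested
with Lys-C, and quantified together in one LC-MS/MS run. Each
lysine-containing peptide appears as a heavy/light isotope pair, and the
pair's intensity ratio carries the quantification. `silafkit` implements
everything downstream of the search engine:

* **Table IO** for search-engine-style TSVs (evidence, protein groups,
  phospho-sites with the `"+"`-flag dialect and configurable column maps),
  GMT gene sets, and category annotation maps.
* **In-silico Lys-C/P digestion** with missed cleavages.
* **Incorporation and turnover**: label incorporation rate
  `f = I_H / (I_H + I_L)` per protein and timepoint, and per-protein
  first-order turnover fits `f(t) = 1 − exp(−k t)` with half-lives
  `ln 2 / k`.
* **Ratio quantification**: decoy/contaminant/only-by-site exclusion,
  per-run median-centering of log2 H/L ratios, median aggregation of
  peptides to proteins, technical-replicate averaging.
* **Phosphosite occupancy**: strict localization-probability filtering
  (> 0.75) and protein-normalized occupancy changes
  `Δocc = log2(site H/L) − log2(protein H/L)` per replicate, with
  confound flagging for strongly changed proteins.
* **Moderated statistics** (implemented, not delegated): an
  empirical-Bayes moderated one-sample t-test
  `t̃ = x̄ / sqrt(s̃² / n)` with `s̃² = (d₀s₀² + d s²)/(d₀ + d)`,
  hyperparameters from closed-form digamma/trigamma moment inversion, and
  Benjamini–Hochberg FDR.
* **Enrichment**: hypergeometric overrepresentation analysis and
  permutation-based weighted running-sum GSEA over ranked log2 fold
  changes.
* **A synthetic-experiment generator** with persisted ground truth
  (JSON), so every stage is testable by parameter recovery, plus
  `run_pipeline()` / `score_recovery()` to orchestrate and score a whole
  analysis.

See the vignette (`vignettes/silaf-quantification.Rmd`) for the models,
parameter defaults and design decisions.

## Worked example

Simulate the default synthetic study — 1000 proteins, 4 biological × 2
technical replicates, log2-ratio noise 0.25, a 50-protein OXPHOS-like
category truly down twofold, phosphosites with occupancy shifts — then run
and score the full pipeline:

```r
library(silafkit)

gt  <- make_ground_truth(seed = 42)
sim <- simulate_experiment(gt)
res <- run_pipeline(sim$evidence, sim$protein_groups, sim$sites,
                    annotation_from_ground_truth(gt),
                    gene_sets_from_ground_truth(gt))
res
#> silaf_run (comparison)
#>   mode: comparison
#>   n_protein_groups_input: 1010
#>   n_protein_groups_excluded: 10
#>   n_proteins_quantified: 1000
#>   n_significant_up: 1
#>   n_significant_down: 50
#>   n_sites_detected: 462
#>   n_sites_localized: 373
#>   n_sites_quantified_occupancy: 373
#>   n_sites_significant: 93
```

The 10 injected decoy/contaminant/only-by-site groups are excluded; at
adjusted p < 0.01 the pipeline calls 50 proteins down — the OXPHOS-like
category — and 1 false positive up. GSEA on the protein ranking flags only
that category, with a negative enrichment score:

```r
subset(res$enrichment$gsea, select = -leading_edge)
#>       set_id n_set         es        nes           p       p_adj direction tested
#> 1   Ribosome    50  0.1902651  0.6525362 0.926470588 0.926470588        up   TRUE
#> 2 Glycolysis    40  0.2625597  0.8325411 0.744000000 0.926470588        up   TRUE
#> 3     OXPHOS    50 -1.0000000 -1.7449813 0.001055966 0.005279831      down   TRUE
#> 4 Proteasome    40  0.2839624  0.9577309 0.575000000 0.926470588        up   TRUE
#> 5        TCA    40  0.2666549  0.8476557 0.637096774 0.926470588        up   TRUE
```

Because the generator persists its ground truth, the run can be scored:

```r
score_recovery(res, gt)
#>           metric      value tolerance comparison pass
#> 1     log2fc_mae 0.03244377      0.10         le TRUE
#> 2  empirical_fdr 0.05660377      0.10         le TRUE
#> 3    sensitivity 1.00000000      0.80         ge TRUE
#> 4 sign_agreement 1.00000000      0.95         ge TRUE
#> 5 occupancy_bias 0.01358337      0.05         le TRUE
```

Fold changes are recovered with a mean absolute error of 0.032 log2
units, occupancy changes with bias 0.014, and the knockdown category is
found with full sensitivity at an empirical FDR within the tolerance.
Turnover fitting works the same way on pulse-labeling time courses:

```r
fit_turnover(seq(0, 14, 2), 1 - exp(-0.3 * seq(0, 14, 2)))
#>   k_hat half_life          rss n_timepoints converged
#> 1   0.3  2.310491 5.222157e-18            8      TRUE
```

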