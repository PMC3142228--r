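# mirPIN

Condition-specific activity of miRNA-regulated protein-interaction
subnetworks, for paired tumor/normal expression studies.

## The problem

Tumor-suppressive microRNAs that are lost in cancer de-repress their target
mRNAs, and the encoded proteins act through their physical interaction
partners. Given paired tumor/normal miRNA and mRNA profiles, a protein
interaction network (PIN), and a miRNA→target prediction table, `mirPIN`
asks four questions a systems-biology analyst would ask:

1. **Which miRNAs are down-regulated in tumors, and which genes are
   up-regulated?** — paired two-class *Significance Analysis of
   Microarrays* (SAM): per feature, with pair differences
   `z_k = tumor_k − normal_k`,

   ```
   d = z̄ / (s + s0),   s = sqrt( Σ(z_k − z̄)² / (n(n−1)) ),   fc = 2^z̄
   ```

   against a sign-flip permutation null; a feature is called when
   `|d − d̄_exp|` exceeds `delta` (default 5) at its rank and its fold
   change passes `fc` (default 2), with a permutation FDR.
2. **What subnetwork does each down-regulated miRNA control?** — its
   up-regulated predicted targets present in the PIN (**L0**) plus their
   direct interaction partners (**L1**), with the induced edge set.
3. **Is that subnetwork active in tumor, in normal, in both?** — an edge is
   a *co-expressed PPI* (CePPI) in a condition when its endpoints' profiles
   correlate (default r ≥ 0.5, p ≤ 0.05); a network is *activated* when its
   edges are enriched for CePPIs against the whole-PIN background
   (hypergeometric upper tail, p ≤ 0.05). A robustness stage deletes random
   PIN edges (5–20%) and checks that activation calls survive.
4. **Do the miRNAs work as markers?** — per-miRNA ROC/AUC
   (Mann-Whitney with tie correction), combined z-score panels with accuracy
   at the Youden threshold, Kaplan-Meier curves, log-rank tests, and the
   maximum survival-rate difference **Dmax** between median-split groups.

GO over-representation (hypergeometric, BH-adjusted) with coverage and
term-tree metrics contrasts L0 against L0 ∪ L1 per network.

Because the original clinical and repository data are not shippable, the
package includes a first-class synthetic-study generator
(`simulateStudy()`) with recorded ground truth: 22 tumor/normal pairs, 23
planted down-regulated miRNAs (shift 1.5 log2), 16 planted-activated
subnetworks driven by per-network latent factors, background co-expression,
a toy GO, and exponential survival data. See the methods vignette
(`vignettes/mirpin-methods.Rmd`) for the model and every default.

## Worked example

```r
library(mirPIN)

study <- simulateStudy(generatorConfig(seed = 1))
study$mirna
#> PairedExpression: 62 features x 44 samples ( 22 tumor / 22 normal, 22 pairs )
study$pin
#> InteractionNetwork: 4000 nodes, 11994 edges

res <- runPipeline(study, runConfig(seed = 1, robustness.reps = 100))
#> [diffexpr] 62 miRNAs / 4000 genes; down miRNAs: 17, up genes: 31
#> [netbuild] 8 networks from 17 down-regulated miRNAs
#> [activity] 1 of 8 networks activated in tumor
#> [robustness] mean retention: 1 0.9 0.87 0.83
#> [enrich] 2 networks compared (L0 vs union)
#> [markers] 17 markers evaluated

res$sam_mirna
#> SamResult: 62 features; s0 = 0.1137 ; delta = 5 ; fc >= 2
#>   calls: up 0 / down 17 / unchanged 45 ; est. FDR = 0
```

All 17 down-calls are planted miRNAs (the confusion table in
`res$summary` shows 17 true positives, 0 false positives, 6 misses — the
1.5 log2 shift sits near the delta = 5 boundary, so calls are conservative
but clean). Because ground truth is available, the activity stage also
labels the *planted* networks, isolating the CePPI machinery from upstream
attrition:

```r
head(res$planted_activity[, c("mirna", "n_edges", "k_tumor", "p_tumor",
                              "p_normal", "label")])
#>      mirna n_edges k_tumor  p_tumor p_normal           label
#> 1 miR-S001     116      45 2.93e-18    0.818 activated_tumor
#> 2 miR-S002     240     100 1.25e-42    0.461 activated_tumor
#> 3 miR-S003     118      10 6.34e-01    0.823   inactive_both
#> 4 miR-S004     143      73 1.15e-38    0.618 activated_tumor
#> 5 miR-S005      98      68 1.70e-48    0.417 activated_tumor
#> 6 miR-S006     190       3 1.00e+00    0.523   inactive_both

sum(res$planted_activity$label == "activated_tumor")
#> [1] 16      # the 16 planted-activated networks, recovered exactly
```

`k_tumor` of `n_edges` network interactions are co-expressed in tumor
against a whole-PIN background; `p_tumor`/`p_normal` are the per-condition
enrichment tails. Robustness (100 random removals per fraction):

```r
res$robustness$summary
#>   fraction mean_retention
#> 1     0.05           1.00
#> 2     0.10           0.90
#> 3     0.15           0.87
#> 4     0.20           0.83

res$markers$combined
#>   auc            p accuracy n_markers n_pos n_neg
#> 1   1 1.343993e-08        1        17    22    22
```

The combined 17-miRNA panel separates tumor from normal perfectly on this
synthetic run. `runPipeline(..., outdir = "run1")` writes every stage table
(TSV), GraphML per network, and `summary.json`; identical seeds give
byte-identical summaries. A thin command-line wrapper with `simulate` and
`run-all` subcommands lives at `inst/scripts/mirpin.R`.

## File formats

Tab-separated, UTF-8, `#` comments, no quoting. Expression: matrix TSV
(first column feature id) plus sample metadata (`sample_id`, `condition`,
`pair_id`); PIN: two-column symbol edge list (HPRD style); targets:
`miRNA<TAB>gene`; GO: `gene<TAB>term` annotation plus `child<TAB>parent`
is_a edges (propagated on load, cycles rejected); survival:
`subject`, `time`, `event`, `marker`. Writers and parsers round-trip at
full precision. Gene identity is the upper-cased symbol; missing expression
values are an error, not an imputation.
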