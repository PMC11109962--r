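# notchdyn

Tools for telling **dynamic** (Notch-responsive) from **static** RBPJ
transcription-factor binding sites in replicated ChIP-seq data, and for
predicting responsiveness from binding features alone.

RBPJ sits on its sites whether Notch signalling is on or off; what changes
is the complex built on it. Genome-wide, only a minority of sites lose
occupancy when Notch is blocked with a γ-secretase inhibitor (GSI) — these
dynamic sites are stronger, TSS-distal, enhancer-resident, RBPJ-motif-rich,
and their genes carry the transcriptional Notch response. notchdyn
implements the analysis chain that establishes this, end to end:

1. **Consensus peaks** — replicate peaks grouped by overlap; a site needs
   `k`-of-`n` replicate support (3 of 5 by default) and a Fisher-combined
   p ≤ 1e-6, with single peaks at p ≤ 1e-10 rescuing a group. Combined
   significance is min–max normalized on the −log10 scale.
2. **Binding dynamics** — median-of-ratios normalization, then
   `log2FC = log2((mean_treated + 1)/(mean_control + 1))`; a site is
   dynamic iff log2FC < −0.5 under GSI (or > +0.5 under GSI washout).
3. **Motifs** — canonical `TGGGAA` and degenerate `TGRGAA` RBPJ motifs,
   SP1, and head-to-head RBPJ dimer sites (half-sites on opposite strands,
   15–17 nt apart, ≤ 2 mismatches total).
4. **Annotation & gene association** — positional category (promoter /
   UTRs / gene body / downstream / intergenic), signed TSS distance, and
   GREAT-style basal-plus-extension regulatory domains (5 kb up / 1 kb
   down, ≤ 1 Mb extension).
5. **Responsiveness forest** — a random forest on five features
   (normalized peak p, category, SP1, canonical RBPJ, degenerate RBPJ);
   stratified 85/15 then 80/20 splits; candidates screened at dynamic-class
   TPR > 65% on validation.
6. **Enrichment & enhancer clusters** — strict |log2FC| > 1 & padj < 0.05
   deregulated-gene calls, "both static and dynamic ⇒ dynamic" gene
   classes, hypergeometric enrichment, median splits, and 12.5-kb enhancer
   stitching with a slope-1 rank–signal cut.
7. **Synthetic data** — a seeded generator producing genome, genes,
   replicate peaks, counts and expression with planted truth, so every
   stage is testable without external data.

Everything takes a data frame and returns a tibble, so stages chain with
the pipe; fitted forests have `tidy()`, `glance()`, `predict()` and
`autoplot()` methods.

## Worked example

```r
library(notchdyn)
library(dplyr)

bundle <- simulate_bundle(sim_config(seed = 1, n_chroms = 2,
                                     chrom_length = 600000,
                                     n_genes = 200, n_sites = 400))
pl <- run_pipeline(bundle)   # consensus -> dynamics -> motifs -> annotation -> features

truth_compare(select(pl$dynamics, site_id, label),
              select(pl$consensus, site_id, label = truth_label))
#> # A tibble: 1 × 8
#>      tp    fp    tn    fn   tpr    fpr accuracy   auc
#>   <int> <int> <int> <int> <dbl>  <dbl>    <dbl> <dbl>
#> 1    28    14   345     3 0.903 0.0390    0.956    NA
```

The fold-change rule recovers 28 of the 31 planted dynamic sites that
survived replicate validation (TPR 0.90) while mislabelling 3.9% of
static sites — the planted effect (log2FC −1) sits ~1.6 standard errors
past the −0.5 cutoff at this depth.

```r
sp <- split_data(pl$features, seed = 1)
fit <- train_and_select(sp$train, sp$validation, seed_base = 1)
fit
#> Responsiveness random forest
#>   trees: 500, candidate seed: 1, qualified: TRUE
#>   validation: accuracy 0.879, dynamic TPR 0.857, static TPR 0.881, AUC 0.880
```

The first candidate forest clears the 65% dynamic-TPR selection bound;
`tidy(fit)` shows normalized peak significance and positional category as
the dominant features, matching the biology the classes were defined by.

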