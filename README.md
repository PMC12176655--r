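# liveqibc

Multigenerational single-cell lineage tracking coupled to end-point
multiplexed cytometry, in R.

## The problem

How DNA damage and replication stress propagate through cell generations —
and why two sisters born of the same mitosis can behave so differently — is
invisible to end-point assays alone. The experimental design this package
supports couples three views of the *same* cells:

1. **Live imaging** of an endogenously tagged replication marker
   (PCNA-like; punctate foci mark S phase) and a damage marker (53BP1-like
   nuclear bodies mark inherited lesions, formed in G1 and cleared at S
   entry), acquired every 30 minutes for tens of hours so that lineages of
   up to four generations (P, F1, F2, F3) can be reconstructed.
2. **End-point multiplexed immunofluorescence** (iterative stain/elute
   rounds) of the same field after fixation — DAPI for DNA content, plus
   pRb, γH2AX, p21, p53 — matched cell-by-cell back to the live tracks.
3. **Single-cell RNA-seq** variability: which genes become more
   heterogeneous after genotoxic stress.

`liveqibc` provides the computational layer for this design: lineage-tree
reconstruction from per-frame feature tables, cell-cycle staging from PCNA
foci counts, live-to-endpoint registration with elution QC and DNA-content
gating, sister-cell heterogeneity scoring, endoreplication/rereplication
classification, and a residual-based highly-variable-gene statistic —
together with a fully ground-truthed synthetic-data generator that
exercises every stage.

## The core statistics and rules

* **Tracking** — exact minimum-cost bipartite matching of centroids per
  frame pair (distance-gated, maximum cardinality first), division
  detection by assigning *pairs* of newborn tracks to ending parents via
  the pair midpoint, and binary lineage forests labelled by division
  depth.
* **Staging** — threshold rules on PCNA foci: G1 at 0–4 foci; S entry at
  ≥ 10 foci sustained for ≥ 2 frames; G2 entry at ≤ 4 foci sustained for
  ≥ 2 frames; everything else is a transition period.
* **Routes to polyploidy** — two S segments separated by a low-foci gap
  without division = endoreplication; one continuous over-long S without
  division = rereplication; S segments separated by division = normal.
* **Sister heterogeneity** — |difference| between sisters, categorised
  low/medium/high per marker (e.g. 53BP1 foci: 0–1 low, 2–4 medium, > 4
  high), compared across conditions by chi-square / Fisher tests.
* **HVG detection** — normalise each cell to 10,000 counts
  (`log(1 + 10000·c/total)`), fit `log2(sd) ~ log2(mean)` by OLS across
  genes, call genes with residual > 0.5 highly variable, and test gene-set
  enrichment with a two-sided Fisher exact test (sample odds ratio, Woolf
  CI).

## Worked example

```r
library(liveqibc)

cfg <- sim_config(n_founders = 20, duration = 55, motion_sigma = 3, seed = 1)
cfg
#> Synthetic lineage movie configuration
#>   20 founders, 55 h at 30-min frames (111 frames)
#>   phase means (h): G1=10 S=8 G2=4 M=0.5 (CV 0.15)
#>   PCNA foci lambda: G1=1 S=30 G2=1
#>   fates: normal=1 endoreplication=0 rereplication=0 arrest=0

sim <- simulate_lineages(cfg)          # observation table + ground truth
sim$truth
#> Ground truth: 206 cells, 93 division events, 111 frames

tracks    <- track_cells(sim$obs)
divisions <- detect_divisions(tracks)
forest    <- build_lineages(tracks, divisions)
forest
#> Lineage forest: 20 trees, 206 tracks, 93 division events
#>   generations: F1=40 F2=80 F3=66 P=20

acc <- tracking_accuracy(tracks, divisions, sim$truth)
sprintf("link accuracy %.4f, edge recall %.4f", acc$link_accuracy, acc$edge_recall)
#> "link accuracy 1.0000, edge recall 0.9892"
```

Every frame-to-frame link is correct and 92 of the 93 true
parent–daughter edges are recovered without manual curation; the missed
event is a pair of adjacent sisters dividing almost simultaneously
(`apply_curation()` replays manual fixes for such cases). Staging and
expression variability:

```r
traces <- stage_tracks(forest)          # per-track PCNA phase traces

csim <- simulate_counts(count_sim_config(seed = 1))   # 2000 genes x 500 cells
fit  <- fit_residuals(normalize_counts(csim$counts)$normalized)
fit
#> HVG fit: 2000 genes (2000 evaluable), log2(sd) = -0.939 + 0.382 * log2(mean)
#>   97 highly variable (residual > 0.5)

ev <- fit$genes$evaluable
enrichment_test(fit$genes$hvg[ev], fit$genes$gene[ev] %in% csim$gene_set)
#>      in_set
#> hvg   yes   no
#>   yes  30   67
#>   no   70 1833
#> odds ratio 11.725 (95% CI 7.167-19.183), two-sided exact p = 8.3e-18
```

The generator planted 100 overdispersed genes, 30 of them inside the
designated gene set; the caller recovers 97 and the enrichment test makes
the planted overlap obvious. `run_pipeline(default_run_config(seed), dir)`
chains simulate → track → stage → end-point annotation → sister scoring
and writes all artifacts (CSV/JSON/Newick plus a provenance record); a
thin command-line wrapper lives at `inst/exec/liveqibc`.

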