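---
title: "Models and methods behind liveqibc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind liveqibc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liveqibc)
```

# Scope

`liveqibc` couples three measurement layers of the same cells: (i)
multigenerational live-cell imaging of a PCNA-like replication marker and a
53BP1-like damage marker, (ii) end-point multiplexed (4i-style)
immunofluorescence of cell-cycle and DNA-damage markers on the fixed sample,
and (iii) single-cell RNA-seq variability analysis. This vignette explains
each model, its assumptions, the tunable parameters, and what the synthetic
benchmark does and does not demonstrate.

# The synthetic movie generator

`sim_config()` / `simulate_lineages()` produce per-cell per-frame feature
tables of the kind any high-content segmentation front end emits, plus a
complete ground truth (lineage forest, per-frame phase and DNA content,
division frames, fates, inherited damage counts). The generative model:

* **Acquisition.** Frames every 30 min (default) for 55 h, i.e. 111 frames
  — the cadence and horizon of a multigeneration tracking experiment that
  covers up to three divisions.
* **Cell cycle.** Phase durations are lognormal with means G1 = 10 h,
  S = 8 h, G2 = 4 h, M = 0.5 h and a common coefficient of variation
  (default 0.15). The lognormal guarantees positivity; the means are
  order-of-magnitude values for a transformed human cell line and are fully
  configurable. Founders enter the movie at a uniformly random point of
  their cycle, so the population is asynchronous.
* **PCNA foci.** Poisson per frame with rates
  `λ_G1 = λ_G2 = 1`, `λ_S = 30`. The rates deliberately straddle the
  staging thresholds (4 and 10 foci) with a wide margin: at `λ = 30`, a
  frame below 10 foci has probability ~2e-6, so S phases read as
  uninterrupted high-foci runs unless a treatment multiplier makes them
  erratic.
* **53BP1 bodies.** Drawn once per cell at birth from a Poisson with mean
  `bp1_inherit_mean` (damage inherited through mitosis), held through G1,
  and set to zero from S entry onward when `bp1_clear_at_s` is on. Founders
  that join past G1 carry none.
* **Motion.** An isotropic Gaussian random walk (default σ = 3 px/frame)
  simulated jointly over all live cells with a hard-core exclusion: no two
  nuclear centroids come closer than `min_spacing` (default 40 px,
  enforced by a few push-apart relaxation sweeps per frame). The exclusion
  reflects that nuclei cannot interpenetrate and gives the generator a
  controlled crowding regime. Daughters are placed symmetrically
  (`division_displacement`, default 25 px) about the parent's last
  position, so a division looks like one object being replaced by two
  half-area objects flanking it.
* **Nuclear area.** Grows linearly to double over one reference cycle and
  splits 45–55 % between daughters, with small additive observation noise.
* **Fates.** Per cycle a cell draws normal / endoreplication /
  rereplication / arrest from `fate_probs`. Endoreplication repeats
  G1→S→G2 without mitosis, doubling DNA each round; rereplication extends
  one S phase by a second drawn S duration with no intervening low-foci
  gap, pushing DNA continuously past 4N; arrest is an indefinite G1. These
  generative definitions intentionally mirror the route classifier's
  decision rules so that truth and call are commensurable — a caveat
  spelled out below.
* **Determinism.** All draws run under one seed in a fixed traversal
  order; equal seeds give byte-identical tables.

What the generator does **not** emulate: sub-nuclear PCNA texture
(early/mid/late S morphologies), apoptosis, segmentation artifacts other
than uniform dropout, drift/rotation of the stage, and photobleaching.
Passing the benchmark therefore shows the algorithms are correct under the
stated statistical structure, not that they are robust to every real-world
imaging pathology.

# Tracking and lineage assembly

`track_cells()` links centroids frame to frame with an exact
minimum-cost bipartite assignment (a Jonker–Volgonant-style shortest
augmenting path solver written for this package, run per connected
component of the distance-gated candidate graph). Among maximum-cardinality
matchings it minimises total displacement; ties cannot arise generically,
and component decomposition makes the result order-independent.

Key gates (`link_params()`): `max_displacement` 20 px/frame (≈ 5σ of the
default motion plus the displacement bursts that hard-core exclusion
produces around a division), `max_gap` 1 frame with a proportionally
widened gate and an **area-continuity gate** (0.7–1.4× the last area) so a
lost track cannot swallow a newborn daughter, `division_window` 2 frames,
`division_radius` 40 px, `area_ratio_bounds` (0.35, 0.70).

Two division-specific mechanisms matter:

* **Link breaking.** A frame link whose area ratio falls inside
  `area_ratio_bounds` while an unmatched object appears within
  `division_radius` is interpreted as mitosis: the parent track is closed
  so both daughters register as births. Without this, a parent would
  continue into whichever daughter lands nearest.
* **Pair-midpoint division assignment.** Candidate births are assigned to
  ending parents as *pairs*: the cost of a pair is the distance from the
  parent's end position to the midpoint of the two births (daughters
  separate symmetrically at cytokinesis). An exact search per connected
  component maximises the number of events, then minimises total midpoint
  cost. This resolves the genuinely ambiguous case of two adjacent sisters
  dividing in the same frame, which defeats per-daughter nearest-distance
  rules.

`build_lineages()` turns tracks plus division events into binary forests
with generation labels (P, F1, F2, ...) equal to division depth.
`apply_curation()` replays an ordered edit list (reassign, split, merge,
delete) and stores it for provenance, mirroring the manual curation step
of real tracking pipelines; edits that would give a parent more than two
daughters are rejected.

# Cell-cycle staging from PCNA foci

`call_phases()` implements threshold rules on foci counts: G1 at 0–4 foci;
S entry at the first run of ≥ 2 consecutive frames with ≥ 10 foci; G2
entry at the first subsequent run of ≥ 2 frames with ≤ 4 foci; frames
matching neither rule are "transition". Decisions taken where the rules
are silent:

* A division-born track starts in G1; a track that opens the movie with a
  persistent high-foci run starts in S.
* Sub-persistence excursions stay "transition" rather than being absorbed
  — conservative, and it preserves the transition category as a signal of
  perturbed replication.
* M is assigned only to the division frame itself (mitosis is not staged
  from PCNA).
* When a second S entry follows an S exit within one track (an endocycle),
  the low-foci gap is relabelled G1; ploidy is carried by the DNA-content
  ledger, not by the labels.

`align_lineages_by_phase()` shifts each track so that a chosen anchor
(S entry or division) sits at time zero — the in-silico alignment used to
average damage signals in cell-cycle time.

# Polyploidization-route classification

`classify_ploidy_route()` formalises patterns that were originally read by
eye: two S segments separated by ≥ `min_gap` low-foci frames (default 4
frames = 2 h) without a division → endoreplication; a single S longer than
`max_normal_s_duration`, or S resuming after a shorter gap, without a
division → rereplication; S segments separated by a division → normal; no
S, no division, low foci → arrested; otherwise ambiguous. An end-point DNA
class that is not >4N downgrades a polyploid call to ambiguous.

`max_normal_s_duration` defaults to 12 h. The rationale: the rule only
needs to exclude normal S phases, and a normal 8 h S with CV 0.15 lies
more than three standard deviations below 12 h; moreover a cell that
divides is called "normal" regardless of S duration, so a dividing cell
can never trip the rule. A higher cutoff (e.g. 14 h) buys no additional
specificity but misses a substantial fraction of genuine extended-S
(rereplication) traces whose durations fall near 13–14 h.

Because the generator's fate definitions mirror these rules, the reported
≈ 95–99 % route accuracy measures the pipeline's ability to recover the
patterns through segmentation-level noise (Poisson foci, staging
quantisation, tracking) — it does not validate the biological rule itself
against microscopy, which requires expert-annotated data.

# End-point registration, elution QC, DNA gating

`register_rounds()` assumes translation-only misalignment between the
final live frame and each staining round (same plate, same stage):
mutual-nearest-neighbour pairs vote a coordinate-wise median shift, then
the optimal gated matching (same engine as tracking) assigns cells within
a 15 px residual tolerance. Fewer than 3 mutual pairs flags failure.
Cells washed away during staining appear as unmatched live cells.

`verify_elution()` scores residual fluorescence per cell as
(post − background)/(pre − background); a round passes when the median
residual is at most `max_residual_fraction` (default 0.1). Cells with
background-level pre signal are excluded from the median (a ratio would be
meaningless) and counted; non-eluting outliers are listed.

`gate_dna_content()` finds the G1 (2N) peak as a mode of the DAPI-total
density **on the log scale** — DNA classes sit at multiples of the 2N
value, so log-spacing is uniform and one bandwidth resolves 2N, 4N and 8N
alike. The peak is the *lowest substantial* mode (≥ 25 % of the maximum
height): a polyploid or G2-heavy population can out-peak G1 without moving
the 2N position. Boundaries default to 0.75/1.25/1.75/2.5 × peak for
subG1/G1/S/G2/hyperploid; the factors are configuration, not constants of
nature.

# Sister-cell heterogeneity

`score_pair()` applies the categorical thresholds: a sister difference d
is low when d ≤ low_max, medium when low_max < d ≤ med_max, high
otherwise (bounds closed on the lower category, following the interval
notation "0–1", "2–4"). Two published threshold schemes ship as presets —
`"replication_stress"` (53BP1 (1,4); γH2AX (100,200); p53 (50,100); p21
(100,500)) and `"irradiation"` (53BP1 (1,4); γH2AX (50,100); p53
(200,500); pRb (500,1000)) — and because the cutoffs are
experiment-dependent the scheme is a required argument, never defaulted.
The 53BP1 marker is evaluated on the live-imaging trace of each daughter
(maximum by default; mean and birth value are options since the original
summary statistic is not stated); other markers use end-point values.
`compare_conditions()` tests category-by-condition tables with Pearson's
chi-square (switching to Fisher's exact test when an expected count is
zero) and reports a low-versus-rest 2×2 Fisher collapse for two-condition
designs.

# Highly variable genes

`normalize_counts()` implements the standard log-normalization:
`log(1 + 10000 · count / cell_total)` (natural log; pseudocount and scale
factor configurable). `fit_residuals()` computes per-gene mean and sample
standard deviation (n − 1 denominator — declared, since either convention
is defensible) of the normalized values, fits `log2(sd) ~ log2(mean)` by
ordinary least squares over evaluable genes (positive mean and sd), and
flags genes with residual strictly above 0.5. Genes with zero expression
or zero variance are non-evaluable rather than given −∞ logs.
`enrichment_test()` computes the two-sided Fisher exact p by full
hypergeometric enumeration, and reports the sample odds ratio (ad/bc) with
a Woolf logit 95 % CI (0.5 added to all cells when any is zero, flagged)
— simpler than the conditional MLE and documented as such; the two
estimators differ slightly for extreme tables.

The count generator plants overdispersion multiplicatively
(`dispersion × hvg_dispersion_factor`). Defaults emulate a deeper-coverage
plate-based experiment (gene means lognormal around 20 UMI, CV 1, NB
dispersion 0.5): at shallow droplet-style coverage (< 1 UMI/gene) the
log-transform compresses overdispersion so strongly that a 0.5-residual
cutoff detects almost nothing — a property of the statistic worth knowing
before applying it to sparse data.

# Numerical choices and degenerate inputs

* Assignment ties: costs are continuous; components are solved
  independently, so row order cannot change results.
* `call_phases()` on an empty series is an error; all-constant images
  segment to zero objects without error; an all-identical-expression
  matrix is a degenerate-fit error.
* Division of post/pre elution ratios excludes near-zero denominators
  (threshold 1e-6 of the median pre signal).
* The hard-core relaxation runs 12 sweeps and converges to the target
  spacing within ~0.1 px; it is a soft constraint, not an exact sampler of
  a Gibbs hard-disc process.

# Problem sizes in the test-suite benchmark

The shipped tests run the default 20-founder, 55-hour movie (about 200
cells, 6,000 frame links), two 100-founder single-fate cohorts for route
classification, a 2,000-gene × 500-cell count matrix with 100 planted
variable genes, 10,000 random foci series against the staging oracle, and
1,000 random instances against the exhaustive matching oracle. These sizes
were chosen as the smallest that exercise every code path with stable
statistics.

# Known limitations

* Tracking has no appearance model; it is purely geometric plus the area
  gates. Heavily confluent or fast-moving cells (relative displacement
  comparable to neighbour spacing) will defeat it, as they defeat any
  centroid-gated tracker.
* Touching nuclei are not split (no watershed); merged objects are
  excluded by the size filter and flagged.
* The route classifier sees foci counts only; rereplication that neither
  prolongs S beyond the cutoff nor produces a second S segment is
  indistinguishable from normal S and is called ambiguous.
* The registration model is translation-only; rotation or scale drift
  between rounds would need a richer transform.
* All validation is against the package's own generative model; claims
  about behaviour on real microscopy or sequencing data must be
  established on real data.
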