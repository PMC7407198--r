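# radnet

Radiality network analysis of multiplex cytokine and phosphoprotein tissue
panels.

## What this is for

Chronic inflammation around a failed or infected knee prosthesis involves
dozens of interacting cytokines and phosphoproteins. Given a multiplex
immunoassay panel — 9 cytokines (pg/mL) and 21 phosphoproteins (relative
signal) measured per patient, per anatomical location, per tissue depth —
this package identifies, within each patient-group × depth condition, which
analytes are *central* to the signaling network and which are *peripheral*,
and how that membership shifts between the native surgical response
(primary total knee arthroplasty) and the two revision conditions (aseptic
and septic total knee revision). Peripheral ("low radiality") nodes are the
candidate drivers of dysregulated signaling.

It is written for analysts working with tissue-level multiplex panels who
need the whole chain — QC, normalization, network construction, centrality,
significance calls, cross-network comparison, and the conventional ANOVA /
confounder statistics that accompany it — as tested, reproducible code,
plus a synthetic-cohort generator for validating the pipeline when patient
data cannot be shared.

## The method

Each condition is a complete weighted graph over the 30 analytes. Nodes are
compared through their normalized replicate profiles (one entry per
patient; values scaled to each analyte's global maximum so every analyte
lies in [0, 1]). The edge weight between nodes *u* and *w* is the Euclidean
distance

    E(u, w) = sqrt( sum_i (u_i − w_i)^2 )

and node centrality is radiality: with network diameter ΔG and n nodes,

    Crad(u) = sum_{w ≠ u} ( ΔG + 1 − dist(u, w) ) / (n − 1).

Radiality is normalized to the network mean, and a node is significantly
**low** (peripheral) or **high** (central) when its normalized radiality
falls strictly outside mean ± one standard deviation. On Euclidean
networks every direct edge is a shortest path (triangle inequality), so
dist(·,·) reduces to E(·,·); the package certifies this reduction with an
exhaustive shortest-path oracle rather than assuming it.

Preprocessing follows a fixed order: LLOQ/ULOQ censoring → 1.5×IQR outlier
removal (per analyte × group × depth × location) → location averaging
within depth → per-analyte global maximum normalization. Conventional
statistics (two-way Type II ANOVA with Bonferroni post-tests; Pearson
covariate confounder screen) run alongside.

## Worked example

```r
library(radnet)

cfg <- cohort_config(seed = 101L)      # 6 / 5 / 6 patients, full design
records <- generate_cohort(cfg)        # 17 patients × 7 samples × 30 analytes
res <- analyze_cohort(records)
res$tables[["septic.ATL"]]
```

```
<radiality_table> septic x ATL: 30 nodes, diameter 1.450
  normalized mean 1.000, sd 0.110 (sample), cuts [0.890, 1.110]
  low: p-PTEN, IL-1b, IL-4, IL-6, IL-1a, IL-13, IFN-y
  high:
```

Each table lists, per node, raw radiality, radiality normalized to the
network mean (mean exactly 1), and the low/high/ns call against the
mean ± SD cuts shown. The packaged reference fixtures — the published
normalized-radiality values for the six networks, typed at their printed
two-decimal precision — can be classified with the same rule:

```r
v <- read_radiality_fixture(radnet_fixture_path("ATL"), "primary")
calls <- classify_nodes(v)
names(calls)[calls == "low"]
#> [1] "IL-1b" "IL-6"  "IL-1a" "IL-10"
```

reproducing the published pattern: in the primary-TKA adjacent-layer
network exactly four nodes are peripheral, all cytokines, and none is
central. The `analysis/` directory holds five numbered drivers
(`01_simulate_cohort.R` … `05_compare_networks.R`) that run the whole
workflow on a synthetic cohort and write tables, QC reports, and the
cross-network comparison under `results/`.

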