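---
title: "Radiality networks from multiplex tissue panels: model, pipeline, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiality networks from multiplex tissue panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(radnet)
```

## The problem

Periprosthetic joint infection (PJI) and aseptic implant failure both leave
the tissue around a knee prosthesis in a state of chronic immune
dysregulation. A multiplex immunoassay panel — here 9 cytokines and 21
phosphoproteins, measured in tissue collected at surgery from three patient
groups (primary total knee arthroplasty, aseptic revision, septic revision)
at two debridement depths (the adjacent tissue layer, ATL, and the radial
tissue layer, RTL, about 1 cm deeper) — produces a modest-sized but richly
structured dataset. The question this package operationalizes: within each
group-by-depth condition, which analytes behave as *central* coordinated
members of the signaling network and which sit at its *periphery*, and how
does that membership shift between the native surgical response and the two
failure modes?

## The model

Each condition ("network") is a complete weighted graph over the 30
analytes. For nodes $u$ and $w$ with normalized replicate profiles
$u_1,\dots,u_n$ and $w_1,\dots,w_n$ (one entry per patient in the group),
the edge weight is the Euclidean distance

$$E(u,w) = \sqrt{\sum_{i=1}^{n} (u_i - w_i)^2}.$$

Node centrality is **radiality**: with network diameter
$\Delta G = \max_{u,w} \mathrm{dist}(u,w)$ and $n$ nodes,

$$C_{rad}(u) = \frac{\sum_{w \ne u} \left(\Delta G + 1 - \mathrm{dist}(u,w)\right)}{n - 1}.$$

Radiality is an affine decreasing function of a node's summed distance to
the rest of the network: nodes close to everything score high, peripheral
nodes score low. Radiality values are then divided by their network mean
(so every network is on a common scale with mean exactly 1), and a node is
called significantly **low** or **high** when its normalized radiality
falls strictly below/above the mean minus/plus one standard deviation of
the normalized values.

Radiality is defined through shortest paths, but on these graphs no
computation of shortest paths is ever needed: Euclidean edge weights
satisfy the triangle inequality, so on a complete graph every direct edge
is already a shortest path. Rather than assuming this silently, the
package ships `shortest_path_oracle()`, an exhaustive Floyd–Warshall
relaxation used by the test suite to certify on every random network that
the all-pairs shortest-path matrix equals the direct distance matrix (to
1e-12), and to demonstrate that the oracle itself detects violations on
hand-built non-metric inputs.

The summation convention is pinned explicitly: the sum runs over the
$n-1$ *other* nodes with denominator $n-1$. Including the $w = u$ term
would add the constant $(\Delta G + 1)/(n-1)$ to every node — it would
cancel under mean-normalization but change raw radiality — and a
regression test pins the chosen convention (a 2-node network has
$C_{rad} = 1$ for both nodes; a 3-node configuration with distances
5, 5, 0 yields 3.5, 1.0, 3.5).

## The pipeline

Stage order is fixed and asserted by a regression test, because averaging
and normalization do not commute:

1. **Censoring.** Readings flagged below the LLOQ or above the ULOQ are
   omitted. The generator emits flags rather than dropping records, so
   this stage owns the omission.
2. **Outlier removal.** The 1.5×IQR rule, applied per analyte × group ×
   depth × location across patients — before averaging, the only point
   where a single errant assay reading still exists as such. Quartiles
   use linear interpolation of order statistics (`quantile()` type 7),
   the most common convention; it is test-pinned. Fewer than four values
   per cell: no filtering (quartile fences from 2–3 points are
   meaningless), with a warning.
3. **Depth averaging.** The four ATL locations (three for RTL) are
   averaged per patient and analyte. If every location was removed, the
   entry is missing, not zero.
4. **Maximum normalization.** Every depth-averaged value is divided by
   that analyte's maximum across *all* groups, depths, and patients
   jointly. The six networks are compared on one scale, so the basis must
   be global; per-network maxima would destroy cross-network
   comparability. Ties all map to 1.

The replicates entering the distance computation are **patients** (after
location averaging), not patient × location samples: averaging precedes
network analysis in the pipeline, so depth-averaged patient profiles are
the natural replicate unit. The alternative is available by assembling a
response matrix from unaveraged data, but it is not the default.

**Missing entries.** Aligned replicate indices are required by the
distance sum, and gaps can arise when a patient's analyte is fully
censored at one depth. Two policies are implemented:
`impute_mean` (default) fills a gap with the node's mean over the other
patients; `pairwise_complete` keeps the gap and sums each pairwise
distance over the replicates both nodes share. The default is the less
surprising choice for small cohorts; both are exercised in tests.

**SD convention.** The significance rule defaults to the sample
(n−1) standard deviation, with the population convention available as a
switch. On the packaged reference columns, all in-scope classification
outcomes are identical under both conventions, which is why the default
matters little in practice; it is still explicit and test-pinned.
Values exactly on a cut point are `ns` (strict inequalities), and a
zero-spread network (all values identical) classifies everything `ns`.

## The synthetic cohort generator

No raw patient concentrations are published for this design, so the
generator is the package's test bed. It emulates: the group sizes
(6/5/6), the seven-samples-per-patient layout (PC cannot be collected at
RTL), log-normal positive right-skewed concentrations with group- and
depth-dependent location shifts following the reported qualitative trends
(all cytokines higher in revision than primary and highest in septic,
except IL-10 and IL-12p70 which peak in aseptic; most phosphoproteins
highest in primary, except p-c-Jun and p-BAD peaking in aseptic and
p-PTEN in septic; ATL generally above RTL), sporadic multiplicative
outliers planted beyond the Tukey fence so the IQR filter provably
catches them, and LLOQ/ULOQ censoring emitted as QC flags.

Absolute scales (cytokine baseline 20 pg/mL, phosphoprotein baseline 2
relative units, dispersions sdlog 1.0 and 0.6) are **illustrative**: they
are what a practitioner would call plausible multiplex immunoassay
magnitudes, not estimates from the study. The generator deliberately does
not simulate bead fluorescence, standard curves, plate effects, or
covariate–analyte correlations (the study found none significant).
Consequently, passing tests demonstrate that the pipeline's *mechanics*
are correct and recover planted structure; they cannot validate the
biological conclusions drawn from the real cohort.

`plant_peripheral_node()` displaces one node's readings in one network by
`exp(-shift)`. After global maximum normalization the displaced profile
sits near the origin — far from every other node — so at sufficient shift
it maximizes summed distance and attains the minimum radiality. This
gives the pipeline a parameter-recovery test with a known answer: at
`shift = 8` the planted node is the network minimum and is called low in
100/100 seeded replicates.

## Behaviour of the mean − SD threshold on null data

One property deserves emphasis because it bounds what the classifier can
do. Classification is *scale-free*: node $u$ is called low exactly when
its average distance to the others exceeds the across-node mean plus one
standard deviation of those average distances. Tightening a homogeneous
cluster rescales both sides identically, so the rule always flags the
right tail of its own average-distance distribution. On cohorts of 30
exchangeable noise nodes this typically yields about five low calls per
network at any dispersion — a "clean" null network with zero low calls
essentially never occurs (the only zero-call regime is exactly duplicated
profiles, where the spread is zero and everything is `ns`; that branch is
covered by a unit test). The mean ± SD rule is best read as "the most
peripheral ~16% of nodes", not as a test with a controlled false-positive
rate; cross-group *differences* in membership, not membership itself,
carry the signal. The `null_low_call_experiment()` documents this
empirically and the acceptance suite states the corresponding expectation
honestly rather than engineering around it.

## Conventional statistics

The two-way ANOVA stage uses Type II sums of squares (the design is
unbalanced, 6/5/6, and no sums-of-squares type is canonical for it;
Type II is the standard choice when interactions are secondary), computed
by nested-model comparison and cross-checked in tests against
`car::Anova` to 1e-8. Post-tests are classical Bonferroni multiple
comparisons on cell means with the pooled full-model error: three group
pairs at each depth plus the depth contrast within each group, a family
of nine, explicit in every result object. Depth is treated as a
between-cells factor: without patient-level pairing information a
within-patient coding cannot be verified, and the between coding is the
conservative default.

Null calibration at reduced size (1000 cohorts of 4 patients/group; sizes
chosen to keep the experiment comfortably inside a test run) gives a
family-wise flag rate of ≈ 3.6–4.0% — at or just under the nominal 5%,
as Bonferroni with correlated contrasts should be. A caveat discovered
during calibration: interposing the per-cell 1.5×IQR filter *before* the
ANOVA inflates the null flag rate several-fold (to 11–18% here) on
log-normal data with small per-cell samples, because trimming each cell
by its own sample fences distorts the variance and dependence structure
of what remains. The filter is kept exactly where the method places it in
the main pipeline, but the calibration experiment exposes the effect
(`anova_null_calibration(iqr_filter = TRUE)`) instead of hiding it; it is
a real limitation of case-by-case outlier removal feeding small-sample
ANOVA.

The Pearson confounder screen correlates age, sex (0/1 indicator, i.e.
point-biserial), and BMI with each analyte's per-patient response,
Bonferroni-corrected over the 90-pair family. Synthetic covariates are
generated independently of the analytes, and at the study's size the
screen reports zero significant pairs in ≈ 95% of null cohorts.

## Reference fixtures and their limits

The package ships the published normalized-radiality values of all six
networks as two-decimal CSV fixtures. Re-applying the mean ± SD rule to
these printed columns reproduces the published significance pattern for
five of the six networks under either SD convention; each column sums to
30.0 ± 0.1 (mean 1 over 30 nodes, up to printing precision). The
RTL-primary column is the documented exception: it prints three nodes at
1.11 of which only two are marked significant, so the underlying
unrounded values must straddle the cut in a way two-decimal values cannot
resolve. That column's high-side calls are therefore excluded from exact
reproduction, and no convention was tuned to force agreement. The
fixtures also cannot support re-deriving raw radiality or the distance
matrices — the patient-level data behind them are unpublished.

## Problem sizes used by the packaged experiments

Test and acceptance runs use: 100 random 30-node networks for the oracle
equivalences; 100 seeded replicates for planted-node recovery and the
null low-call census (6 patients/group); 1000 null cohorts of 4
patients/group for ANOVA calibration; 100 null cohorts at the study size
for the confounder screen. These sizes make the Monte Carlo error small
relative to every asserted margin while keeping a full run in minutes.
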