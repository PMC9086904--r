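---
title: "Single-subject gray-matter morphological networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject gray-matter morphological networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

morphnet builds, for each subject, a *morphological* brain network: nodes
are atlas regions (116 AAL regions by default), and the edge between two
regions quantifies how similar their voxel-wise gray-matter volume (GMV)
distributions are. For region $i$ with voxel values $x_{i1},\dots,x_{in_i}$
we estimate a probability density $p_i$ by Gaussian kernel density
estimation, discretize it on a shared value grid, and connect regions by the
Kullback–Leibler–based similarity

$$\mathrm{KLS}(p, q) = \exp\{-[D_{KL}(p\|q) + D_{KL}(q\|p)]\},$$

which is exactly 1 for identical distributions and decays toward 0 as they
diverge. The result is a symmetric $116\times116$ matrix per subject with
zero diagonal and entries in $(0, 1]$.

Each weighted matrix is binarized over a *sparsity* sweep: at sparsity $S$
the $\mathrm{round}(S\,N(N-1)/2)$ strongest edges are kept. Following the
convention in graph-theoretic studies of structural covariance, metrics are
computed at every $S \in \{0.10, 0.11, \dots, 0.35\}$ and summarized by the
trapezoidal area under the metric-vs-sparsity curve (AUC), so that no single
arbitrary threshold drives inference.

Per threshold we compute the clustering coefficient $C_p$ (mean
Watts–Strogatz local clustering, degree $<2$ contributing 0), characteristic
path length $L_p$ (mean shortest path over connected ordered pairs), global
and local efficiency $E_{glob}, E_{loc}$, and nodal degree, betweenness and
efficiency. Small-world indices normalize against degree-preserving
Maslov–Sneppen rewired graphs: $\gamma = C_p/\bar C_p^{null}$,
$\lambda = L_p/\bar L_p^{null}$, $\sigma = \gamma/\lambda$; $\sigma > 1$
indicates small-world organization.

Group inference is nonparametric: one-way ANOVA $F$ (omnibus) and pooled
$t$ (post-hoc) statistics on AUC values, with label-permutation p-values
using the add-one convention
$p = (1 + \#\{|s^{perm}| \ge |s^{obs}|\})/(1 + n_{perm})$ and
Benjamini–Hochberg FDR within each nodal metric family. Edge-level group
differences use network-based statistics (NBS): edges with $F > 4.64$
(omnibus) or $|t| > 2.64$ (signed contrasts) are kept, connected components
are scored by edge count, and each observed component is compared with the
permutation null of the *maximal* component size. Clinical associations use
partial correlations with age, sex, education, HAMA and HAMD as covariates,
testing $t = r\sqrt{(n-k-2)/(1-r^2)}$ on $n-k-2$ degrees of freedom.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| grid points | 512 | KDE discretization per region pair; convergence-checkable |
| bandwidth | Silverman (`bw.nrd0`) | per-vector kernel width |
| density floor | 1e-12 | avoids `log(0)`; renormalized afterwards |
| sparsity range | 0.10–0.35 step 0.01 | 26 binarization levels |
| nulls | 100 | rewired graphs per threshold for γ, λ, σ |
| swaps per edge | 10 | Maslov–Sneppen rewiring effort |
| permutations | 10,000 | group and NBS label permutations |
| FDR level | 0.05 | BH within each nodal metric family |
| NBS thresholds | F = 4.64, \|t\| = 2.64 | edge-level cutoffs, taken as opaque configuration |

The KDE grid spans the pooled sample range of each pair padded by three
bandwidths. Divergences are computed on discrete grid masses (not
trapezoid-integrated densities): masses are exactly normalized, floored and
renormalized, which makes self-similarity exactly 1 and keeps every
logarithm finite. The upstream literature this construction follows does
not pin down grid size, bandwidth rule or the KL symmetrization, so all
three are explicit configuration here rather than claims about any
particular study's settings.

## What the synthetic cohort emulates

No imaging data ship with the package. The generator produces the
statistical structure the analysis assumes, for three groups mirroring a
tremor/sleep study design: essential tremor with poor sleep (SleET,
n = 45), with normal sleep (NorET, n = 59), and healthy controls (HC,
n = 66).

* **Voxel values** per region are two-component Gaussian mixtures — smooth,
  unimodal-to-bimodal densities like smoothed GMV maps. Component means
  load on shared latent factors (4 by default) plus a region-specific
  baseline, so regions close in latent space have similar distributions in
  every subject; thresholded KLS networks therefore inherit community
  structure and, empirically, σ > 1 across the whole sparsity range (this
  is enforced by an acceptance test, not assumed).
* **The planted global effect** (default 0.6, SleET) shrinks the shared
  geometry and inflates region noise for that group, so its thresholded
  networks become more random: higher global efficiency and lower path
  length at fixed sparsity. This mirrors the qualitative "shift toward
  randomization" finding that motivates the pipeline; the magnitude is a
  free parameter, not an estimate from any real data.
* **Planted edges** pull a region pair's mixture parameters together
  (raising that edge's KLS) within one group, giving NBS something
  recoverable.
* **Clinical scores** are drawn per group from the published demographic
  table's means and SDs, rounded and clipped to instrument ranges (PSQI
  0–21, MMSE 0–30, …). PSQI is clipped to the side consistent with the
  subject's sleep group and MMSE/HAMA/HAMD to the inclusion region — the
  generator emulates a *post-screening* sample, which is why every
  generated subject passes the eligibility rules.
* **The degree–TRS correlation** (default ρ = −0.35 in SleET, left
  thalamus) rewrites the tremor score as a linear function of the
  subject's *expected* target-region degree — computed analytically from
  the mixture moments via a Gaussian-approximation KLS at sparsity 0.2 —
  plus calibrated noise. Using the analytic degree keeps planting cheap
  and exact; the recovery tests correlate against the same analytic degree,
  so they validate the statistical machinery, not the KDE pipeline.

What the generator does **not** emulate: anatomy, spatial smoothness,
scanner noise, registration or segmentation error, age/sex effects on
brain structure, or realistic effect sizes (the study reports none that
could calibrate them). A green test therefore establishes that the
pipeline's statistics behave correctly on data with the assumed structure —
not that the package reproduces the study's empirical tables, which would
require the original MRI.

## Numerical and design choices

* **Binary graphs after thresholding.** The small-world framework and the
  toolkit workflow this follows operate on binarized networks; weighted
  variants are out of scope.
* **Ties at the sparsity cutoff** break deterministically (descending
  weight, then ascending row/column index), so thresholding is a pure
  function.
* **Disconnected graphs** can occur at low sparsity: $L_p$ averages over
  connected pairs only and the panel carries a per-threshold
  disconnectedness flag, rather than dropping subjects (which would bias
  AUC).
* **Null models**: 100 rewired graphs per threshold, 10 swap attempts per
  edge, seeded per (subject, threshold) from the global seed by stable
  string hashing — results are independent of evaluation order. Graphs
  whose degree sequence admits no swap (e.g. complete graphs) keep
  themselves as nulls and are flagged; γ = λ = σ = 1 there.
* **Permutation p-values** use the add-one convention, never 0, with the
  identity arrangement counted when enumerating exhaustively. Pairwise
  null draws are canonicalized (sorted pooled values, smaller group
  first) so the two-sided p is exactly invariant to swapping the samples.
* **Degenerate sweeps**: if a very sparse graph's rewired nulls have zero
  mean clustering, the normalized metrics are undefined at that threshold
  and their AUC is reported as `NA` rather than an error; group tests
  flag `NA` metrics instead of failing.
* **FDR families**: degree, betweenness and efficiency are corrected
  separately across the 116 regions (the common per-measure convention);
  global metrics form one family. Config-exposed.
* **Betweenness** is reported as raw geodesic pair counts (undirected
  convention); a flag enables pair-count normalization. Group inference is
  invariant to the common scale.
* **Compiled kernels**: clustering, path length, efficiency and rewiring
  are implemented in C++ because a single cohort sweep evaluates ~50,000
  null graphs; equality with an independent Floyd–Warshall/triangle-count
  oracle (and with igraph) is part of the test suite.
* **Seeding**: one global seed expands into per-subject and per-stage
  substreams via a stable polynomial hash, so cohorts are byte-identical
  across runs and subjects are reproducible independently of cohort order.
* **YAML vs JSON**: the pipeline configuration round-trips through JSON
  (jsonlite); no YAML parser is among the package's allowed dependencies.

## Scale-downs in the test suite

The full design (170 subjects × 116 regions, 10,000 permutations) fits the
method but not a CI budget. The suite therefore runs the documented
scale-downs: 20 subjects / 100 nulls for the small-world acceptance check;
reduced cohorts (36 regions, 6 vs 6 subjects) for the planted
global-effect recovery; n_perm = 499 with 200 replicates for type-I
calibration of the permutation ANOVA and NBS family-wise error; and the
analytic expected degree in place of full network rebuilds for the 100-seed
correlation recovery. Each scaled test checks a property that is
scale-free by construction (direction of a planted effect, nominal error
rate, exact identities), not a magnitude that depends on the full size.

## Known limitations

* KLS depends on KDE settings; with very few voxels per region (< ~50) the
  similarity estimates get noisy and the small-world guarantee of the
  generator weakens.
* The NBS edge thresholds F = 4.64 and |t| = 2.64 are used as opaque
  defaults; they are not recomputed from degrees of freedom.
* Permutation tests are unadjusted for covariates by design; covariate
  adjustment happens only in the partial-correlation stage.
* The NIfTI reader handles the common single-file NIfTI-1 cases only (no
  extensions, no .hdr/.img pairs, no NIfTI-2).
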