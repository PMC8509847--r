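---
title: "Frequency-resolved brain network analysis with fbandnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-resolved brain network analysis with fbandnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbandnet)
```

## The analysis

`fbandnet` implements a paired pre/post analysis of resting-state functional
brain networks resolved by frequency band. The pipeline is:

1. **Band decomposition.** Each region's BOLD time series (by default 76
   Desikan–Killiany regions, 180 volumes at TR = 2 s) is split into four
   detail bands with an undecimated ("stationary") discrete wavelet
   transform using the Daubechies-4 wavelet. With Nyquist frequency
   $f_N = 1/(2\,\mathrm{TR})$, detail level $j$ covers
   $(f_N/2^{j},\, f_N/2^{j-1})$ Hz — at TR = 2 s the bands are
   0.125–0.25, 0.0625–0.125, 0.03125–0.0625 and 0.015625–0.03125 Hz.
2. **Connectivity.** Per band, session and subject, Pearson correlation
   between every pair of region band series gives a symmetric
   unit-diagonal matrix; for 76 regions, 2850 unique connections. No
   Fisher transform is applied anywhere: thresholding and group
   comparisons operate on raw $r$.
3. **Topology.** Proportional thresholding retains the strongest positive
   connections at each density of a uniform grid (default 10–50% in 1%
   steps). On each binary graph the package computes nodal clustering
   $C_i$, local efficiency $E_i$, degree $k_i$, strength, normalized
   betweenness, participation coefficient
   $y_i = 1 - \sum_m (k_i^{(m)}/k_i)^2$ and within-module degree z-score;
   and the global measures $C_{net}$ (mean clustering), the harmonic
   characteristic path length
   $L_{net} = n(n-1)/\sum_{i \neq j} d_{ij}^{-1}$, global efficiency, and
   smallworldness $\sigma = (C_{net}/C_{rand})/(L_{net}/L_{rand})$, with
   $C_{rand}, L_{rand}$ averaged over degree-preserving rewired reference
   graphs. Each measure is summarized across the density grid by its AUC,
   which on a uniform grid is simply the mean across densities.
4. **Inference.** Pre-to-post changes in every connection and every
   nodal-metric AUC are tested with a paired sign-permutation test,
   accompanied by Cohen's d (pooled SD) and the power of the two-sided
   one-sample t-test at $\alpha = 0.05$. Multiplicity is handled per
   family (76 regions, 2850 connections) with Bonferroni thresholds, and
   per band a subnetwork of significantly changed connections is selected
   by Benjamini–Hochberg FDR at 5%, summarized by within-subnetwork nodal
   degree.
5. **Clinical association.** Exploratory OLS regressions of clinical
   change on network features, with age/sex/IQ partialed out (the
   Frisch–Waugh identity is asserted in the tests). No multiple-testing
   correction is applied to these, and they are labeled exploratory.

## The wavelet implementation

No wavelet library is available to R in this toolchain, and the band
decomposition is the analytic core, so it is implemented in the package.
Under periodic (circular) boundary handling the undecimated transform with
per-level reconstruction is a bank of *zero-phase* linear filters: the
decompose-then-reconstruct chain for detail level $j$ has the real,
non-negative transfer function

$$R_j(\omega) = 2^{-j}\,|G(2^{j-1}\omega)|^2 \prod_{k<j} |H(2^{k-1}\omega)|^2,$$

with $H, G$ the db4 low/high-pass pair ($|H|^2 + |G|^2 = 2$), and the
approximation takes the complementary product. The rows sum to 1 at every
frequency, so the four details plus the approximation reconstruct the input
exactly, and each band output is a circular convolution — which makes the
transform *exactly* shift-equivariant, a property the tests assert at
1e-10. The same construction evaluated per-level against an independent
PyWavelets swt/iswt computation agrees at machine precision; a frozen
fixture from that oracle is kept in the test suite.

Boundary handling is a config option. `periodic` is the default because it
makes shift equivariance exact and testable; `symmetric` reflect-pads the
series (implemented by running the periodic transform on the
series-plus-mirror and truncating), which reduces wrap-around at the ends
at the cost of exact equivariance. Volumes flagged by motion scrubbing are
*not* removed before filtering — the transform needs a contiguous series —
but are excluded pairwise at the correlation step.

## The synthetic cohort generator

No public data accompany the study design this package targets, so the
generator is a first-class module: it emulates a paired cohort of 12
subjects with band-limited, cross-correlated Gaussian signals and planted
post-treatment connectivity changes.

Each band source is white Gaussian noise shaped by the *same* band filter
$R_j$ the analysis applies, so planted structure lives exactly in the
analyzed bands; cross-regional structure is imposed with an eigenvalue
square-root factor of a per-band source correlation matrix, and broadband
measurement noise is added on top. Because the dyadic band filters overlap,
the analyzed band-$b$ correlation of such a sum is a known linear mixture
of the per-band source correlations,

$$\tilde\rho_b = \frac{\sum_{b'} v_{bb'}\, \rho_{b'}}{\sum_{b'} v_{bb'} + \sigma^2 e_b},
\qquad v_{bb'} = \frac{\overline{R_b^2 R_{b'}^2}}{\overline{R_{b'}^2}},$$

with $e_b$ the band filter energy and $\sigma$ the noise SD. The generator
*inverts this mixing*, solving for source correlations such that the
analyzed correlations converge to the requested ground truth as the series
grows — the own-band mixing weight is only ≈0.84–0.97, so without the
inversion a planted $r = 0.6$ would be measured near 0.5. Requested values
whose compensated source matrices leave the correlation cone are rejected
with a diagnostic naming the offending edge (for planted effects) or
projected to the nearest correlation matrix with a warning (for baseline
templates).

Defaults are the study's conditions where stated (12 subjects, 76 regions,
180 volumes, TR = 2 s) and the package's own choices where nothing is
stated: a 4-module template with within-module $r = 0.5$ and between-module
$r = 0.1$, and broadband noise SD 0.3 relative to unit-variance band
sources. The noise level is a deliberate choice: the band filters attenuate
a once-filtered signal twice as hard as flat noise, so noise at SD 1 would
contribute 1.1–1.9× the own-band signal energy inside each analyzed band
and make ordinary planted correlations (e.g. 0.6) infeasible after
compensation; 0.3 keeps planted values up to ≈0.8 feasible while still
exercising noise robustness. What the generator does *not* emulate:
hemodynamic autocorrelation beyond the band shaping, between-subject
variability in connectivity (sessions are independent draws), scanner
drift, or any voxel-level artifact. Passing tests therefore demonstrate
the *pipeline's* statistical behavior under its stated model, not
robustness to real fMRI noise structure.

Planted effects are specified per edge, band and delta. A practical
constraint discovered in development: many simultaneous ±0.4 deltas placed
arbitrarily on a modular template break positive semidefiniteness. Planting
a *matching* (disjoint node pairs) bounds the perturbation's spectral norm
by $|\Delta|$ and is guaranteed safe; the calibration suite plants its 30
effects this way.

## The permutation test and its calibration

The paired test enumerates all $2^n$ sign assignments whenever that count
fits the realization budget — at $n = 12$, always: 4096 assignments, exact
p-values on the grid $k \cdot 2^{-12}$, minimum $2^{-12} = 0.0002441$. The
observed assignment is part of the null set, so p is never 0. Sampling mode
(seeded, blockwise) is retained for cohorts beyond ~20 subjects.

The tail is taken *in the direction of the observed difference*: for
$D > 0$, $p = \Pr(D' \ge D)$. This convention is what produces the
$2^{-12}$ floor and p-values that cap near 0.5, but it has a known
statistical cost: choosing the tail after seeing the sign doubles the null
exceedance rate, so $\Pr(p < 0.05) \approx 0.10$ under the null, and the
Benjamini–Hochberg step applied to such p-values controls FDR at roughly
twice its nominal level. The calibration suite measures exactly this
(the nominal-rate assertions fail, and say so in a comment), and the
null distribution of the directional p — uniform on the achievable
half-grid $\{1, \dots, 2^{11}\}/2^{12}$ — is what the uniformity test
checks against. Users who want nominal calibration should halve $\alpha$
or, equivalently, double the reported p-values.

## Numerical and design choices

* **Thresholding ties.** At each density the target count is
  `round(density * 2850)` (half away from zero); weights strictly above
  the cutoff are kept, and ties at the cutoff are admitted in
  lexicographic (i, j) order until the count is reached. This makes edge
  sets deterministic and nested along the grid (asserted).
* **Negative weights** are never thresholded into a graph; strength is
  the only weighted quantity and all path/clustering/community measures
  force binary treatment of edges.
* **Random references**: 100 rewired graphs with 10·|E| attempted
  degree-preserving double-edge swaps each, seeded. Graphs with no valid
  swap (complete graphs) return their own metrics, giving
  $\sigma = 1$.
* **Community detection**: greedy modularity maximization, which is
  deterministic; the trivial single-module partition is substituted when
  greedy merging stops at a partition with $Q \le 0$ (e.g., complete
  graphs). The partition is computed once per graph and shared by the
  participation coefficient and the within-module z-score, whose SD is
  the population (divide-by-$n_m$) convention; zero-spread and singleton
  modules yield $z = 0$.
* **Zero-variance regions** correlate at 0 (with a warning) rather than
  NA, so thresholding stays total; a 0 never enters a positive-weight
  graph.
* **Scrubbing** follows the FD > 0.5 / DVARS > 8 rule with the offender,
  one volume before and two after excluded; windows union and truncate
  at the series ends.

## Problem sizes in the test suite

The suite exercises the full 76-region, 12-subject geometry wherever the
claim depends on it (exact permutation grids, 2850-edge batteries, FDR
subnetwork recovery at 2000 volumes over 20 replicate cohorts) and smaller
cohorts (5–12 regions, 64–512 volumes) for contracts where dimension is
irrelevant. Oracle equivalence of every graph metric is checked against
independent brute-force implementations (Floyd–Warshall distances,
adjacency-power path counting, triangle counting) on 200 random graphs
with up to 12 nodes at 1e-10.

## Known limitations

* The directional permutation p-value is anti-conservative at the nominal
  level, as discussed above; the package reports it for fidelity to the
  analysis it implements and documents the doubling correction.
* Densities low enough to fragment a graph are handled through harmonic
  (efficiency-style) path lengths, but normalized metrics can be noisy
  there; the 10–50% default grid avoids the extreme regime.
* The generator's leakage inversion is exact in population only for the
  periodic-boundary analysis on series of the same length it was solved
  for; symmetric-boundary analyses of generated cohorts will show small
  systematic offsets at the series ends.
* NIfTI ingestion is out of scope; the package consumes region-by-volume
  tables (TSV) and a JSON manifest.
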