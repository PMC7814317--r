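---
title: "Fitting and comparing degree-distribution models in voxel-level functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting and comparing degree-distribution models in voxel-level functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weibullnet)
```

## The scientific question

The degree distribution — the probability distribution of the number of
connections per node — is one of the most informative summaries of a brain
network's topology. For resting-state functional networks built at the voxel
level there is long-standing disagreement over whether that distribution is
heavy-tailed (a power law, as preferential-attachment growth would predict)
or short-tailed (a power law with exponential cutoff, or a Weibull /
stretched-exponential law, as wiring-cost constraints would predict). The
question has clinical teeth: if the distribution's shape changes in amnestic
mild cognitive impairment (aMCI), the prodromal stage of Alzheimer's disease,
the shape parameter becomes a candidate marker of network-level degeneration
and a correlate of cognitive decline.

`weibullnet` implements the full analysis chain for this question:

1. **Graph construction** (`correlation_matrix()`,
   `apply_distance_exclusion()`, `compute_degrees()`, `subnetwork_degrees()`,
   `compute_fcs()`): Pearson correlations between all voxel pairs inside a
   grey-matter mask, a 20-mm exclusion of short-range connections, and
   binarization at a correlation threshold `T`.
2. **Model fitting and comparison** (`fit_discrete_mle()`,
   `fit_powerlaw_discrete()`, `select_xmin_ks()`, `compare_models()`,
   `fit_all_subjects()`, `group_mean_R()`): discrete maximum likelihood for
   the three candidate models and a Vuong-style normalized loglikelihood
   ratio between them.
3. **Group statistics** (`glm_group_difference()`, `glm_cognition()`,
   `interaction_model()`, `bh_fdr()`, `fcs_group_map()`,
   `demographics_table()`): covariate-adjusted GLMs on the fitted shape
   parameter, FDR-corrected across networks, plus voxelwise group maps of
   functional connectivity strength.
4. **Synthetic cohorts** (`generate_cohort()`, `generate_timeseries()`, the
   `sample_discrete_*()` samplers): ground-truth data so that every stage is
   testable and its error rates measurable without access to imaging data.

## The candidate models and their discretization

Degrees are non-negative integers, so all three candidate densities are
handled in discrete form on the support `k >= xmin`:

| model | continuous density (up to a constant) | discrete form |
|---|---|---|
| power law | \(x^{-\alpha}\) | \(P(k) = k^{-\alpha} / \zeta(\alpha, x_{min})\) |
| power law with exponential cutoff | \(x^{-\alpha} e^{-\lambda x}\) | rounding |
| Weibull (stretched exponential) | \(x^{\beta-1} e^{-\lambda x^\beta}\) | rounding |

The power law has an exact discrete form (zeta normalization). The other two
do not, and are discretized by *rounding*: with continuous survival function
\(S\), \(P(k) = [S(k - \tfrac12) - S(k + \tfrac12)] / S(x_{min} - \tfrac12)\).
Because consecutive bins telescope, this pmf sums to 1 exactly — no truncated
tail sum is ever needed for normalization. For the Weibull,
\(S(x) = e^{-\lambda x^\beta}\) is available in closed form; for the cutoff
model the bin masses are computed by 10-node Gauss–Legendre quadrature per
unit bin (log-scaled to avoid underflow deep in the tail) and the
normalizing survival integral by adaptive quadrature.

The Weibull shape \(\beta\) is the scientifically loaded parameter: at
\(\beta = 1\) the law is exponential (the pmf ratio
\(P(k)/P(k+1) = e^{\lambda}\) exactly), and as \(\beta \to 0\) it
approaches power-law behaviour. A *decrease* in \(\beta\) therefore means a
shift toward a heavier tail — more hub-like, high-degree nodes.

## Maximum likelihood, initialization, and the closed-form exponent

`fit_discrete_mle()` maximizes \(\sum_i \log P(x_i)\) with L-BFGS-B inside
bounded boxes (Weibull shape in \((0.01, 3]\), rate in \((10^{-6}, 100]\);
cutoff exponent in \((1.01, 6]\), rate in \((10^{-6}, 10]\)). Stretched
exponentials have notoriously flat likelihood ridges, so the optimizer starts
from a moment-matching point (the Weibull coefficient of variation depends
only on the shape, which gives a one-dimensional root-find for the
initializer) and adds two deterministic perturbed restarts — deterministic
rather than random so that fitting never consumes global RNG state — plus a
derivative-free Nelder–Mead polish whenever a line search aborts or the
optimum is pinned to a box edge. A property test verifies that a 50×50
parameter grid never beats the optimizer by more than \(10^{-3}\) log-units.

For the pure power law, `fit_powerlaw_discrete()` returns the standard
approximate estimator
\[\hat\alpha \simeq 1 + n \Big[\sum_i \ln \frac{x_i}{x_{min} - 1/2}\Big]^{-1},\]
which is the *exact* MLE of the continuous power law on
\([x_{min}-\tfrac12, \infty)\). Two consequences worth knowing:

* the test suite verifies it against a brute-force grid search over that
  same continuous-approximation likelihood (agreement within \(10^{-2}\)),
  and against hand evaluation — including the degenerate all-ones sample,
  where it equals \(1 + 1/\ln 2 \approx 2.4427\);
* at `xmin = 1` the approximation is visibly biased for the *discrete* law
  (on zeta-sampled data with \(\alpha = 2.5\) it returns roughly 2.0), which
  is why the fit object also exposes `alpha_exact`, the numerical MLE of the
  zeta-normalized form, and why recovery tests assert on `alpha_exact`.

`select_xmin_ks()` implements the usual lower-bound scan: every observed
unique value is tried as `xmin`, the power law is fitted above it, and the
candidate minimizing the Kolmogorov–Smirnov distance between empirical and
fitted CDFs wins; ties break toward the smallest candidate so the most data
is retained. For the three-way model comparison, `xmin` is fixed at 1 and
degrees of 0 (isolated voxels, outside every model's support) are dropped
with their count recorded.

## The normalized loglikelihood ratio

`compare_models()` follows the Vuong construction for non-nested model
comparison: with pointwise differences
\(d_i = \log p_a(x_i) - \log p_b(x_i)\),
\[R = \frac{\sum_i d_i}{\sigma \sqrt n}, \qquad
  \sigma^2 = \frac1n \sum_i (d_i - \bar d)^2,\]
and a two-sided normal tail probability for \(R\). A positive \(R\) favours
the first model; \(p\) asks whether the sign could be a fluctuation. When the
two fitted pmfs coincide on the sample (\(\sigma = 0\)) the comparison is
flagged degenerate and returns \(R = 0, p = 1\). At the group level
(`group_mean_R()`) the mean of \(R\) is taken over subjects whose comparison
reached \(p < 0.05\); subjects with indecisive comparisons contribute
nothing, and their count is reported.

One asymmetry deserves emphasis because the test suite encodes it: Weibull
data with \(\beta = 0.5\) is separated from the best-fitting power law
essentially always at \(n = 5000\) (the calibration harness measures a 100%
win rate over 100 seeds), but *power-law* data is not reliably separated from
the Weibull, because the Weibull family contains near-power-law members as
\(\beta \to 0\) (and the cutoff family contains the power law exactly at
\(\lambda \to 0\)). The comparison machinery is therefore asymmetric by the
geometry of the families, not by implementation: a significant win for the
Weibull is informative; an indecisive comparison against a nesting family is
the correct answer, not a failure.

## Graph construction choices

* Binarization uses \(r_{ij} \ge T\) (inclusive); the FCS floor uses the
  strict \(r_{ij} > r_0\). The asymmetry mirrors the printed rules and is
  kept deliberately.
* Only positive thresholds are accepted: negative correlations never count
  as edges and never enter FCS.
* The grey-matter mask keeps voxels with probability \(\ge\) cutoff
  (inclusive boundary, default 0.2).
* "Within 20 mm" excludes pairs at distance strictly less than `d_min`;
  pairs at exactly 20 mm are kept. Distances are Euclidean between voxel
  centers in mm, from the NIfTI affine for real volumes or lattice
  coordinates for synthetic scenes.
* FCS divides by the full eligible-voxel count \(N\), not by the number of
  suprathreshold terms; distance-excluded pairs are removed from the sum
  only, leaving the denominator fixed. Correlations are capped at
  \(1 - 10^{-12}\) before the Fisher z-transform so duplicate series cannot
  produce infinities.
* Zero-variance voxels cannot carry a correlation and are removed, with a
  warning and a count on the graph object.
* Subnetwork degree sequences are *global* degrees (edges counted to the
  whole brain) restricted to nodes of one atlas label — the union of the
  seven subnetwork sequences is a permutation of the whole-brain sequence.

## The synthetic cohort: what it emulates and what it does not

`generate_timeseries()` builds unit-variance voxel series
\(x_i(t) = \sqrt{c_i}\, s_{g(i)}(t) + \sqrt{1-c_i}\,\epsilon_i(t)\) from one
shared signal per atlas community plus private noise. The coupling \(c_i\)
("hubness", default \(\mathrm{Beta}(2,5)\)) sets a voxel's expected degree
after thresholding: the population correlation of same-community voxels is
\(\sqrt{c_i c_j}\). On a 3-mm lattice with randomly interleaved communities,
thresholded degrees from this generator are short-tailed, and the Weibull
wins the model comparison against the power law in essentially every seed —
the qualitative behaviour expected of real voxel networks. The generator
makes no attempt at hemodynamics, autocorrelated noise, motion, or spatially
smooth signals; passing tests say the *pipeline* behaves correctly on data
with community structure and heterogeneous hubness, not that real rsfMRI
obeys this generative model.

`generate_cohort()` adds the study design. Its default `"degrees"` mode
gives each subject a true shape \(\beta_i \sim N(\beta_{HC} -
\Delta\beta \cdot \mathbb{1}[\text{aMCI}],\; sd_\beta)\) (defaults
\(\beta_{HC} = 0.65\), \(\Delta\beta = 0.1\), \(sd_\beta = 0.05\),
\(\lambda = 0.1\)) and samples one whole-brain degree sequence per subject
(default 8000 nodes) from the discrete Weibull; subnetwork sequences are the
subsets under a uniform random 7-label atlas, exactly the partition relation
the graph module enforces. This matters for multiple-testing calibration:
because all eight per-network shape estimates derive from one underlying
subject shape, the eight group tests are strongly positively correlated, and
under a true null the BH family rejects nothing in ≈95% of cohorts — the
behaviour the null-calibration harness measures. The 8000-node default also
reflects scale: in a voxel-level network even single subnetworks hold
thousands of nodes, so per-network shape estimates are precise relative to
the between-subject spread.

Demographics mirror the study table (aMCI older on average, similar
education and gender mix); cognitive ability — the mean of MMSE and MoCA —
is \(27 + s(\beta_i - \beta_{HC}) - 0.05(\text{age} - 72) + N(0, 1.5^2)\),
clipped to \([0, 30]\), with the MMSE/MoCA pair scattered symmetrically
around it. The default slope \(s = 25\) points per unit shape makes the
injected group gap of 0.1 in \(\beta\) produce a ≈2.5-point cognitive gap,
matching the magnitude of the printed group difference. The noise SD of 1.5
points and the small negative age slope are simulation conveniences recorded
in the ground-truth object; the source gives no generative model for any of
this, so the hubness mechanism and the cognition coupling are one plausible
instantiation, not a claim about disease biology.

The `"timeseries"` mode shifts the aMCI hubness distribution toward high
couplings (\(\mathrm{Beta}(2, 5 - 10\Delta\beta)\)), producing more hub
nodes and hence a lower fitted shape; the shift scales with
\(\Delta\beta\) but is qualitative — exact calibration of a hubness shift to
a shape difference has no closed form and is not attempted.

## Group statistics

Both printed GLMs are ordinary least squares with diagnosis coded
HC = 0 / aMCI = 1 and gender F = 0 / M = 1, so a lower patient shape appears
as a negative diagnosis coefficient:

* shape ~ diagnosis + age + gender + education (group difference);
* cognitive ability ~ shape + age + gender + education, within the aMCI
  group (association with cognition);
* cognitive ability ~ diagnosis × shape + age + gender + education
  (slope heterogeneity).

The FDR family for the shape analysis is the 8 networks (whole brain + 7
subnetworks) within one threshold, each threshold corrected separately. The
2×2 gender test uses the Yates-corrected Pearson chi-square and the
continuous demographic tests the pooled two-sample t: those are the choices
that reproduce the printed demographic p-values (0.45 for gender — the
uncorrected statistic gives 0.32 — and below 0.001 for MMSE and MoCA), and
they were fixed by direct computation against the printed table before being
frozen into tests. A Welch option exists for unequal variances. The
voxelwise FCS group map fits the same diagnosis GLM at every voxel in one
QR pass (verified against a looped `lm()` oracle) with BH correction across
voxels; voxels with residual variance at rounding-noise level are reported
as t = 0 rather than as ratios of floating-point residues.

## Numerical choices and degenerate inputs

* Hurwitz zeta by direct summation (1000 terms) plus an Euler–Maclaurin
  tail; accurate to ~1e-14 for the exponents in range.
* Weibull sampling by the closed-form inverse CDF of the discretized law,
  \(k = \max(x_{min}, \lceil (x_0^\beta - \log(1-u)/\lambda)^{1/\beta} -
  \tfrac12 \rceil)\) — exact for any shape, with no table truncation.
* Power-law sampling tabulates the first \(10^5\) zeta probabilities and
  inverts the extreme tail by bisection on the survival function, so small
  exponents with astronomically long tails still sample exactly.
* Cutoff-law sampling uses an inverse-CDF table truncated at cumulative
  mass \(1 - 10^{-9}\) and renormalized (bias \(< 10^{-9}\)).
* Ties in the `xmin` scan break toward the smallest candidate; candidates
  leaving fewer than two observations are skipped.
* `compare_models()` with \(\sigma < 10^{-12}\) returns the degenerate
  result rather than dividing by zero; empty masks, zero margins,
  rank-deficient designs and sub-minimum group sizes are hard errors with
  named causes.

## Problem sizes used by the self-checks

The packaged calibration harnesses run at the sizes that make their
conclusions statistically meaningful while staying desk-scale: parameter
recovery at \(n = 10^4\) over 20 seeds (mean absolute error ≈ 0.004 on the
shape against a 0.05 acceptance band), model selection at \(n = 5000\) over
100 seeds, power and null calibration on 20 + 20 cohorts over 20 replicates,
and the graph oracles on 30-node graphs over 50 seeds. The analysis scripts
under `analysis/` run the same chain at the full simulated study size
(41 + 30 subjects, 8000-node networks).

## Known limitations

* The synthetic time series are white in time and the communities are
  spatially random; spatial autocorrelation, slow temporal dynamics and
  realistic atlas geometry are all absent.
* The hubness→shape mapping in `"timeseries"` mode is monotone but
  uncalibrated; quantitative effect-size statements should use `"degrees"`
  mode.
* Only the three candidate families are implemented — no log-normal
  alternative, and no bootstrap goodness-of-fit p-value for the power law;
  the comparison framework is the likelihood-ratio one.
* The closed-form power-law exponent is reliable only for large `xmin`; use
  `alpha_exact` when the discrete exponent itself is of interest.
* FCS weights positive correlations only; no negative-edge or weighted-graph
  metrics beyond FCS are provided.
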