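# weibullnet

Degree-distribution analysis of voxel-level resting-state functional brain
networks: which probability law describes the number of connections per
voxel, does that law's shape change in amnestic mild cognitive impairment
(aMCI), and does the change track cognitive decline?

The package is written for network-neuroscience researchers who want the
full chain — graph construction, discrete heavy-tailed model fitting, model
comparison, and covariate-adjusted group statistics — as tested, reusable
functions, exercised end-to-end on synthetic cohorts with known ground truth.

## The models and statistics at the core

Nodal degree is `degree(i) = Σ_{j≠i} a_ij`, with `a_ij = 1` iff the Pearson
correlation `r_ij ≥ T` (`T` in 0.4–0.6), after removing connections between
voxels closer than 20 mm; only positive correlations count. Functional
connectivity strength (weighted degree centrality) is
`FCS(i) = (1/N) Σ_{j≠i} atanh(r_ij)` over `r_ij > r0 = 0.2`.

Three candidate laws are fitted to each degree sequence by discrete maximum
likelihood at `xmin = 1`:

| model | density (up to a constant) |
|---|---|
| power law | `x^(-α)` |
| power law with exponential cutoff | `x^(-α) e^(-λx)` |
| Weibull (stretched exponential) | `x^(β-1) e^(-λx^β)` |

The power law uses its exact discrete (zeta-normalized) form; the other two
are discretized by rounding, `P(k) ∝ S(k-½) − S(k+½)` with `S` the continuous
survival function. Fits are compared with the Vuong-style normalized
loglikelihood ratio `R = Σ d_i / (σ√n)` (`d_i` the pointwise loglikelihood
differences): the sign of `R` names the better model, its two-sided normal
`p` says whether the sign is meaningful, and group-level conclusions average
`R` over subjects with `p < 0.05`. The Weibull shape `β` interpolates between
power-law-like (`β → 0`) and exponential (`β = 1`) behaviour; group
differences in `β` are tested with
`β ~ diagnosis + age + gender + education`, cognition associations with
`cognitive ability ~ β + age + gender + education` inside the patient group
(cognitive ability = mean of MMSE and MoCA), both FDR-corrected across the
8-network family (whole brain + 7 subnetworks).

## Worked example

```r
library(weibullnet)

# one synthetic scene: 400 voxels on a 3-mm lattice, 7 communities,
# per-voxel hubness ~ Beta(2, 5)
scene <- generate_timeseries(400, 150, seed = 101)
graph <- apply_distance_exclusion(correlation_matrix(scene), d_min = 20)
deg   <- compute_degrees(graph, threshold = 0.4)

x <- deg[deg >= 1]                   # zero-degree voxels lie outside the support
fw <- fit_discrete_mle(x, "weibull")
fp <- fit_discrete_mle(x, "powerlaw")
fw
#> Discrete weibull fit (xmin = 1 , n = 200 )
#>   params: beta = 0.9282, lambda = 0.33003
#>   loglik: -452.3642  KS: 0.02032  converged: TRUE

compare_models(x, fw, fp)
#> weibull vs powerlaw: R = 6.192, p = 5.96e-10 (n = 200)
```

The positive `R` with tiny `p` says this network's degrees are fitted far
better by the short-tailed Weibull than by a power law — on this synthetic
scene, in ten out of ten seeds, and the same preference the analysis
pipeline reports at the group level.

The scripts under `analysis/` run the whole study design at full scale and
narrate what they find:

```sh
Rscript analysis/01_simulate_cohort.R     # 41 HC + 30 aMCI, Δβ = 0.1 injected
Rscript analysis/02_build_networks.R      # graph/degree/FCS demo on one scene
Rscript analysis/03_fit_degree_models.R   # 3 models x 568 sequences, group-mean R
Rscript analysis/04_group_statistics.R    # group GLMs, cognition, interaction
```

Step 03 reports the Weibull beating the power law in every network
(group-mean `R` = 57.4 whole-brain, 21.6–21.8 in the subnetworks, all 71
subjects significant) and beating the exponential-cutoff law throughout, and
step
04 recovers the injected effects: every network's diagnosis coefficient is
negative (aMCI lower `β`) and survives FDR, and within aMCI the cognition
slope on `β` is positive in all eight networks, echoing the direction
lower shape ↔ lower cognitive scores.

`run_full_pipeline(run_config(...), out_dir)` performs the same chain as one
call with bit-reproducible outputs.

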