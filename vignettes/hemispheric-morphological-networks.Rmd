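---
title: "Hemispheric morphological networks from cortical thickness distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric morphological networks from cortical thickness distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemimorph)
```

## The model

A *hemispheric morphological network* is an intraindividual structural
covariance graph: for one subject and one hemisphere, the nodes are 256
similar-size cortical subregions and the edge weight between two subregions
is the similarity of their cortical thickness *distributions*. Because the
comparison is between whole distributions rather than mean values, two
regions are "connected" when thickness varies over the same range in the
same proportions — a morphological fingerprint match, computed entirely
within one subject.

The pipeline has six stages:

1. **Parcellation upsampling.** The 78 cortical regions of the AAL scheme
   (39 homologous left/right pairs) are subdivided into 512 subregions (256
   per hemisphere) by k-means on the spherical surface coordinates, run
   independently inside each anatomical region so that subregions never
   cross gyral or sulcal boundaries. Cluster counts per region are assigned
   proportionally to region size with a largest-remainder correction, so
   the per-hemisphere total is exactly 256 and subregion sizes are as even
   as the geometry allows.
2. **Density estimation.** Each subregion's thickness sample is summarized
   as a Gaussian-kernel density evaluated on a fixed 27-point mesh shared
   by all subregions of the subject, then floored and renormalized into a
   discrete probability distribution.
3. **Edge weights.** For subregions $p$ and $q$ of the same hemisphere,
   the Jensen–Shannon divergence
   $$\mathrm{JSD}(p, q) = \tfrac12 \sum_x p(x)\,\log\frac{p(x)}{m(x)}
     + \tfrac12 \sum_x q(x)\,\log\frac{q(x)}{m(x)}, \qquad
     m = \tfrac{p + q}{2},$$
   is transformed into the similarity $\mathrm{JSS} = e^{-\mathrm{JSD}}$.
   With natural logarithms $\mathrm{JSD} \le \log 2$, so JSS lies in
   $[e^{-\log 2}, 1] = [0.5, 1]$, reaching 1 exactly when the two
   distributions agree on the mesh.
4. **Sparsity thresholding.** Each 256×256 weight matrix is binarized at
   sparsity levels $K = 0.10, 0.12, \dots, 0.36$, keeping the
   $\lfloor K \cdot N(N-1)/2 \rfloor$ strongest edges.
5. **Graph metrics.** Per binary network: characteristic path length
   (harmonic mean of shortest paths), clustering coefficient, global,
   local, and nodal efficiency, and degree centrality; path length and
   clustering are additionally normalized by means over degree-preserving
   random networks, giving $\lambda$, $\gamma$, and small-worldness
   $\sigma = \gamma/\lambda$.
6. **Integration, asymmetry, statistics.** Metrics are averaged over the 14
   sparsity levels; local metrics are first averaged over each anatomical
   region's subregions. For each metric the asymmetry index
   $$AI(M) = 100 \times 2 \times \frac{M_L - M_R}{M_L + M_R}$$
   contrasts the two hemispheric networks (positive = leftward). Group
   inference uses a two-way repeated-measures ANOVA (hemisphere within,
   gender between, age covariate) on the hemispheric metrics, one-sample
   t-tests on AI within gender, two-sample t-tests on AI between genders,
   and Benjamini–Hochberg FDR across the 39 homologous region pairs for
   local metrics.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| mesh points | 27 | – | resolution of the density mesh; fine enough to separate regional distributions, coarse enough that ~150-vertex samples fill it |
| bandwidth | Silverman's rule on the subject's pooled thickness | mm | the kernel bandwidth is otherwise a free choice; a pooled data-driven rule keeps all subregions of a subject on a common smoothing scale and is recorded with the output |
| probability floor | 1e-12 | probability | the divergence is undefined at zero mass; the floor keeps logarithms finite without visibly distorting the distribution |
| sparsity grid | 0.10–0.36 step 0.02 | fraction of possible edges | below ~0.10 the 256-node graphs fragment; above 0.36 small-world structure washes out; metrics are integrated over the grid so no single level drives the result |
| random networks | 100 (10 in the validation studies) | – | ensemble size for $L_{ran}$, $C_{ran}$; 10 is enough for the validation cohort because $\sigma$ sits far from the decision boundary |
| swaps per edge | 10 | – | double-edge-swap burn-in; degree sequences are preserved exactly regardless |
| subregion size floor | 30 | vertices | a 27-point density from fewer than ~30 values is unstable |

## The synthetic cohort generator

Real input would be surface-extraction output (one labeled, thickness-valued
vertex table per subject). The generator emulates exactly that contract:

- two unit-sphere hemispheres with contiguous anatomical regions from a
  balanced nearest-seed partition; the right hemisphere is the mirror image
  of the left, so homologous regions have identical geometry;
- a fixed regional mean-thickness profile, evenly spaced over 1.5–4.5 mm in
  canonical region order and identical for homologous pairs — under the
  null the two hemispheres are exactly exchangeable, which the test suite
  exploits (sign balance of asymmetry indexes, exact end-to-end AI negation
  under hemisphere relabeling);
- per subject, thickness = regional mean + a smooth random field (a
  spherical-harmonic series with i.i.d. coefficients; the autocorrelation
  length sets the maximum degree, default $l_{max} = 4$) + i.i.d. vertex
  noise, the field and noise each carrying half of the 0.35 mm within-region
  variance; values are floored at 0.1 mm;
- a manifest of two gender groups, ages 22–36, handedness ≥ 50, one subject
  per family, so the cohort filter passes by construction;
- optional injected effects: additive mean shifts and/or spread rescaling
  restricted to one (gender, hemisphere, region).

The default surface is dimensioned so subregions average ~150 vertices
(hemisphere total = 256 × 150), matching the subregion scale reported for
real cortical meshes (mean 149, sd 22 vertices).

What the generator does *not* emulate: real cortical folding geometry and
mesh topology, spatially varying noise, scanner/site effects, the empirical
(non-Gaussian, skewed) shape of real thickness distributions, and realistic
covariance between regional thickness and age or gender. Passing validation
therefore demonstrates that the pipeline's algebra, determinism, and
statistical calibration are correct under a controlled model — not that any
particular real-data asymmetry finding would replicate.

The documented validation effect for power studies is a −0.5 mm mean shift
of left TPOmid in females. Direction matters: TPOmid sits at the thick end
of the regional profile, and shifting it *toward* the bulk of the other
regions' means reliably gains it similarity partners, raising its
left-hemisphere degree (a leftward, positive-AI effect). An outward shift
of the same magnitude would isolate the region instead and lower its
degree; the monotonicity property tests use shift magnitudes within this
inward regime (0.2–0.8 mm).

## Numerical choices

- **Shared per-subject mesh.** The divergence integrates $p$ and $q$
  against their pointwise average, which is only defined on a common
  support; all subregion densities of one subject therefore share one mesh
  spanning the pooled thickness range padded by 3 bandwidths. On a uniform
  mesh the quadrature weights cancel in the ratios, so plain normalized
  masses are summed (no trapezoid weights).
- **Natural logarithm.** The log base of the divergence is a convention;
  nats are used, so $\mathrm{JSS} \in [0.5, 1]$. Since every downstream
  step (ranking edges by weight) is monotone in JSD, the base has no effect
  on any binarized network.
- **Edge counts and ties.** `floor()` fixes the edge count at each
  sparsity; ties in weight are broken by smaller node id then smaller
  partner id. Ties have measure zero for real-valued similarities but a
  deterministic rule makes binarization exactly reproducible and the edge
  sets exactly nested across levels.
- **Disconnection.** Unreachable pairs contribute 0 to inverse-distance
  sums (the standard efficiency convention), and the harmonic-mean path
  length stays finite on any graph with at least one connected pair — so
  random networks need not be forced connected. Consequently
  $L_p \times E_{global} = 1$ holds as an exact algebraic identity, which
  the suite asserts on every computed network.
- **Nodal efficiency** is implemented as the mean inverse shortest path
  length from a node to all others (its node-average equals global
  efficiency exactly); the per-neighborhood quantity is the separate local
  efficiency.
- **Determinism.** Every stochastic step (surface sampling, k-means
  seeding, field coefficients, edge rewiring) draws from a seed derived
  deterministically from one global seed; identical configurations
  reproduce byte-identical outputs. k-means uses farthest-point seeding,
  Lloyd iterations capped at 100, and one re-seed on an empty cluster.
- **Repeated-measures ANOVA.** With a two-level within factor the design
  decomposes exactly: the subject L/R mean regressed on gender + centered
  age gives the gender effect; the L−R difference regressed on the same
  design gives the hemisphere effect (intercept, under sum coding) and the
  interaction. The decomposition is verified against a general multivariate
  linear model to 1e-8. Age enters linearly and mean-centered; no
  age-by-hemisphere products beyond the within-difference regression, and
  no sphericity correction is needed (two levels).
- **FDR families.** FDR is applied across the 39 homologous region pairs,
  separately per local metric and per test type; global metrics are tested
  at uncorrected p < 0.05.

## Validation study sizes

The packaged validation studies use: a reference cohort of 10 subjects per
gender at full 256-node scale with 10 random networks per normalization
(small-worldness, efficiency brackets, analytic identities); 200 simulated
null cohorts of n = 30 for type-I calibration of the ANOVA and one-sample
AI tests (99% binomial band around the nominal 5%); and 50 replicate
cohorts of 40 + 40 subjects sharing one cortical geometry for power of the
injected TPOmid degree effect (detection with correct sign after FDR in at
least 80%). Unit tests run on a reduced 32-node-per-hemisphere geometry
that exercises every code path.

## Limitations

- The generator's regional profile is a fixed ladder; real regional
  thickness is not evenly spaced and its distributions are skewed.
- Only cortical thickness is modeled; multi-feature morphological networks
  are out of scope.
- Networks are strictly intra-hemispheric; inter-hemispheric edges are
  never computed.
- The kernel family is Gaussian and the bandwidth rule global per subject;
  adaptive or boundary-corrected estimators are not provided.
- Weighted-graph metrics, alternative atlases, and geodesic (rather than
  chordal k-means) subdivision are not implemented.
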