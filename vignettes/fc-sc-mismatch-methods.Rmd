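---
title: "Quantifying FC–SC mismatch and hemispheric specialisation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FC-SC mismatch and hemispheric specialisation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfcsc)
```

## The model

Structural connectivity (SC) is assumed to be a broad, linear driver of
functional connectivity (FC) *after* SC has been brought onto the FC scale.
For subject $k$, over the analysed edge set, the package fits

$$FC_{uv,k} = \beta_{0,k} + \beta_{1,k}\,SC^{trans}_{uv,k} + \varepsilon_{uv,k}$$

by ordinary least squares and defines the mismatch $mFCSC_{uv,k}$ as the
residual. Two assumptions make the residual meaningful:

* **Homoscedasticity**, restored by the power-law transform
  $SC^{trans} = a\,SC^{\,b} + c$ with $a, b > 0$. Raw SC is heavy-tailed
  (a few connections orders of magnitude stronger than the rest) while FC,
  a correlation, is roughly normal on a bounded scale; regressing FC on raw
  SC would concentrate all leverage in the tail.
* **Direct-link dominance**, enforced by exclusion. FC integrates direct and
  indirect interactions; tractography-based SC measures only the direct
  fibre bundle. A residual is interpretable only where the direct link
  plausibly dominates, so edges whose reciprocal-weight direct path is not
  strictly shorter than every indirect path in the group-averaged
  transformed graph are dropped.

The per-subject fit (rather than one pooled regression) deliberately absorbs
inter-individual variation in the mean and range of FC: adding a constant to
a subject's FC leaves every mismatch unchanged, and rescaling a subject's FC
rescales the mismatches proportionally. Both invariances are tested to
1e-10.

Group inference compares mismatch *between* homologous connections, never
against zero: a single mismatch conflates physiology with systematic
measurement error, but bilateral pairs share those errors (a white-matter
bottleneck in one hemisphere is typically mirrored in the other), so the
paired left−right difference cancels them.

## Processing order

The stages must run as: transform → direct-edge exclusion → hemispheric
restriction. The exclusion step needs the complete graph (shortest paths are
invalid on a hemisphere-restricted subgraph, and removing strong
inter-hemispheric edges would distort indirect path lengths), and it must
see *transformed* weights — on raw SC, a handful of extremely strong edges
would form short indirect detours almost everywhere and the exclusion would
remove most of the connectome. `run_pipeline()` hard-codes this order.

Shortest paths are computed on the full graph, not per hemisphere. The
direct-path criterion itself carries no hemisphere restriction; the
intra-hemispheric mask is applied afterwards, together with the bilateral
requirement that an edge's contralateral homolog is also preserved.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | family-wise error rate; per-test threshold is `alpha / n_total_pairs` (dimensionless) |
| asymmetry tolerance | 1e-8 | absolute; inputs below are symmetrised as $(M+M^T)/2$, above are rejected — connectome generators emit symmetric matrices up to rounding |
| exponent multi-start grid | 0.1, 0.5, 1 | power-law fits are multi-modal; the lowest-$L_1$ solution wins |
| `screen_restrict_to_mask` | `TRUE` | whether the FC-asymmetry screen tests only mask-valid pairs or all enumerated pairs |

The Bonferroni denominator is always the full enumerated pair count
(`choose(n_left, 2)`), not the testable count. This keeps the significance
criterion independent of how many connections the exclusion stages removed,
which varies between cohorts; it is conservative for the testable subset.

## The fit: least absolute residuals via soft-L1

Both sorted edge vectors (all `n(n-1)/2` upper-triangular entries, zeros
included, so the two vectors have equal length and rank pairing is
well-defined) enter a least-absolute-residuals fit. The $L_1$ objective is
realised as a soft-L1 loss
$\rho(r) = 2\delta^2(\sqrt{1+(r/\delta)^2}-1)$ with
$\delta = 10^{-3}\,\mathrm{sd}(FC)$, smooth enough for the
Levenberg–Marquardt engine (`minpack.lm::nls.lm`) while within a fraction of
a percent of $|r|$ for residuals above $\delta$. Ties in the sorted vectors
are irrelevant by construction — only sorted values are paired. The
multiplier and offset are initialised per exponent start from the ranges of
the two sorted vectors; parameters are bounded below ($a \ge 10^{-12}$,
$b \ge 10^{-6}$) so the accepted fit is strictly increasing and
rank-preserving. Convergence codes that mean "tolerance finer than machine
improvement" are accepted as convergence; only iteration/evaluation
exhaustion and invalid-input codes count as failure, in which case the best
parameters so far are attached to the error.

With a small exponent (the realistic regime, $b \approx 0.09$) the
multiplier and offset are nearly collinear — $x^b$ spans a narrow range — so
their individual values are well determined only at group scale. That is
precisely why the parameters are estimated from group-averaged connectomes
and then applied per subject, rather than fitted per individual.

## Numerical choices and degenerate inputs

* **Non-positive transformed weights** (possible because the offset is
  negative) are treated as absent edges: never preserved, never part of any
  path. A reciprocal length is undefined or negative there, and a negative
  "length" would corrupt every shortest-path comparison.
* **Equality of direct and shortest indirect length** excludes the edge (the
  preservation condition is a strict inequality).
* **Zero-variance paired differences** (e.g. a noiseless cohort, where all
  residuals vanish) leave the t-statistic undefined; such pairs are flagged
  `zero_variance` and never declared significant.
* **Constant SC** over the edge set makes the exponent unidentifiable and is
  rejected, as are fits on fewer than 4 edges and subject models on fewer
  than 3 edges or with a constant predictor.
* **Category ties**: the six-way classification (signs of the two group
  means × their ordering) resolves zero means by the sign of the
  t-statistic; exact ties are reported as `indeterminate`.
* Excluded entries are stored and written as `NaN` (token `nan`), never 0 —
  a mismatch of 0 is a meaningful value.

## The synthetic cohort generator

`generate_cohort()` produces the statistical structure the method assumes,
and nothing more: a log-normal ground-truth SC template (meanlog 5, sdlog 1:
median edge weight ≈ 148 with skewness > 2, emulating the long SIFT2 tail)
mirrored exactly across hemispheres; per-subject multiplicative log-normal
SC perturbations (sdlog 0.1); FC generated as the power law
(0.4114, 0.0926, −0.3789 by default, the realistic regime) of the subject's
own SC, times a subject-level scale $1+\mathcal N(0, 0.1)$, plus a
subject-level shift $\mathcal N(0, 0.1)$ and i.i.d. edge noise
$\mathcal N(0, 0.05)$, symmetrised. Defaults are 42 regions per hemisphere
and 50 subjects. The subject scale/shift reproduce the inter-individual FC
variation that motivates per-subject fitting; because the generated FC is
*exactly* affine in the transformed SC, the generator is a closed loop: with
all noise terms at zero, the fit recovers the link parameters to machine
precision and every mismatch is numerically zero.

Mismatch injections add a chosen offset to one side's FC edge for all
subjects (or scale an SC edge, for structure-side scenarios), modelling a
lateralised functional specialisation. Without injections, left and right
edge distributions are exchangeable, so downstream tests are
null-calibrated by construction.

What the generator does **not** emulate: spatial autocorrelation between
edges, distance-dependent tractography biases, negative or bounded FC
support, indirect-path contributions to FC, and non-affine structure–function
coupling. Passing tests therefore demonstrate the pipeline's correctness and
calibration under its own assumptions, not its validity on real
connectomes.

## Verification sizes and expectations

The test suite works at sizes chosen to make each property sharp: exhaustive
simple-path enumeration cross-checks the direct-edge criterion on 200 random
weighted graphs of up to 8 nodes; OLS identities (residual mean and
residual–predictor correlation below 1e-10) on 10-region cohorts;
calibration at the full study scale — two null 50-subject, 84-region cohorts
pooling > 1500 testable pairs, whose uncorrected type-I rate must sit within
3 Monte-Carlo standard deviations of 0.05. Sensitivity is assessed by
injecting an offset of one standard deviation of the paired left−right
mismatch difference ($\sqrt 2 \times$ the edge-noise sd) into 20
mask-testable pairs of a 50-subject cohort; that offset gives the paired
t-test a noncentrality of $\sqrt{50}$, i.e. essentially certain detection at
the Bonferroni threshold, so a detected fraction above 0.9 with zero false
positives is the expected outcome, and the offset is defined on the scale
the test actually sees. Injection sites are chosen from the mask of the
uninjected cohort at the same seed; FC-side injections do not alter SC, so
the mask is identical and the selection is not circular.

## Known limitations

* The power law is fitted once, at group level; atypical individuals whose
  SC distribution deviates from the group's are transformed with group
  parameters.
* The direct/indirect criterion is a hard threshold; an edge marginally
  beaten by an indirect path is dropped entirely.
* Exclusion by structural shortest paths may drop a pair whose two regions
  are jointly driven by a third region rather than communicating
  indirectly; this is conservative, not incorrect, for mismatch
  interpretation.
* Bonferroni over all enumerated pairs is strict; no FDR alternative is
  offered because the bilateral comparison is the method's defining
  inference.
* The six-way pair categorisation describes group means only; it does not
  imply that individual subjects share the pattern.
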