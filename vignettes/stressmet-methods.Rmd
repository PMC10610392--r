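---
title: "Methods: multi-environment stress-tolerance analysis with stressmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-environment stress-tolerance analysis with stressmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stressmet` implements the ideotype-identification workflow used in
multi-environment trials (METs) of crops under abiotic stress: raw
replicate-level trait values observed under optimal, drought and heat
conditions are converted into tolerance indices, and those indices are then
analysed for genetics, stability, and multi-trait selection. This vignette
records the models, the tunable parameters and the design choices, so that
every number the package produces can be traced to a stated decision.

## 1. Tolerance index environments

For each trait $x$, genotype $i$, season $s$ and stress condition
$c \in \{\text{drought}, \text{heat}\}$, the tolerance index is the ratio

$$ TI_{i} = \frac{x_i \,\text{under stress}}{x_i\,\text{under optimal conditions}} $$

computed within the same season. Each (stress condition, season) pair
becomes a derived *index environment*; three seasons by two stresses give
E1–E6, coded season-first with drought before heat. Indices near 1 mean the
genotype held its optimal-condition performance under stress.

Two conventions deserve note:

* **Per-replicate pairing.** The index is formed per replicate, pairing
  stress block $k$ with optimal block $k$ of the same season. This retains a
  replicate-within-environment stratum, so the joint ANOVA of a 20-genotype,
  6-environment, 3-replicate index table has the familiar df layout
  (GEN 19, GEN:ENV 95, REP(ENV) 12, Residuals 228). Forming indices on
  genotype means would collapse that stratum.
* **Sense handling.** Traits where smaller is agronomically better (e.g.
  canopy temperature) are *not* inverted at the index stage; the raw ratio
  is kept and orientation is handled downstream by the MGIDI rescaling and
  the selection-gain "sense" flags. This keeps the index table a faithful
  description of the measurement.

## 2. Joint ANOVA, variance components, genetic parameters

Per trait, the replicate-level indices follow

$$ y_{ijk} = \mu + G_i + E_j + R_{k(j)} + GE_{ij} + \varepsilon_{ijk}. $$

`joint_anova()` computes the balanced factorial decomposition; F for
genotype and interaction is taken against the residual mean square, F for
environment against replicates-within-environments. Shapiro–Wilk and
Bartlett pre-tests are reported (`index_pretests()`) but never block the
analysis.

`variance_components()` solves the expected mean squares with genotype
random: $\sigma^2_\varepsilon = MS_{res}$,
$\sigma^2_{ge} = (MS_{GE} - MS_{res})/r$,
$\sigma^2_g = (MS_G - MS_{GE})/(re)$. Negative solutions are truncated at 0
and flagged, so the derived ratios stay in $[0, 1]$. From these,
`genetic_parameters()` reports plot-basis heritability
$H^2 = \sigma^2_g/\sigma^2_p$, the interaction determination
$R^2_{gei} = \sigma^2_{ge}/\sigma^2_p$, genotype-mean heritability
$h^2_{mg} = \sigma^2_g/(\sigma^2_g + \sigma^2_{ge}/e +
\sigma^2_\varepsilon/(er))$, selection accuracy $\sqrt{h^2_{mg}}$,
$r_{ge} = \sigma^2_{ge}/(\sigma^2_{ge} + \sigma^2_\varepsilon)$, and the
genotypic/residual coefficients of variation. Published parameter tables in
this field are often computed by REML with rounding that the EMS formulas
cannot reproduce exactly; the package therefore validates these estimators
by parameter recovery on simulated data with known components, not against
any printed table.

ANOVA F-tests treat genotypes as fixed (the usual reading of a designed
trial), while components, BLUPs and everything downstream treat genotypes
as random — both parameterizations are needed to serve the two halves of
the workflow.

`fit_blup()` fits the same model by REML (`lme4`), with genotype,
environment, replicate-within-environment and interaction random, and
returns the shrunken genotype effects and the $g \times e$ interaction BLUP
matrix. When REML is degenerate — zero residual variance, or
non-convergence — a method-of-moments shrinkage fallback multiplies each
raw centered effect by $\sigma^2/(\sigma^2 + \sigma^2_{err})$; with zero
residual variance this reproduces the raw centered table exactly, which is
also the correct REML limit.

## 3. AMMI decomposition

`ammi_decompose()` double-centers the genotype-by-environment means table
to the interaction matrix
$GEI_{ij} = \bar y_{ij} - \bar y_{i\cdot} - \bar y_{\cdot j} + \mu$ and
factorizes it by SVD. Numerical conventions:

* **Symmetric score scaling**: both genotype and environment scores carry
  $\sqrt{\lambda_k}$, so each axis has equal sums of squares on both sides.
  This is the convention under which published genotype and environment
  score columns have matching per-axis sums of squares, and it makes the
  interaction matrix recoverable as the sum of score outer products.
* **Sign convention**: the largest-magnitude environment loading of each
  axis is made positive. Comparisons against printed score tables use
  absolute values where signs may legitimately differ.
* **Gollob degrees of freedom** $df_k = g + e - 1 - 2k$ for the axis tests
  in `ammi_anova()`, with $SS_k = r\lambda_k^2$ tested against the pooled
  replicate-level residual. Axis df sum to $(g-1)(e-1)$ by construction.

`ammi_predict()` reconstructs
$\hat y_{ij} = \mu + g_i + e_j + \sum_{k\le n} score_{ik} score_{jk}$; $n$
at full rank reproduces the observed means to machine precision, and the
fitting error is non-increasing in $n$. `ammi_biplot_coords()` exports the
axis-1/axis-2 coordinates and the pairwise environment-vector angles
(acute = positively correlated interaction patterns).

## 4. WAASB and WAASBY stability

The weighted average of absolute scores,

$$ WAASB_i = \frac{\sum_k |score_{ik}|\, EP_k}{\sum_k EP_k}, $$

weights each axis by its explained proportion of interaction sum of squares
$EP_k$; lower values mean more stable. The default input is the
decomposition of the **BLUP** interaction matrix (`waasb_from_blup()`), the
shrinkage-stabilised estimate of GEI; a fixed-effects variant simply
decomposes the raw centered means. All available axes are included by
default — that is the weighting under which published worked examples
reproduce from their printed five-axis scores.

`waasby()` rescales mean performance and WAASB each to 0–100 (100 = best;
performance respects the trait's sense, stability is reversed so the lowest
WAASB maps to 100) and averages them with weights $\theta_Y/\theta_S$
(default 50/50). `classify_quadrants()` cuts the performance-by-WAASB plane
at the grand mean of each axis by default: quadrant IV (above-average
performance, below-average WAASB) is the productive-stable corner.
Published quadrant figures do not always state their cutpoints, so the cuts
are exposed as parameters; items exactly on a cut go to the lower quadrant
and are flagged.

## 5. MGIDI ideotype selection

`rescale_traits()` maps each trait linearly onto $[0, 100]$ with 100 in the
desired direction. `trait_factor_analysis()` eigendecomposes the trait
correlation matrix, retains factors with eigenvalue strictly greater than 1
(Kaiser), scales eigenvectors to loadings, rotates by varimax (Kaiser
normalization, tolerance $10^{-6}$), and computes factor scores by the
regression method $F = Z R^{-1} L$. A singular correlation matrix gets a
$10^{-8}$ ridge, reported via message. The ideotype — 100 on every trait —
is projected through the same equation, and

$$ MGIDI_i = \sqrt{\textstyle\sum_f (F_{if} - F_f^{ideo})^2} $$

ranks genotypes by closeness to it. The selected set holds the
$\max(1, \mathrm{round}(\alpha g))$ best at intensity $\alpha$ (default
0.20, i.e. 4 of 20). Because varimax is orthogonal, the distances are
invariant to the rotation, and because the 0–100 map absorbs any per-trait
affine transformation, the ranking is invariant to the units of the raw
inputs. `selection_gains()` reports per-trait differentials
$X_s - X_o$ and gains $SG\% = 100\,(X_s - X_o)\,h^2_{mg}/X_o$ — the
genotype-mean heritability is the multiplier, stated in the output
metadata — and `factor_contributions()` decomposes each genotype's squared
distance into per-factor shares (its weakness profile).

The standard input is the matrix of BLUP-based genotype means across the
index environments; raw means are accepted.

## 6. Stepwise regression of the yield index

`stepwise_fit()` is a forward-selection/backward-elimination search on
partial-F p-values: entry threshold 0.05, stay threshold 0.10 (conventional
defaults, exposed as arguments). The partial $R^2$ recorded at entry is the
$R^2$ increment; entries sum to the final total $R^2$, and the final
coefficients are exactly an OLS refit on the selected set. By default the
pipeline regresses on the genotype-by-environment mean rows ("pooled"
mode); a genotype-means mode exists for comparison. `predict_report()`
evaluates any equation — fitted or transcribed from a publication — and
reports per-row error, relative error and accuracy
$100(1 - |\text{relative error}|)$. Published tables in this area round
predictions to 3 decimals and compute their printed diagnostics from the
rounded values; `predict_report(..., predicted = )` accepts such
precomputed predictions so printed diagnostics can be checked exactly,
while the default path keeps full precision.

## 7. Tolerance categories: Ward clustering and LDA validation

`ward_cluster()` z-scores the genotype-by-trait index means, clusters on
Euclidean distance with Ward linkage (the `ward.D2` variant: squared
distances in the objective, heights on the distance scale), cuts at $k = 5$
and names the categories HT, T, M, S, HS by descending mean of the
grain-yield index. The exported heatmap matrix clips z-scores at $\pm 3$
for display only.

`lda_fit()` is the classical pooled-covariance Gaussian discriminant:
posteriors proportional to $\pi_g \exp(-\tfrac12 d_g^2)$ with Mahalanobis
distances under the common covariance. Priors are group frequencies by
default with an equal-priors switch. When the trait panel is wider than the
residual degrees of freedom (20 traits, 20 genotypes, 5 groups), the pooled
covariance is singular; the Moore–Penrose pseudo-inverse is then used and
reported. This is the package's documented choice for wide panels — it
yields the maximum-separation discriminant in the span of the data.
`lda_loo()` refits with each observation held out; `agreement_table()`
summarises prior/posterior movement.

A caution from the packaged worked example: the published resubstitution
agreement of 75% for the four-predictor panel does not reproduce from the
printed genotype-mean predictors under either prior convention (both give
35%; an independent `MASS::lda` fit agrees), although the printed posterior
labels themselves agree with the priors at exactly 75%. The original fit
evidently used observation-level data that the source does not print.
`reference_lda_validation()` therefore reports both conventions and attaches
the discrepancy explicitly instead of forcing agreement.

## 8. The synthetic trial generator

`generate_met()` provides ground truth for every stage. Per trait it
simulates

$$ y = \bigl(\mu + g_i + e_j + r_{k(j)} + \textstyle\sum_m \lambda_m
  u_{im} v_{jm} + \varepsilon\bigr) \times f_{i,c,s}, $$

with independent zero-mean Gaussian effects, an explicit bilinear
interaction whose score vectors are centered and orthonormalized (so the
planted axes survive double-centering and AMMI recovery is checkable
axis-by-axis), and a multiplicative stress response
$f_{i,c,s} = F_{\text{group}(i),c}\,(1 + \delta_{i,c})(1 + \eta_{i,c,s})$
($f = 1$ under optimal conditions). The pieces of $f$ matter:

* $F_{\text{group},c}$ — five tolerance groups from highly tolerant
  (retaining 92%/89% of optimal performance under drought/heat) to highly
  sensitive (64%/59%), giving the group separation that clustering and LDA
  are meant to find;
* $\delta_{i,c} \sim N(0, \texttt{tol\_sd})$ — a genotype's own deviation
  from its group, constant over seasons (default 0.04). Without it,
  genotypes within a group would be identical on the index scale, because
  additive genotype effects cancel in the stress/optimal ratio;
* $\eta_{i,c,s} \sim N(0, \texttt{tol\_gei\_sd})$ — season-to-season
  variability of the response (default 0.05). This is the planted
  genotype-by-environment interaction of the *indices*; without it the
  index-scale interaction variance is essentially zero and WAASB is
  degenerate.

The defaults (20 genotypes, 3 seasons, 3 conditions, 3 replicates, 20
traits with field-plausible means and CVs) mirror the reference trial
design and give heritabilities and interaction determination in the range
reported for real wheat index data. Traits that rise under stress (canopy
temperature) take the reciprocal response (`stress_inverts`). Ratio-bound
positivity is enforced by truncation at $10^{-6}$ (counted and messaged),
not resampling, so the draw stream stays aligned across configurations. All
randomness flows through the single config seed; output is byte-identical
under a fixed seed.

What the generator does **not** emulate: weather covariates, spatial field
trend, unbalanced or missing plots, non-Gaussian measurement error, and
trait-specific stress physiology beyond the multiplicative response. Tests
passing on this generator therefore certify the statistical machinery —
recovery of planted components, invariances, worked-example equivalence —
not field realism.

## 9. Numerical choices and degenerate inputs

* Balance is checked cell-by-cell; missing or duplicated cells are reported
  with their coordinates.
* Negative variance components truncate to 0 (flagged); undefined ratios
  (zero denominators) return `NA` with flags rather than errors.
* Constant trait columns are dropped from rescaling with a warning;
  constant performance or stability in WAASBY rescales to 100 for all,
  flagged.
* SVD sign ambiguity: largest-magnitude environment loading per axis made
  positive; WAASB is invariant to these sign choices by construction.
* Rank ties break by label order (stable, documented).
* Stepwise search treats NaN p-values from perfect fits as 1 ("no further
  evidence") and stops.
* The pipeline writes every stage table as CSV plus a JSON manifest with
  MD5 checksums; identical config and seed reproduce identical checksums.

## 10. Problem sizes used by the test suite

Simulation-backed tests run at deliberately modest sizes chosen to keep the
whole suite fast while leaving the tested contrasts far from their
thresholds: variance-component recovery at $g = 50$, $e = 6$, $r = 3$ over
100 seeds (median relative error bound 25%); the method-of-moments vs REML
comparison over 50 seeds; MGIDI planted-superior recovery over 100 seeds at
$g = 12$; null calibration of the stepwise entry rate over 200 seeds; LDA
permutation baselines over 200 shuffles. Worked-example tests run from the
packaged printed tables and are instantaneous.

## 11. Known limitations

* Only balanced designs are supported; unbalanced data fail fast rather
  than being imputed.
* The AMMI axis tests are Gollob F-tests only (no cross-validation or
  FR-tests for axis retention).
* Factor retention is Kaiser-only; no parallel analysis or oblique
  rotations.
* The LDA is linear (pooled covariance) by design; no QDA.
* Published-table reproduction is limited to what the printed precision
  permits; where a published value cannot be derived from printed inputs,
  the package reports its own computation and the discrepancy rather than
  the printed number.
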