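# stressmet

Multi-environment trial (MET) analysis of abiotic stress tolerance indices,
for plant breeders screening genotypes under combined drought and heat
stress. Given replicate-level trait values observed under optimal and
stressed conditions across seasons, `stressmet` runs the complete
ideotype-identification chain:

1. **Tolerance indices** — per replicate and season, the ratio
   `x(stress) / x(optimal)` for each trait, organised into derived index
   environments (three seasons × two stresses → E1–E6).
2. **Joint ANOVA and genetic parameters** — the model
   `y = μ + G + E + R(E) + GE + ε` per trait, with variance components from
   the expected mean squares, heritabilities (plot basis `H² = σ²g/σ²p` and
   genotype-mean basis `h²mg`), selection accuracy, and REML BLUPs of the
   genotype and genotype-by-environment effects (`lme4`).
3. **AMMI** — SVD of the double-centered G×E matrix with symmetric-scaled
   scores, Gollob axis tests (`df_k = g + e − 1 − 2k`), n-term prediction,
   and biplot coordinates with environment-vector angles.
4. **WAASB / WAASBY** — the weighted average of absolute IPCA scores
   `WAASB_i = Σ_k |score_ik|·EP_k / Σ_k EP_k` computed on the BLUP
   interaction matrix (lower = more stable), the 0–100 rescaled
   performance/stability blend `WAASBY = (rY·θY + rW·θS)/(θY+θS)`, and the
   four-quadrant performance × stability classification.
5. **MGIDI** — sense-oriented 0–100 rescaling, factor analysis of the trait
   correlation matrix (Kaiser retention, varimax, regression scores), and
   each genotype's Euclidean distance in factor space to the all-optimal
   ideotype, with selection gains `SG% = 100·(Xs − Xo)·h²mg / Xo`.
6. **Stepwise regression** — forward/backward selection of the trait
   indices driving the yield index, with per-step partial R² and
   per-genotype prediction accuracy reports.
7. **Tolerance categories** — Ward (ward.D2) clustering of z-scored index
   means into HT/T/M/S/HS categories, validated by a pooled-covariance
   linear discriminant model (posterior membership probabilities,
   resubstitution and leave-one-out agreement; pseudo-inverse for trait
   panels wider than the residual degrees of freedom).

A seeded synthetic trial generator (`generate_met()`) plants known genotype
effects, low-rank interaction, and tolerance-group structure, so every
stage is testable against ground truth. Packaged reference tables
(`reference_table()`) transcribe the printed worked examples of a published
20-genotype wheat MET so the stability, regression and classification
arithmetic can be checked against published numbers offline.

## Worked example

```r
library(stressmet)

# simulate the default trial: 20 genotypes x {optimal, drought, heat}
# x 3 seasons x 3 replicates x 20 traits
cfg <- pipeline_config(sim = sim_config(seed = 42), seed = 42)
b   <- run_pipeline(cfg)

# most stable genotypes (lowest WAASB on the BLUP interaction matrix)
head(b$waasb$genotypes[order(b$waasb$genotypes$rank), ], 5)
#>   label     Y  waasb  rank
#> 1 G07   0.876 0.0151     1
#> 2 G16   0.817 0.0173     2
#> 3 G03   0.764 0.0249     3
#> 4 G09   0.675 0.0252     4
#> 5 G15   0.629 0.0288     5

# MGIDI selected set at 20% intensity, and the consensus of all analyses
b$mgidi$index$selected
#> [1] "G12" "G07" "G02" "G17"
b$consensus$intersection
#> [1] "G07"

# genetic parameters of the yield index
subset(b$parameters, trait == "GY")[, c("trait", "H2", "R2gei", "h2mg", "As")]
#>   trait    H2  R2gei  h2mg    As
#> 1 GY    0.597 0.0446 0.956 0.978
```

Here `Y` is the genotype's mean tolerance index (1 = no loss under
stress), `waasb` its stability score (0 = contributes no interaction), and
the consensus lists the genotypes that are simultaneously in the MGIDI
selected set, in the productive-stable WAASB quadrant, and in an
LDA-confirmed tolerant category — the pipeline's ideotype candidates.

The published worked examples reproduce directly from the packaged tables:

```r
ep  <- reference_axis_proportions()
w   <- reference_table("waasb")
gen <- w[w$type == "genotype", ]
S   <- as.matrix(gen[, paste0("IPC", 1:5)]); rownames(S) <- gen$code
round(waasb_weighted(S, ep)[c("G01", "G06")], 4)
#>    G01    G06
#> 0.0318 0.0536
```

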