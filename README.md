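# lfqnest

Differential-abundance analysis for label-free quantification (LFQ)
proteomics with **nested technical and biological replicates**, built for
two-factor injury-response designs such as the comparison of fetal and
adult cartilage secretomes after injury: 2 ages × 2 conditions
(control/injured) × 3 biological replicates × 2 technical replicates =
24 MS runs.

It is aimed at proteomics analysts who have a MaxQuant
`proteinGroups`-style intensity table and want the full statistical
pipeline — filtering, left-censored imputation, normalization,
nested-replicate linear models with second-level contrasts, moderated
tests, conservative FDR control, and the four-test Venn decomposition of
the resulting protein sets — as reusable, tested functions rather than a
one-off script. Because studies of this kind often deposit no raw
quantification matrix, the package ships a synthetic-data generator that
emulates the design with known ground truth, so every stage can be
validated end to end.

## The model

For protein *p*, the normalized log intensity of run *r* is modelled by
group means with a compound-symmetric block covariance:

- **Groups:** μ ∈ {Ac, Ai, Fc, Fi} (adult/fetal × control/injured).
- **Blocks:** the technical replicates of one biological replicate share
  a within-block correlation ρ, estimated once for all proteins
  (consensus correlation) and plugged into a per-protein GLS fit with
  working covariance σ²[(1−ρ)I + ρJ] on each block.
- **Contrasts:** adult response (Ai−Ac), fetal response (Fi−Fc), total
  response (their mean), the **second-level difference** (Fi−Fc)−(Ai−Ac)
  testing whether the injury response depends on age, and the baseline
  difference (Fc−Ac).
- **Moderated tests:** residual variances s²ₚ are shrunk by empirical
  Bayes toward a prior (d₀, s₀²) fitted by moment-matching log s² to a
  scaled F distribution; moderated t = β̂/(u·s̃), s̃² = (d₀s₀² + d s²)/(d₀+d),
  with d + d₀ degrees of freedom.
- **FDR:** Benjamini–Yekutieli step-up (valid under arbitrary
  dependence), applied per contrast family; proteins with q < 0.05 are
  called significant.

Preprocessing follows the published rules: decoy/contaminant removal, a
minimum of three identifications per protein, global ε-imputation with
ε = (minimum observed intensity)/4 — a pseudo-count that guarantees at
least a fourfold change against proteins unobserved in one group — log
transform, and mean log-shift normalization. Sample quality is
summarized by Spearman rank correlations between runs and
correlation-ellipse glyphs (x, y) = (cos(θ+d/2), cos(θ−d/2)) with
cos(d) = ρ.

## Worked example

The `analysis/` directory is a numbered workflow over the package. With
the package installed:

```sh
Rscript analysis/01_simulate.R        # study-scale synthetic experiment
Rscript analysis/02_preprocess.R
Rscript analysis/03_fit_models.R
Rscript analysis/04_decompose.R
Rscript analysis/05_sample_correlation.R
```

which prints (stage 1–3 excerpts):

```
simulated 2141 protein rows (25 decoy, 10 contaminant) x 24 runs
missing cells: 9.3%; true rho_block = 0.800
removed 25 reverse, 10 contaminant, 2 sparse rows; 2104 proteins kept
imputation epsilon = 88.63 (raw scale)
consensus within-block correlation: 0.503 (raw pooled r = 0.336)
empirical-Bayes prior: d0 = 1.31, s0^2 = 0.5444
  adult_response        138 significant (q < 0.05)
  ...
  adult_response       empirical FDR 0.007, recall 0.33
```

The consensus correlation (0.50) sits below the generator's uncensored
truth (0.80) because ε-imputed cells carry no replicate structure — the
vignette discusses this attenuation. The empirical FDR of every
significant set stays well under the nominal 0.05, and stage 5 confirms
the expected reproducibility ordering: technical-replicate pairs
(mean ρ = 0.96) correlate more strongly than biological replicates
(0.91), which exceed between-group pairs (0.73).

Equivalently, in R:

```r
library(lfqnest)
res <- run_pipeline(run_config(simulation = sim_config(n_proteins = 2106, seed = 1),
                               output_dir = "results/run1"))
res$summary$rho_block
res$partition$counts
```

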