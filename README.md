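# mrnadecay

Tools for modeling genome-wide variation in mRNA degradation rates in
budding yeast from transcript properties, and for estimating decay
constants of individual transcripts from transcriptional-shutoff qRT-PCR
time courses.

## The problem

Steady-state mRNA abundance reflects a balance between synthesis and
degradation, yet no single transcript property explains the wide
variation in degradation rates across a transcriptome. Properties tied
to translation — coding length, ribosome density, biased codon usage
(CAI, nTE), GC content at the codon wobble position (GC3), poly-proline
runs — are each weakly predictive, and many are correlated with one
another. The productive question is how much variation a *combination*
of properties explains, which calls for multiple regression with careful
predictor transformation, outlier handling, and model reduction.

`mrnadecay` implements that analysis as a reusable, tested pipeline:

- **Sequence features** — positional GC content (GC1/GC2/GC3), codon
  adaptation index, normalized translational efficiency, and
  poly-proline run classification, computed from coding sequences in
  FASTA.
- **Rate kinetics** — conversions between half-life and first-order rate
  constant (k = ln 2 / t½), growth-dilution correction
  (k_deg = k_obs − ln 2 / T_doubling), copy numbers from TPM assuming
  ~60,000 mRNAs per cell, and steady-state synthesis rates
  (synthesis = abundance × k).
- **Predictor table** — assembly of heterogeneous per-gene datasets into
  a gene × predictor matrix with declared log10 / log10(x+1)
  transformations and a Tukey-fence (1.5 × IQR) outlier filter on the
  response.
- **Regression modeling** — univariate screening at α = 0.05, backward
  and forward stepwise selection in which only significant terms are
  retained, AIC-based reduction, one-way ANOVA for categorical labels,
  a "model++" extension with GO SLIM / RNA-binding-protein indicator
  columns, Wilcoxon rank-sum group comparison, and residual-outlier
  characterization.
- **qPCR decay** — delta-Ct quantification against a reference gene
  (Y = 2^(ct_ref − ct_gene)), normalization to t = 0, log-linear decay
  fitting over all replicate points, case-resampling bootstrap 95%
  confidence intervals, and pairwise comparison of decay constants.
- **Synthetic data** — generators for coding sequences with controlled
  GC3 and planted poly-proline runs, predictor tables with known linear
  structure and target R², categorical effects, and Ct time courses
  from known decay constants, so every stage is testable against ground
  truth.

The model is ordinary least squares on transformed predictors,

    k_i = β₀ + Σ_j β_j x_ij + ε_i,   ε_i ~ N(0, σ²),

with the degradation rate constant k (min⁻¹, approximately normal)
untransformed, and variance decomposition reported as univariate and
model R².

## Worked example

Generate a genome-scale synthetic dataset with a known target R² of
0.43, filter the response, screen predictors, and build the reduced
model:

```r
library(mrnadecay)

sim      <- sim_predictor_table(n_genes = 4000, seed = 1)
filtered <- filter_response(sim$table)
screen   <- univariate_screen(filtered)
head(screen, 4)
#>          predictor r_squared   p_value sign    n
#> 1    coding_length    0.1770 2.92e-170    +  3975
#> 2 ribosome_density    0.0825  2.17e-76    -  3975
#> 3              cai    0.0540  6.63e-50    -  3975
#> 4              gc3    0.0359  1.76e-33    -  3975

model <- backward_stepwise(filtered, screen = screen)
model
#> <rate_model> 6 term(s), n = 3975, R^2 = 0.3948 (adj 0.3939), AIC = -16322.6
```

Coding length is the strongest single predictor (sign `+`: longer
transcripts degrade faster), while ribosome density, CAI, and GC3
associate negatively with degradation rate; the combined model explains
far more variance (R² ≈ 0.39 after outlier filtering) than any single
predictor.

Fit shutoff qPCR time courses for three reporter constructs and compare
their decay constants:

```r
q   <- sim_qpcr(seed = 1)              # known k: 0.060, 0.040, 0.025 min^-1
res <- qpcr_pipeline(q$ct_table, n_boot = 1000, seed = 2)
res$fit_table
#>   gene      k half_life ci_low ci_high n_boot seed n_points
#> 1 GFP2 0.0683      10.1 0.0585  0.0819   1000    2       18
#> 2 GFP3 0.0342      20.2 0.0251  0.0429   1000    3       18
#> 3 GFP4 0.0174      39.9 0.0121  0.0216   1000    4       18

res$comparisons
#>   gene_a gene_b delta_k  ci_low ci_high significant
#> 1   GFP2   GFP3  0.0341 0.02072  0.0517        TRUE
#> 2   GFP2   GFP4  0.0509 0.03965  0.0656        TRUE
#> 3   GFP3   GFP4  0.0169 0.00684  0.0270        TRUE
```

Each fit reports the decay constant k (min⁻¹), the implied half-life
(ln 2 / k), and a bootstrap 95% CI; all three pairwise rate differences
are resolved at this noise level.

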