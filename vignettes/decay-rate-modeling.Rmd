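---
title: "Modeling mRNA degradation rates from transcript properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mRNA degradation rates from transcript properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrnadecay)
```

## The model

The quantity being modeled is the first-order mRNA degradation rate
constant $k$ (min$^{-1}$), related to the half-life by
$k = \ln 2 / t_{1/2}$. Across a yeast transcriptome $k$ is
approximately normally distributed, so it enters the regression
untransformed, as the response of an ordinary least-squares model

$$k_i = \beta_0 + \sum_j \beta_j x_{ij} + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma^2),$$

over transformed transcript properties $x_{ij}$. Many predictors
(coding length, UTR lengths, abundance, protein per cell, transcription
rate, protein half-life) are approximately log-normal and are
$\log_{10}$-transformed — or $\log_{10}(x + 1)$ where zeros are
legitimate values (UTR lengths, ribosome density as RPKM). Proportions
(GC by codon position, UTR GC), nTE, and the folding energy $\Delta G$
(negative by construction) stay untransformed. Each column of a
`predictor_table` carries its transformation as metadata so the fitting
code, not the caller, owns this bookkeeping.

Rates measured in growing cultures by metabolic labeling include a
dilution component from cell division. `correct_for_dilution()` treats
the observed loss rate as $k_{obs} = k_{deg} + \ln 2 / T$ for doubling
time $T$ and subtracts the growth term. The doubling time is a required
input — it is a property of the culture, not of the data — and corrected
rates that come out non-positive are flagged as missing rather than
raising an error, so bulk assembly of published tables is robust to a
handful of very stable transcripts.

Copy numbers are estimated from TPM as the transcript's share of the
mRNA pool scaled by a per-cell total, $c = (\mathrm{TPM}/10^6) \times
60{,}000$, using the commonly assumed ~60,000 mRNAs per yeast cell. The
printed form of this scaling in published tables is ambiguous
("TPM/total reads"); the pool-share reading is the only one with the
right units and is documented here deliberately. At steady state,
synthesis balances degradation, so per-gene synthesis rates are
$\mathrm{abundance} \times k$.

## Sequence features

**CAI.** The codon adaptation index is the geometric mean of relative
adaptiveness weights $w$, where $w$ is a codon's frequency relative to
the most-used synonym of its amino acid in a reference set. Following
the standard convention (the one the seqinr implementation uses), stop
codons and the single-codon amino acids Met (ATG) and Trp (TGG) — whose
$w$ is 1 by construction and would only dilute the signal — are
excluded. The mean is computed in log space; a test verifies agreement
with seqinr's `cai()` to 10 decimal places. Zero-count codons in the
usage table receive a pseudo-count (default 0.5) before normalization
so that $w > 0$ and CAI stays strictly positive.

**GC by position.** GC1/GC2/GC3 are the proportions of G/C at the
three codon positions. The terminal stop codon is excluded by default:
GC3 is interesting because of wobble-position decoding, which stop
codons do not undergo. An `include_terminal_stop` flag restores the
naive count for comparison with conventions that include it.

**nTE.** The normalized translational efficiency weight of a codon
balances usage demand against tRNA supply. The per-transcript
aggregation is not standardized anywhere; this package uses the
arithmetic mean of per-codon weights (with a geometric-mean option),
the natural choice for a quantity already on a normalized linear scale.

**Poly-proline.** A transcript is classified poly-proline when at least
four consecutive proline codons (CCA/CCC/CCG/CCT of the standard code)
occur in frame — consecutive prolines stall peptide-bond formation.
The run length is a parameter (`min_run = 4`); alternative genetic
codes are out of scope.

## Outlier filtering and model building

Extreme rate constants distort least squares, so before fitting, the
response passes a Tukey-fence filter: values outside
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ are excluded.
On a normal response this removes well under 1% of genes. Quartiles use
linear interpolation (R's quantile type 7) for cross-platform
determinism. The filter is single-pass — fences are computed once on
the input — and two-sided by default; because rate constants are
bounded below by zero, a `one_sided_upper` mode is available. Filtering
happens on the response before any model is fitted; predictors are
never filtered, and missing predictor values are handled per-model as
complete cases (as `lm` would), never by global row deletion.

Model building offers the two classical routes, both starting from a
univariate screen of every predictor against the response at
$\alpha = 0.05$ with no multiple-testing correction (screening is a
gate, not an inference):

- **Backward**: start from all screened predictors, repeatedly refit
  and drop the highest-p term while any term has $p \ge \alpha$.
- **Forward**: add predictors in order of ascending univariate p. A
  newly added term that is not significant is removed again; if an
  addition makes an existing term non-significant, the two competing
  models (with the new term, or with the displaced one) are compared
  and the one with the higher $R^2$ kept. Predictors that failed the
  screen are never added.

Term significance uses the coefficient t-test; for main-effects models
this is equivalent to the drop-one F-test, so only one is implemented.
Ties in removal/addition order break alphabetically so runs are exactly
reproducible. `aic_reduce()` provides the third standard route — greedy
backward elimination minimizing AIC (as computed by `stats::AIC`,
pinned only up to the additive constant that cancels in comparisons) —
and a test confirms it selects the same terms as `stats::step`.

On well-separated designs with five or fewer candidates, backward
selection provably coincides with exhaustive best-subset search under
the same all-terms-significant rule; the test suite verifies this on
100 seeded designs.

Categorical structure (GO SLIM terms, RNA-binding-protein target sets)
enters in two ways: a one-way ANOVA ($R^2$ = between-group SS / total
SS) for a single labeling, and the "model++" extension, which refits
the reduced continuous model plus one 0/1 indicator column per label.
Genes may carry several labels, so indicators — not a forced single
label per gene — are the default representation. Labels with fewer
than 10 member genes (configurable) are dropped to avoid degrees-of-
freedom explosion. Both models are evaluated on identical complete-case
rows, so the extension can never lose $R^2$, and the gain is tested
with a nested-model F-test.

Residual outliers are genes whose residual exceeds the mean residual by
more than 2 SD — one-sided, because with $k$ as the response these are
the transcripts degrading faster than their properties predict — and
their feature medians are contrasted with the rest on the transformed
scale.

## qPCR shutoff analysis

After transcriptional shutoff, relative abundance is quantified against
a co-amplified reference gene as $Y = 2^{(ct_{ref} - ct_{gene})}$,
assuming amplification efficiency 2 exactly (measured efficiencies are
metadata, not model inputs). Protocols are sometimes written with the
exponent reversed; since a decaying transcript must show decreasing
$Y$, the standard orientation is the default and the reciprocal form is
available as `convention = "as_printed"`, with the choice recorded in
all outputs. Each replicate is normalized to its own $t = 0$ value
(set exactly to 1), then the decay constant is estimated by unweighted
least squares of $\ln Y$ on time over **all** replicate points — not on
per-time means — though means ± SEM are exported for plotting. A
non-positive estimated $k$ (no decay) is flagged rather than rejected.

Uncertainty comes from a case-resampling bootstrap of the
$(t, \ln Y)$ points with percentile 2.5/97.5 intervals (default 1000
resamples; a seed is mandatory and recorded). Resamples that collapse
onto a single time point are redrawn. Slopes are computed in closed
form on an index matrix, which keeps 1000 resamples per fit effectively
free. Two constructs are compared through the paired difference of
their bootstrap draws; a 95% interval on $\Delta k$ excluding zero is
flagged significant. Coverage of the percentile interval is validated
by simulation (see below).

## What the synthetic generator emulates — and what it does not

The generators reproduce the statistical structure the analysis
assumes, with defaults fixed once as the study conditions:

- `sim_predictor_table()`: predictors multivariate normal on the
  transformed scale (the empirical motivation for log transforms),
  back-transformed to original units; response
  $k = \beta_0 + \sum\beta_j z_j + \varepsilon$ built from
  standardized predictors. Defaults: 4000 genes (the typical
  complete-case scale of genome-wide yeast datasets), mean rate 0.12
  min$^{-1}$, per-SD effects of 0.006–0.018 min$^{-1}$ with signs
  matching the biology (longer transcripts faster, translated/optimized
  transcripts slower), and a target $R^2$ of 0.43 from which $\sigma$
  is solved via the realized signal variance. The rare non-positive
  simulated rate becomes missing, matching the response invariant.
- `sim_cds()`: per-codon sampling tilted toward G/C-ending synonyms to
  hit a GC3 target within ±0.02 per gene (rejection sampling), with
  ATG/stop bookends and poly-proline runs planted in a declared
  fraction; unplanted genes are redrawn if a run arises by chance, so
  the truth labels are exact. Feasible GC3 under uniform amino-acid
  usage is about [0.10, 1] — Met and Trp pin the lower end.
- `sim_qpcr()`: $ct_{gene}(t) = ct_0 + k\,t/\ln 2 +
  N(0, \sigma_{ct})$, reference Ct constant plus the same noise —
  Gaussian on the Ct scale, hence multiplicative on abundance, matching
  qPCR error behavior. Defaults: constructs with $k$ = 0.060, 0.040,
  0.025 min$^{-1}$ (half-lives ≈ 12–28 min, reporter-like), times 0–30
  min, 3 replicates, Ct noise SD 0.2.

What the generators do **not** emulate: real codon usage and amino-acid
composition (uniform amino acids), secondary-structure constraints,
heteroskedastic or outlier-prone measurement error in the genome-wide
datasets, gene-length-correlated coverage differences, identifier
mapping issues, or shared regulation that correlates the response
beyond the planted categorical shifts. Passing tests therefore
demonstrate that the *pipeline* is correct and calibrated under its own
assumptions — not that those assumptions hold for any particular real
dataset.

## Validation problem sizes

The test suite validates, among others: CAI against a brute-force
count-based oracle on 1000 random sequences (to $10^{-12}$); backward
stepwise against exhaustive best-subset on 100 seeded 5-candidate
designs at $n = 300$; realized model $R^2$ within [0.38, 0.48] of the
0.43 target over 100 seeds at $n = 4000$; 95% CI coverage of true
coefficients over 500 replicates at $n = 1000$; exact decay recovery
from noiseless Ct fixtures and a pooled median relative error below 10%
over 500 noisy replicates of the default shutoff design; bootstrap CI
coverage within [90%, 98%] over 500 datasets; and uniformity of screen
p-values (Kolmogorov–Smirnov) plus calibrated model++ F-tests under a
zero-effect null. `scripts/acceptance.R` re-runs the same computations
from scratch at these sizes and writes the measured values as JSON.

## Design decisions and limitations

- The workflow surface is a set of R functions (`run_features`,
  `run_model`, `run_qpcr`) writing TSV outputs plus a JSON manifest
  (configuration, seeds, package version) for reproducibility; run
  configuration lives in ordinary function arguments rather than a
  separate config-file format, since the natural caller is an R script
  that is itself version-controlled.
- Only main-effects linear models are supported: no interactions,
  regularization, or nonlinear terms. With thousands of genes and a
  dozen predictors, OLS is the transparent choice and matches how the
  field reports variance decomposition.
- The dilution correction assumes additive rates (exponential growth,
  first-order decay); non-steady-state cultures violate this.
- Multi-reference qPCR normalization and efficiency-corrected (Pfaffl)
  quantification are out of scope; with efficiency near 2 the
  single-reference delta-Ct model is standard.
- The bootstrap treats points as exchangeable; replicate-level
  clustering (resampling whole replicates) would widen intervals
  slightly and could be added where replicate effects dominate.
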