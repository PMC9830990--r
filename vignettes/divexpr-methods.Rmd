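---
title: "divexpr: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{divexpr: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divexpr)
```

`divexpr` analyses replicated experimental-evolution RNA-seq designs: two
selection regimes (E = early reproduction, L = late reproduction), several
independently evolving replicate lines per regime, two sexes, and one
pooled library per line × sex × tissue (reproductive abdomen vs somatic
head/thorax). This vignette documents the statistical models, the defaults
and why they were chosen, what the synthetic generator does and does not
emulate, and the numerical corner cases.

## Count model and differential expression

Counts are modelled per gene as negative binomial,
$y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi_g)$ with
$\mathrm{Var} = \mu + \phi\mu^2$ and
$\log \mu_{gs} = x_s^\top\beta_g + o_s$, where the offset $o_s$ is the log
effective library size (raw size × TMM factor). Within a tissue the mean
model is the one-way layout on the four regime × sex cells; every pairwise
contrast (E vs L within each sex, M vs F within each regime) is tested by a
likelihood-ratio test against the design that merges the two contrasted
cells, and the sex-by-regime interaction by comparing the 4-cell model to
the additive regime + sex model (1 df). Fitting is iteratively reweighted
least squares with working weights $\mu/(1+\phi\mu)$, convergence when the
relative deviance change is below 1e-8 (cap 50 iterations); non-converged
genes are flagged and excluded from calls.

Dispersions are estimated by Cox–Reid adjusted profile likelihood: a common
value maximizing the summed APL, then per-gene (tagwise) values shrunk
toward the common one with a fixed prior weight (default 10
genes-equivalent degrees of freedom). We deliberately use *no* abundance
trend: the shrinkage target is a single common dispersion, which is the
simplest model consistent with a moderate number of libraries, and the
prior weight is exposed (`prior_weight`; 0 = no shrinkage, large values
collapse all genes onto the common value). This stage is delegated to
edgeR's Cox–Reid routines; everything else (TMM, GLM, LRT, multiplicity,
calls) is implemented in the package and cross-checked against independent
oracles in the test suite.

A gene is called differentially expressed at BH $q < 0.05$ **and**
$|\log_2 FC| > 1$, both inequalities strict; the fold-change floor guards
against calls driven by tissue-scaling effects. Contrast log2FCs are
computed from a refit on prior-augmented counts (0.5 per mean-relative
library) so that empty cells give large finite, rather than infinite,
estimates; p-values always come from the unaugmented fits. Sign
conventions, fixed globally: sex effects are male − female (so FB genes
have negative sex log2FC), regime effects are L − E.

With only four replicate lines per regime, lines are the biological
replicates and genes are treated as independent observations in the
downstream proportion, median and correlation tests — as the large degrees
of freedom of such analyses imply. That ignores gene–gene correlation, so
those p-values are calibrated per gene-set comparison, not
experiment-wide.

## Filtering and normalization

Genes are kept when strictly more than 2 cpm (raw library sizes, single
pass) is seen in at least 3 samples. Filtering precedes normalization and
is applied per analysis subset (each tissue separately) in `run_de()`; the
pipeline's repeatability stage filters once globally because the
ordination uses all samples jointly.

TMM follows the canonical recipe: reference = sample whose 75th-percentile
count proportion is closest to the mean; M/A values over genes positive in
both; 30%/5% two-sided trims; precision-weighted mean of the surviving M
values; factors rescaled to geometric mean 1. Two numerical notes
established while testing:

* TMM is *not* exactly invariant to rescaling a single sample's counts —
  the M values are, but the delta-method precision weights depend on
  library size. The shift is small (≲0.01 in our property tests) and is the
  behaviour of the canonical algorithm, which we match to <1e-9.
* Log2-cpm uses a prior count proportional to the effective library size in
  *absolute* terms (`prior_count` per million reads, default 0.5/1e6 of
  the library). This makes the transform exactly invariant to sequencing
  depth (doubling counts and libraries leaves values unchanged), at the
  price of a somewhat stronger prior than edgeR's mean-relative 0.5 on deep
  libraries. The alternative (mean-relative prior) breaks exact depth
  invariance; we preferred the exact identity since log-cpm here feeds
  distance geometry and average-expression comparisons, not fold-change
  estimation.

## Multivariate repeatability

One PCA is fitted on all samples jointly (covariance matrix, centered, not
scaled — expression changes are kept on their log2 scale rather than
variance-standardized per gene). The first k = 16 components are retained
by default, which for the reference 32-sample layout captures the
dominant half of the spectrum while dropping the noise floor; k is capped
at samples − 1 and configurable, since synthetic designs may be smaller. For a group (regime × sex × tissue):

$$R = \frac{D}{D + d}$$

with D the Euclidean distance between the E and L centroids of that sex ×
tissue stratum and d the mean distance of the group's replicate samples to
their own centroid. R is invariant to rotation, translation and scaling of
the score space (property-tested), lies in [0, 1], is defined as 0 in the
fully degenerate D = d = 0 case, and both regimes of a stratum share the
same D by construction. A worked anchor: d = D/2 gives R = 2/3 ≈ 0.66 —
replicates half as far from their own average as E is from L.

Confidence intervals resample *genes* with replacement (default 1000
replicates, percentile 2.5/97.5). Resampling the 4 replicate samples per
group is too degenerate to be the default but is available
(`boot_unit = "samples"`). The PCA is refitted in every replicate by
default (the more honest propagation of ordination uncertainty);
`refit_pca = FALSE` computes distances directly in the resampled gene
space. The percentile CI is clamped to [0, 1] and to contain the point
estimate.

## Sexualization analyses

Per regime, a gene is FB/MB/UB by the same q-and-fold-change rule applied
to the sex contrast; "sex-biased" for downstream comparisons means biased
in either regime. Proportion comparisons use the Pearson chi-square on the
2×2 table without continuity correction, the classical large-sample choice
for gene-count tables of this size; Yates is available behind a flag.
Median-expression shifts between regimes use the Brown–Mood two-sample
median test — the canonical median test with a simple signed normal
approximation — with a percentile bootstrap CI of the median
difference (genes resampled; default 10000 replicates). A Wilcoxon
rank-sum variant (`method = "wilcoxon"`) and a paired sign-test variant
(`paired = TRUE`) are provided. The sex-bias correlation between regimes is
Pearson's r over the biased-in-either union with a Fisher-z CI and df =
n − 2.

Candidate genes come from a 12-column tabular homology scan: per query the
best hit minimizes e-value, ties broken by maximal bit score, then by
first occurrence. Candidate and sex-bias enrichment among DE genes use the
2×2 chi-square; gene-set over-representation uses the one-sided upper-tail
hypergeometric per term with BH across terms. The gene universe is always
the set of genes passing the expression filter in the analyzed condition.
The conditional (DAG-aware) test some GO tools apply is intentionally not
implemented; with annotation supplied as flat GMT gene sets, parent–child
redundancy between terms is the user's responsibility.

## Divergence curve

Lifespan divergence over time is modelled as $Y = 1 + a(1 - b^X)$: Y(0) = 1
(no divergence at the start), asymptote 1 + a, rate b ∈ (0, 1) with
smaller b meaning faster saturation. Fitting is Levenberg–Marquardt on the
analytic Jacobian, b clamped inside (0, 1); starts are a₀ = max(Y) − 1,
b₀ = 0.5; failure to converge in 200 iterations is an error with
diagnostics. Standard errors are the usual asymptotic
$s^2 (J^\top J)^{-1}$. Between-sex comparisons use
$t = (\hat\theta_F - \hat\theta_M)/\sqrt{SE_F^2 + SE_M^2}$ with
Welch–Satterthwaite degrees of freedom from the two residual dfs — the
natural construction when only per-sex fits are available. Perfect
(zero-residual) fits have numerically zero SEs; comparison then errors and
advises exact comparison, rather than producing 0/0. X is taken in
whatever time unit the input provides.

## The synthetic generator: what it emulates and what it does not

`simulate_dataset()` draws, per gene: a baseline log2 abundance
(Normal(5, 2)), a head/thorax shift (Normal(0, 1)), a dispersion
(log-normal, median 0.05, log-sd 0.5), and per tissue: sex-biased status
(35% abdomen, 5% soma), regime-DE status (6%), interaction status (0.5%),
with |log2FC| = 1 + Exponential(1) and random signs; interaction genes get
independent per-sex regime effects. Line random effects are
Normal(0, σ²_line) per gene × line with σ_line = 0.15 — no between-line
variance estimate is available for this kind of system, so this default
was chosen once as a value that yields repeatabilities in the plausible
0.6–0.75 range and is documented as a free parameter. Library sizes are log-uniform
on [5e6, 2e7]; expected counts are the library size times softmax-
normalized 2^η, then NB sampled (Poisson at φ = 0). Identical seeds give
bit-identical data; `simulate_null()` zeroes all systematic effects but
keeps line effects and dispersions.

What the generator does **not** emulate: GC/length biases, read-level
noise, batch effects, correlated gene modules, compositional antagonism
beyond the softmax constraint, or mapping artifacts. A green test therefore
establishes that the *statistical pipeline* behaves as specified under the
assumed NB world, not that any biological claim about real libraries is
reproduced.

Two measured consequences of the stated world are worth knowing. First,
the heavy abundance tail (log2 sd = 2, plus exponential effect sizes) lets
single genes carry several percent of a library, so NB noise on those genes
alone moves realized column sums a few percent away from the requested
library sizes; column-sum fidelity to <1% holds only under a lighter tail
and small dispersion, which is how the corresponding property is tested.
The same mechanism (plus line effects shifting library composition) moves
TMM factors a few percent away from 1 even in null data — TMM is correctly
absorbing real composition changes. Second, with line effects on, the
common-dispersion estimator recovers the *effective* dispersion
φ + (ln2·σ_line)², not φ alone — the estimator is unbiased for the
variation actually present; recovery checks therefore set σ_line = 0.

## Runtime and determinism

All stochastic stages take explicit seeds and restore the caller's RNG
state. The acceptance suite runs the spec's criteria at the example sizes
stated there (600–2000 genes per simulated dataset, 5–10 seeds, 500
curve-fit replicates), which keeps the full test run under ~2 minutes on
one CPU while using the stated effect sizes, dispersions and thresholds
unchanged. The pipeline writes per-stage TSVs, a MANIFEST of completed
stages and a summary.json that is a pure function of (config, seed).

## Known limitations

* No quasi-likelihood F-tests, robust dispersion outlier handling or
  voom-style precision weights; with n = 4 lines per regime the LRT is
  mildly liberal (null p < 0.05 fraction ~0.05–0.07 in our checks, inside
  the spec's sanity band).
* Enrichment assumes flat gene sets; no ontology DAG handling.
* The divergence-curve module fits per-sex curves from a single series per
  sex; replicate-line-level curve fitting is not implemented (no
  line-level data model is defined for this input).
* `boot_unit = "samples"` with 4 lines per group is statistically
  degenerate and provided only for comparison.
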