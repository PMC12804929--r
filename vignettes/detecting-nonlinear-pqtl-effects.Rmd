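---
title: "Detecting non-linear genetic and covariate effects on quantitative molecular traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-linear genetic and covariate effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Protein quantitative trait locus (pQTL) studies usually model a molecular
trait — say, a plasma protein level on a log-like NPX scale — as a *linear*
function of allele counts plus covariates. That model is blind to three kinds
of structure that are biologically common: **dominance** (the heterozygote
mean deviating from the midpoint of the homozygote means), **epistasis**
(the effect of one locus depending on the genotype at another, e.g. the
classic ABO x FUT2 secretor-status interactions), and **non-linear covariate
effects** (e.g. hormone levels as a step-like function of age gated by sex).

`pqtlgap` operationalizes a simple detection idea: fit a flexible non-linear
genomic predictor and a penalized linear baseline on the same data, and treat
a statistically robust *performance gap* on held-out samples as evidence of
non-linear structure. The gap is then *decomposed* with targeted analyses —
covariate-only models, one-hot re-encoding, per-genotype OLS, a pairwise
interaction scan, staged boosted models, and an iterative complexity ladder —
to say *which kind* of non-linearity is responsible.

## The models

**Linear baseline.** An elastic net over additively coded dosages and
covariates, fit with `glmnet` under k-fold cross-validation over the mixing
grid alpha in {1e-4, 1e-3, 1e-2, 1e-1, 1} with a lambda path (200 values) per
alpha; the per-fold winners are ensembled by averaging their predictions.

**Non-linear predictor.** A locally connected feed-forward network on one-hot
genotype encodings: each window of 4 consecutive variants (16 one-hot
columns) feeds 4 private hidden units (no weight sharing), after which two
dense ReLU layers of width 128 (dropout 0.1) receive both the genotype
features and the standardized covariates. Three additions, made as this
package's own design choices, matter for desk-scale training and are worth
stating explicitly:

* a **linear residual shortcut** from all inputs straight to the output, so
  the additive polygenic component is representable exactly;
* a **zero-initialized output layer**, so optimization starts from the pure
  linear model and the hidden path grows only where linearity leaves
  residual signal;
* decoupled **weight decay** (AdamW-style, default 1e-3) alongside early
  stopping on a held-out validation set (patience 10 checks).

Without these, a network of this size reliably *loses* to the elastic net on
purely additive traits at n of a few thousand, which would make every
detected "gap" uninterpretable. With them, the network matches the elastic
net within a few hundredths of R-squared on additive simulations and
decisively beats it when dominance or epistasis carries a sizeable share of
the trait variance (the test suite asserts both directions).

**Attribution.** Integrated gradients along the straight path from an
all-zeros one-hot baseline (covariates at their training means) with a
midpoint Riemann sum. For our piecewise-linear (ReLU) networks the sum
converges at rate 1/n_steps, so the completeness identity — attributions
summing to f(x) − f(baseline) — is checked at n_steps in the thousands;
for affine networks the rule is exact at any n_steps, which the tests use as
a closed-form oracle. Per-variant importance is the mean over validation
samples and the variant's four columns of absolute attributions.

**Boosted models for decomposition.** A compiled histogram gradient booster
(squared loss, depth-3 trees, 32 quantile bins, learning rate 0.1, early
stopping) supports *feature-interaction constraints* over disjoint groups:
once a tree path splits on a feature from one group, descendants stay inside
it. The three stages of the decomposition map onto group structures: `base`
(each variant alone; covariates together), `plus_gxg` (variants may
interact), `plus_gxe` (unconstrained). A single-feature tree can still fit
per-genotype steps, so the `base` stage *bounds* rather than exactly matches
linear-in-dosage behaviour — an acknowledged approximation.

## Pipeline protocol

Per trait: a GWAS scan (OLS per variant with covariates via Frisch-Waugh
residualization) on the training rows only pre-filters variants at p < 1e-3;
runs 1–3 train the network on all pre-filtered variants with distinct seeds;
attributions from those runs rank variants; one Bayesian-optimization pass
(Gaussian-process surrogate, expected improvement on a dense grid) picks the
top-fraction that maximizes validation R-squared; runs 4–10 train on that
subset; the ensemble prediction is the mean over all 10 test predictions.
The BO result is shared by runs 4–10 rather than recomputed per run (the
protocol is ambiguous on this; one pass is the cheaper reading and keeps the
run count interpretable). The linear baseline sees *all* QC-passed variants,
not the pre-filtered subset — an asymmetry preserved deliberately, since the
baseline's regularization handles the full set. A small-cohort variant uses
20 runs, ranks variants by GWAS p-value, and seeds BO with the fractions of
pre-filtered variants passing p-value thresholds 1e-8 ... 1e-4 before free
search.

Test rows are touched only for final predictions; the result object carries
an instrumentation record (`rows_touched`) asserted by the tests.

## Gap statistics

The paired bootstrap (n = 1000) resamples test indices once per replicate and
applies them to *both* models' predictions — pairing is required for the
empirical p-value (the proportion of resamples where the flexible model's
R-squared is at most the linear model's) to be coherent. Significance is
non-overlap of the two 95 percent percentile CIs with the flexible model
ahead. Empirical p-values are BH-adjusted across traits; exact zeros are
clipped to 1/n_boot only inside the adjustment, since BH on exact zeros is
degenerate. Gap-source classification compares the full-model gap with the
covariate-only gap: if the latter reaches the former minus delta, where delta
is the half-width of the full gap's bootstrap CI, the non-linearity is
attributed to covariates (the original display is visual; the delta rule is
this package's explicit rendering). In transfer evaluation a group's gap is
set to 0 when both models have negative mean R-squared — no meaningful
comparison exists below the mean-predictor floor. Replication proportions get
Clopper-Pearson exact intervals via beta quantiles.

The iterative complexity ladder refits a linear model as terms are added
(covariates, additive genotypes, squared/log covariates, one-hot genotypes,
ExE, GxE, GxG products) and records validation R-squared changes. Expanded
designs are exactly collinear by construction (additive = het + 2 x hom), so
fits use a tiny ridge (1e-8 per unit-variance column, scaled by n) on
standardized columns — a numerical stabilizer, not a modeling choice.

## The synthetic-data generator

`simulate_genotypes` draws Hardy-Weinberg genotypes at MAFs uniform in a
configurable range (default 0.05–0.5). LD blocks use a first-order
copy-with-mutation process on haplotypes: within a block each haplotype
copies the previous variant's allele with probability `ld_decay` (default
0.8). When blocks are enabled, one MAF is drawn *per block* so each variant's
marginal frequency equals its recorded MAF exactly; with per-variant MAFs the
copy process would blend neighbouring frequencies. Missingness is completely
at random (the real mechanism is unspecified). Covariates emulate the usual
block: uniform age (40–70), balanced binary sex, a 5-level center factor, a
90/10 genotyping-array factor, and standard-normal PCs.

`simulate_trait` sums additive effects (per effect-allele count), dominance
specified as *genotype-class means* (matching how dominance is displayed in
practice), 3x3 genotype-combination tables for epistasis, dosage x covariate
(GxE) and covariate x covariate (ExE) products, arbitrary named covariate
functions, and Gaussian noise; the returned ledger reports each component's
empirical variance. The optional `log2like` scale applies
sign(y) * log2(1 + |y|) after summation — a monotone warp chosen only to
create the linear-versus-log mismatch that inverse-rank normalization (INT)
probes; it is *not* a model of NPX measurement noise, for which no generative
form is published.

What a green test does and does not establish: the generator produces
independent (or block-LD) HWE genotypes, homogeneous samples, and planted
effects of known form. Real cohorts add population structure, cryptic
relatedness beyond the QC threshold, batch effects correlated with traits,
and platform-specific measurement error; detection power and false-flag
rates measured here do not automatically transfer to those settings.

## Numerical and procedural choices

* PLINK boundary semantics: `mind`/`geno` remove strictly greater
  missingness, `maf` keeps frequencies at or above the threshold, `hwe`
  removes p strictly below; kinship pruning is greedy (repeatedly drop the
  sample with most remaining above-threshold pairs, ties to the smaller
  index). Filters run in the order kinship, mind, geno, hwe, maf, and the
  report reconciles exactly at each step.
* The HWE exact test uses the plain (not mid-p) conditional formulation via
  the stable mode-outward recurrence; the tail rule includes probabilities
  within a 1e-9 relative slack of the observed one so exact ties (symmetric
  configurations) are counted regardless of floating-point rounding.
* INT uses the Blom offset 3/8 with average ranks for ties; missing values
  stay missing; all-identical input is an error.
* The per-genotype ("one-hot") association model drops the
  homozygous-reference indicator: the published formula lists an intercept
  plus all three class indicators, which is rank-deficient. The dominance
  contrast tests beta_het − beta_hom_alt / 2 = 0.
* The interaction model uses one-hot main effects and a single product of
  additive codings (the formula's single beta3 term); collinear pairs are
  skipped and logged. Both Bonferroni denominators are supported: pooled
  across traits (0.05 / 1,389,888 for 171 traits x 8,128 pairs) and
  per-family via `n_comparisons`.
* All randomness flows from explicit seeds; per-run pipeline seeds are
  base_seed + run_index; reruns from a result's config snapshot reproduce
  predictions bit-for-bit on the same platform.
* The CLI (`inst/cli/complexpqtl`) takes JSON configs (no YAML parser is
  assumed in the runtime environment) and logs line-delimited JSON.

## Known limitations

The network is a desk-scale stand-in for large published genotype
architectures: CPU training, no GPU path, and hyperparameters chosen for
n in the thousands. The booster's `base` stage only bounds linearity (see
above). The generator does not simulate admixture, imputation dosages, or
sequence-level data. Mixed-model association is out of scope — relatedness
is handled by QC pruning, not by the test itself.
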