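---
title: "Methods: cross-ancestry drug-target MR with correlated instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-ancestry drug-target MR with correlated instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmr)
```

## The estimand: biomarker-weighted drug-target effects

`crossmr` implements drug-target (cis) Mendelian randomization from
regional GWAS summary statistics, compared across two ancestry groups.
The data-generating model it assumes — and that its simulator
implements — is a path model: genetic variants $G$ in and around the
target's gene act on the protein $P$ with per-variant effects $\delta$;
$P$ acts on a downstream biomarker $X$ with effect $\mu$ (biomarker-SD
per protein-SD); $X$ acts on the outcome $D$ with effect $\theta$; $P$
may also act on $D$ directly, bypassing the biomarker, with effect
$\phi_P$; and a latent confounder $U$ loads on $P$, $X$ and $D$. The
total protein effect on the outcome is

$$\omega = \mu\theta + \phi_P.$$

When instruments are weighted by their association with the *biomarker*
(the common situation when no well-powered protein GWAS exists in one of
the populations), the MR slope targets

$$\omega_{bw} = \frac{\omega}{\mu} = \theta + \frac{\phi_P}{\mu},$$

not $\theta$: the estimand is the target's total effect rescaled by the
protein-to-biomarker effect. Two consequences matter and are both
asserted by the test suite. First, $\omega_{bw} = 0 \iff \omega = 0$, so
the biomarker-weighted analysis is a valid null-hypothesis test for the
protein even when the biomarker itself is not causal. Second, a
cross-ancestry comparison of $\omega_{bw}$ between groups $j$ and $k$ is
a valid test of $\omega_j - \omega_k = 0$ *only if* $\mu_j = \mu_k$;
when the protein-to-biomarker effects differ, the type-I error of the
interaction test inflates even with identical protein effects. This is
why the package classifies *directional discordance* separately: if one
is only willing to assume $\mathrm{sign}(\mu_j) = \mathrm{sign}(\mu_k)$,
opposite-signed replicated effects remain interpretable.

## Instrument selection

`select_instruments()` composes, in order: allele harmonization of the
exposure and outcome sets, alignment to the LD matrix (with sign flips
where the LD reference allele is the other allele), restriction to the
gene region with flank (inclusive bounds, 1-based GRCh37), a
minor-allele-frequency floor (`maf_min`, default 0.01), an
instrument-strength floor on the marginal Wald statistic
$F = (\beta/\mathrm{se})^2$ (`f_min`, default 15), and greedy LD
clumping at `r2_max` (default 0.3) ranked by the exposure p-value with
deterministic tie-breaks (smaller position, then lexicographic id).
Clumping runs last and per ancestry, with that ancestry's LD panel, so
the surviving variant set may legitimately differ between outcome GWAS —
the chain is re-run per exposure–outcome pair rather than fixing one
variant list. A filter log accounts for every removal; its counts
reconcile exactly with input and output sizes.

Harmonization policy for strand-ambiguous (A/T, C/G) variants is
configurable because conventions differ between pipelines: the default
drops a palindromic variant when either trait's effect-allele frequency
is within 0.08 of 0.5 and otherwise resolves orientation by frequency;
`"frequency"` always resolves; `"keep"` trusts the literal allele match.

## GLS estimation under residual LD

Because cis instruments are deliberately allowed to remain in moderate
LD ($r^2 < 0.3$), the sampling errors of the per-variant outcome betas
are correlated. Both estimators therefore work in generalised least
squares form with

$$\Sigma = D\,\rho\,D, \qquad D = \mathrm{diag}(\mathrm{se}_Y),$$

where $\rho$ is the signed LD correlation. IVW solves the one-parameter
GLS regression of $b_Y$ on $b_X$ (heterogeneity $Q$ on $n-1$ df); Egger
first orients all variants so $b_X \ge 0$ (jointly flipping $b_X$,
$b_Y$ and the LD rows/columns, which leaves IVW invariant) and adds a
free intercept absorbing directional pleiotropy ($Q$ on $n-2$ df).
With identity LD, IVW reduces exactly to the textbook
inverse-variance-weighted estimate with weights $1/\mathrm{se}_Y^2$; the
test suite checks both estimators against an independent
whitened-least-squares oracle to $10^{-10}$.

Numerical choices:

* if the smallest eigenvalue of $\rho$ falls below $10^{-8}$, a ridge of
  $10^{-6}$ is added to its diagonal (logged on the result); clumping at
  $r^2 < 0.3$ makes this rare by construction;
* standard errors are fixed-effect by default; multiplicative
  overdispersion inflation by $\max(1, \sqrt{Q/\mathrm{df}})$ is
  available behind `overdispersion = TRUE` because the variance model is
  a genuine free choice in summary-statistic MR;
* slope inference uses the normal reference distribution
  ($\mathrm{CI} = \hat\beta \pm 1.959964\,\mathrm{se}$), matching
  standard summary-statistic MR practice;
* binary outcomes are reported as odds ratios by exponentiating the
  slope and its confidence bounds.

## Diagnostics and model selection

Before estimation, `diagnostics_filter()` computes, on an initial IVW
fit, per-variant leverage (diagonal of the GLS projection matrix; the
leverages sum to the number of fitted parameters) and an outlier
statistic defined as the squared entries of the symmetric-square-root
whitened residual vector $\Sigma^{-1/2}(b_Y - \hat b_Y)$. Variants with
leverage above three times the mean or outlier statistic above 10.83
are removed in one pass; removal is deliberately not iterated by
default (an `iterative` mode exists) because residual heterogeneity is
instead *flagged* when the refitted $Q$ has $p < 0.001$. The outlier
cut 10.83 is kept as a plain configuration number; it coincides with
the 0.999 chi-square(1) quantile. The whitened-residual construction is
a declared package choice: with correlated instruments there is no
single canonical per-variant outlier statistic, and the symmetric
square root treats variants exchangeably.

Model choice between IVW and Egger follows the heterogeneity-difference
rule: Egger is preferred when $Q_{IVW} - Q_{Egger} > 3.84$. Because the
two models are nested and $\Sigma$ is treated as known, the difference
is the Wald chi-square(1) statistic for the Egger intercept; 3.84 is
the 95% quantile of chi-square(1), i.e. the squared 97.5% quantile of
the standard normal (the two-sided 5% cut for one extra parameter). Two
properties follow and are tested: the difference is non-negative up to
solver tolerance on every instance, and under no-pleiotropy nulls the
rule selects Egger in about 5% of replicates — the exceedance
probability of the 95% quantile, not 2.5%; quantile labels in parts of
the applied literature conflate the two, so the package documents and
asserts the 5% behaviour.

## Cross-ancestry colocalization

`cross_ancestry_coloc()` treats the same trait measured in two ancestry
groups as the two traits of a standard single-causal-variant
colocalization. Per variant and group it computes the Wakefield log
approximate Bayes factor

$$\log\mathrm{ABF} = \tfrac12\left[\log(1-r) + r z^2\right],
\qquad r = \frac{W}{V + W},$$

with $z = \beta/\mathrm{se}$, $V = \mathrm{se}^2$ and prior effect
variance $W$. The prior effect standard deviation defaults to 0.15 for
quantitative traits (effects in SD units) and 0.2 for binary traits
(log-OR scale), the convention of the coloc literature, and is
config-exposed since it is rarely stated in applied reports. Hypothesis
weights are accumulated in log space with log-sum-exp so regional lead
variants with $|z| > 40$ do not overflow; the $m \le 3$ cases are
checked against brute-force enumeration of all causal configurations to
$10^{-10}$. Per-variant priors default to $p_1 = p_2 = 10^{-4}$ and
$p_{12} = 10^{-6}$ — note these are *priors*; applied texts sometimes
print them next to posterior-probability notation, and the package
deliberately implements the only reading consistent with the ABF
machinery. A posterior probability of a shared signal above 0.80 is
reported as colocalization.

One limitation is structural: with several causal variants per locus
under ancestry-specific LD, the marginal lead variants differ between
groups and the single-causal model shifts weight from H4 toward H3.
The package's H4 validation experiments therefore plant one dominant
shared causal variant, which is also the method's stated assumption;
multi-causal colocalization (SuSiE-style) is out of scope.

## Interaction testing and multiplicity

`interaction_test()` takes the Rucker-chosen fit from each ancestry;
when the chosen model differs between ancestries the test proceeds on
the chosen fits with a logged note (the underlying reports are silent on
this case, and refusing would bias a systematic screen). The interaction
effect is the difference of estimates — on the log-OR scale for binary
outcomes, so its exponential is the ratio of odds ratios — with
$\mathrm{se}_\Delta = \sqrt{\mathrm{se}_j^2 + \mathrm{se}_k^2}$ exactly,
and a two-sided normal p-value. The multiplicity plan for a screen of
$T$ traits uses a Bonferroni-corrected interaction alpha $0.05/T$
(for $T = 32$: $1.6\times10^{-3}$), and for effects required to
replicate in both ancestries a combined alpha of $0.05^2 = 0.0025$,
implying $32 \times 0.05^2 = 0.08$ expected false replications across
the screen. Direction classes: *discordant* when both ancestry effects
are individually significant at 0.05 with opposite signs, *concordant*
when both significant with matching signs, *indeterminate* otherwise.

## The synthetic-data generator

The generator exists so every stage can be validated against known
truth without external downloads. Its construction:

* **Genotypes.** A latent Gaussian vector with the target LD correlation
  is cut at the Hardy–Weinberg quantiles of each variant's MAF (below
  $\Phi^{-1}((1-f)^2)$: 0 copies; above $\Phi^{-1}(1-f^2)$: 2). Realized
  genotype correlations are attenuated relative to the latent LD, so the
  LD matrix handed to the estimators is *recomputed from the simulated
  genotypes*, keeping estimator inputs self-consistent. The hot loop is
  compiled code with an explicitly seeded generator; identical seeds
  reproduce identical cohorts.
* **Phenotypes.** $P = G\delta + c_P U + e_P$ and
  $X = \mu P + c_X U + e_X$ with residual variances solved so both are
  approximately unit variance — $\delta$ and $\mu$ then read directly in
  SD units. Continuous outcomes add unit Gaussian noise to
  $\theta X + \phi_P P + c_D U$; binary outcomes are drawn from a
  logistic model whose intercept is solved numerically for the target
  prevalence (default 0.10), so the true log-OR matches the linear
  predictor coefficient under the rare-disease approximation.
* **Defaults.** 60 variants with first-order autoregressive LD
  (decay 0.8; the second ancestry uses 0.7 to emulate panel
  differences), MAF drawn uniformly on (0.05, 0.5), three causal
  variants of effect 0.25 protein-SD per allele — a strong cis locus,
  as expected in a drug target's own gene region and necessary for the
  default desk-scale cohorts to yield instruments at $F \ge 15$ —
  $\mu = 0.5$, $\theta = 0.4$, confounder loadings 0.3. One global seed
  fans out to per-stage child seeds by fixed offsets.
* **Marginal GWAS.** Per-variant simple linear regression in closed form
  (continuous) or univariate logistic regression via `glm.fit` (binary);
  monomorphic variants yield flagged records with missing effect sizes.

What the generator does **not** emulate: real allele-frequency spectra
or haplotype structure (no coalescent model), more than one region,
INDELs or multi-allelic sites, sample overlap between exposure and
outcome cohorts, and between-cohort heterogeneity in trait definitions.
Passing tests therefore demonstrate internal statistical correctness of
the estimators under the structural model — not robustness to the many
data-quality artefacts of real GWAS.

## Validation experiment sizes

The acceptance-level experiments run at sizes chosen to put the
estimators in their validity regime while remaining desk-scale:

* **Parameter recovery** uses two-sample studies with 50,000 individuals
  in each cohort, 200 replicates per scenario; the biomarker-weighted
  estimate is required to recover $\omega/\mu$ within 5% of truth both
  with $\phi_P = 0$ (recovering $\theta$) and $\phi_P \ne 0$ (recovering
  $(\mu\theta+\phi_P)/\mu$, *not* $\theta$).
* **Interaction calibration** uses exposure cohorts of 30,000 with
  outcome cohorts of 5,000, 1,000 replicates; the asymmetry reflects how
  these analyses are powered in practice (biomarker GWAS are far larger
  than disease GWAS), and the measured rates are insensitive to growing
  the exposure side further. One structural finding is worth stating
  plainly: with the estimator held at IVW the interaction test is
  calibrated at its nominal level, but the production pipeline feeds the
  *Rucker-selected* fit from each ancestry into the test, and
  selection-then-test inflates the type-I error by roughly three
  percentage points under these conditions. The mechanism is
  post-selection inference: in the ~5% of null replicates where Egger is
  spuriously preferred, the selected model's standard error understates
  its conditional sampling spread. `scripts/acceptance.R` reports both
  rates side by side (`interaction_type1_rate_rucker`,
  `interaction_type1_rate_fixed_ivw`); users screening many traits for
  interactions at a corrected alpha should be aware the effective level
  of the selection-based pipeline is somewhat above nominal.
* **Model-selection null calibration** draws 2,000 summary-level
  no-pleiotropy replicates (independent variants, known SEs), where the
  Q-difference is exactly chi-square(1).

`scripts/acceptance.R` re-runs all of these from scratch at a given
seed and writes the resulting quantities as JSON; to stay within a
desk-scale runtime it uses 100-replicate recovery and 500-replicate
calibration versions of the same experiments.

## Known limitations

Single-causal-variant colocalization only; no multivariable MR, no
weighted-median/mode estimators, no Steiger filtering, no proxy-variant
lookup, no liftover, and no local-ancestry analysis — ancestry is a
global group label. The leverage/outlier formulas under correlated
instruments follow the whitened-residual construction described above;
other constructions exist and can rank borderline variants differently.
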