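---
title: "Environment-specific heritability from a half-sib split-brood design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environment-specific heritability from a half-sib split-brood design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envherit)
```

## The scientific problem

How much a sexually selected trait can respond to selection depends on how
much additive genetic variance it expresses — and that expression can itself
depend on the environment an animal develops in. `envherit` implements the
quantitative-genetic analysis of a half-sib split-brood breeding experiment in
which male leaf-footed cactus bugs (*Narnia femorata*) were reared on one of
three naturally occurring diets (cactus with ripe fruit, with unripe fruit, or
without fruit) and measured for body dry mass, hind-femur area (the weapon),
and testis dry mass. The analysis asks three questions:

1. How do trait means differ across developmental diets?
2. How do the allometric scaling relationships among the traits change with diet?
3. How much additive genetic variance, heritability, and evolvability does
   each trait express on each diet?

## The character-state animal model

The genetic analysis treats a trait measured on different diets as distinct,
genetically correlated *character states*. For one trait the model is

$$y = 1\mu + X_1\tau + X_2\beta + Z a_{\times\tau} + e$$

where $\tau$ holds the fixed diet (environment) effects, $\beta$ the fixed
dissector-block effects, and $a_{\times\tau}$ is the vector of
environment-specific additive genetic effects with

$$a_{\times\tau} \sim \mathrm{MVN}(0,\ A \otimes G), \qquad
  e \sim \mathrm{MVN}(0,\ \sigma^2 I).$$

$A$ is the additive relationship matrix from the pedigree (built by the
recursive tabular method in `additive_relationship_matrix()`), and $G$ is an
unstructured $3\times3$ covariance matrix whose diagonal holds the additive
variances expressed on each diet ($\sigma^2_{aT_1}, \sigma^2_{aT_2},
\sigma^2_{aT_3}$) and whose off-diagonals are the cross-environment additive
covariances. Because every individual is reared on exactly one diet, the
phenotypic covariance of individuals $i$ and $j$ is simply
$A_{ij}\,G_{e_i e_j} + \sigma^2\,\delta_{ij}$; individuals reared on different
diets are connected through their sires, which is what identifies the
off-diagonals of $G$.

Derived quantities (`genetic_summary()`):

* heritability per environment $h^2_i = \sigma^2_{aT_i} / (\sigma^2_{aT_i} + \sigma^2)$,
  with a first-order delta-method standard error from the asymptotic covariance
  of the variance components;
* $V_P = \sigma^2_{aT_i} + \sigma^2$ (fixed effects excluded — the definition
  consistent with the published heritability cells this package uses as its
  worked example);
* the coefficient of additive genetic variation and mean-standardized
  evolvability. Two CV$_A$ variants are reported side by side:
  `CVA_stated` $= \sqrt{V_A}/\bar X$ (the standard definition, without the
  100 multiplier) and `CVA_printed` $= V_A/\bar X$. The published table this
  package reproduces as a worked example prints the latter variant in its
  CV$_A$ rows even though it states the former; the algebraic identity
  $I_A = \mathrm{CV}_A^2$ holds only for the stated variant, and only the
  stated variant is invariant to the trait's measurement scale. Both are kept
  so either convention can be compared against.

## REML estimation

`reml_fit()` maximizes the restricted log-likelihood

$$\ell_R = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py + (n-p)\log 2\pi\right]$$

with $V = Z(A\otimes G)Z' + \sigma^2 I$ and
$P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}$, over the seven parameters
$(\mathrm{vech}(G), \sigma^2)$. The full constant is included, so values are
comparable with any textbook implementation. The maximization has two phases:

1. **EM warm start.** Classical EM-REML updates
   $G \leftarrow G + G\,(S'AS - U)\,G/q$ and
   $\sigma^2 \leftarrow \sigma^2 + \sigma^4 (r'r - \mathrm{tr}\,P)/n$ (where
   $r = Py$, $S$ aggregates $r$ by individual and environment, $U$ collects
   environment-blocked sums of $P \odot A$, and $q$ is the pedigree size).
   These never decrease $\ell_R$ — a property the test suite asserts per
   iteration — but crawl near optima. The warm start is capped at 20
   iterations and hands over to phase 2 as soon as the per-iteration gain
   drops below 1 log-likelihood unit.
2. **Average-information (AI) updates with step-halving.** The AI matrix
   $\mathrm{AI}_{jk} = \tfrac12 y'P V_j P V_k P y$ (with $V_k = \partial
   V/\partial\theta_k$) is a quasi-Newton curvature approximation. Updates are
   taken in transformed coordinates — $G = LL'$ through its Cholesky factor
   and $\sigma^2$ through its logarithm — so that every iterate is a valid
   covariance and boundary optima (a singular $G$, a vanishing residual)
   become interior stationary points of the transformed problem. Steps are
   halved until the restricted log-likelihood does not decrease.

Two numerical devices matter in practice and are part of the package's design:

* **Truncated pseudo-inverse directions.** Near the PSD boundary the
  transformed AI matrix develops near-null curvature directions (the Jacobian
  of $L \mapsto LL'$ loses rank). The gradient provably has no component along
  those directions, so the Newton step uses a pseudo-inverse with a relative
  eigenvalue truncation of $10^{-5}$; keeping those directions produces wild,
  always-rejected steps.
* **Boundary snapping.** When an eigenvalue or diagonal entry of $G$ falls
  below 2% of $\mathrm{tr}(G)$, a candidate with that component pinned at the
  floor is also evaluated and accepted only if $\ell_R$ does not decrease.
  Without this the iteration approaches boundary optima asymptotically
  (observed: 70–150 iterations on boundary-bound datasets; with it, 12–35,
  reaching the same optima).

Convergence requires $|\Delta\ell_R| < 10^{-8}$ together with an AI-scaled
gradient norm (the Newton decrement $\sqrt{g'\,\mathrm{AI}^{-}g}$, which is
invariant to the trait's measurement scale) below $10^{-4}$, within 500
iterations. Before convergence is accepted, a confirmation line search along
the *lightly* truncated AI direction checks that no material gain hides in a
flat direction the working truncation discards; if it finds one, iteration
continues from the improved point. Five consecutive accepted steps that each
change $\ell_R$ by less than the tolerance, with a near-threshold gradient,
are likewise accepted (after the same confirmation): at that point the
attainable remaining gain is below the log-likelihood resolution, which
happens on occasional small datasets whose optimum sits on a flat
constrained ridge. Additive variances estimated at the floor
($10^{-10}\times\mathrm{var}(y)$) are flagged and reported as 0 in summaries.
The asymptotic covariance of the variance components is the inverse AI matrix
at the optimum (raw parameterization), which is also what the delta-method
heritability standard errors use. BLUPs of the environment-specific breeding
values for every pedigree member are $A S G$ evaluated at the optimum.

Fixed-effect inference uses Wald F statistics per term with numerator df equal
to the number of estimable contrasts and denominator df $n - \mathrm{rank}(X)$
— a documented, deliberately simple choice; no claim is made that it matches
any particular proprietary package's df approximation. Adjusted environment
means average dissector blocks with equal weights, making them invariant to
the factor parameterization.

## The synthetic-data generator

`simulate_breeding_design()` emulates the study design generatively: each
sire is mated to three unrelated dams (founders drawn MVN$(0, G)$ on the
character-state scale), each offspring receives the parental-average breeding
value plus a Mendelian deviation MVN$(0, G/2)$, is assigned one diet by a
multinomial split-brood draw and one dissector block uniformly, and the
phenotype adds the diet mean, the block effect, the breeding value expressed
in that diet, and $N(0, \sigma^2)$ residual noise.

Default study conditions (chosen once, as the conditions the analysed study
reports):

* 35 sire families × 3 dams × 10 offspring per dam (n ≈ 1050, matching the
  study's 1039 males over 35 sire families);
* allocation weights 11 : 6 : 14 over ripe/unripe/no-fruit, the study's
  per-sire-family medians, with a 3% chance that a sire × diet cell is
  emptied (its offspring reassigned) to mimic the reported unbalance;
* 3 dissector blocks with small fixed effects (the study does not report the
  number of dissectors or their effects);
* per-trait genetic architecture on the scale of the published estimates:
  body mass $V_A = (36.53, 0.97, 1.51)$, $\sigma^2 = 54$; femur area
  $V_A = (0.41, 0, 0.26)$, $\sigma^2 = 2$; cross-environment genetic
  correlation 0.5 (the study reports no correlations; 0.5 is a moderate,
  PSD-safe default). The published testis-mass variances are inconsistent with
  the printed means by an unstated unit factor (a Gaussian trait with mean
  0.20 mg and variance 5.08 mg² would be negative most of the time), so the
  testis defaults keep the printed means and heritabilities
  (0.21/0.09/0.11) but scale the variances to a phenotypic CV near 25%.

What the generator does *not* emulate: ontogeny and instar timing, genetic
correlations *between* traits (each trait's genetics is simulated and fitted
independently, as in the analysed study), maternal or dominance effects,
non-Gaussian residuals, and measurement error structure beyond the dissector
block. Passing recovery tests therefore show that the estimator recovers the
generating model of this design — not that real cactus-bug data satisfy that
model.

A Gaussian simulation at the published body-mass magnitudes produces a small
fraction (~4%) of non-positive masses in the poorer diets. The heritability
fits use the untransformed values and are unaffected; the log-scale
trait-expression battery cannot accept them, so `run_pipeline()` excludes
non-positive rows from the battery only, with a warning — the same per-stage
missingness principle the study itself uses (femur area measured on 910 of
1039 males).

## Trait expression and allometry

The battery (`scaling_battery()`) works throughout on natural-log transformed
traits (the log base is cosmetic for every reported conclusion; natural log is
used and documented). Per trait, a one-way ANOVA on diet is followed by
all-pairs Tukey–Kramer comparisons — the studentized-range tail probability
computed by `stats::ptukey`, the Kramer correction handling unequal group
sizes — and a compact letter display at $\alpha = 0.05$. Three ANCOVAs
(femur ~ body, testis ~ body, testis ~ femur, each with diet) apply the
screening rule: the diet × covariate interaction is retained if and only if
its p-value is ≤ 0.20, otherwise the common-slope model is reported. Main
effects use Type II sums of squares; adjusted diet means are evaluated at the
grand covariate mean (via emmeans) with Tukey-adjusted pairwise comparisons.
Which Tukey variant the original analysis software applied to adjusted means
is not documented; Tukey–Kramer is this package's documented choice.

## Reproducibility and reporting

`run_pipeline()` executes simulate → fit (3 traits) → genetic summary →
scaling battery from a single `pipeline_config()`, writing a report bundle
whose CSVs carry a hash of the scientific configuration (paths excluded) and
are byte-identical across repeat runs at a fixed seed. Rendered tables round
to 2 decimals; machine outputs (JSON fit reports, BLUP tables) keep full
precision.

Problem sizes used by the test suite were chosen to exercise each property at
the smallest scale where it is informative: oracle equivalence on pedigrees of
tens to two hundred individuals, likelihood oracles at n ≤ 50 where dense
Kronecker construction is exact and fast, parameter recovery at the full study
scale (35 sires, n ≈ 1050) over 100 replicates, and null-calibration runs at a
12-sire design where a single fit costs a fraction of a second.

## Known limitations

* Dense $A$ and $V$ limit the implementation to a few thousand individuals —
  ample for this design, far from livestock-scale.
* Single-trait character-state models only; no multi-trait, dominance, or
  maternal components.
* The Wald denominator df is a simple residual df, not a Satterthwaite or
  Kenward–Roger approximation; p-values for fixed effects in small designs
  are approximate.
* With few sire families, variance components with tiny true values are
  weakly identified; the PSD constraint then truncates their sampling
  distribution at zero, so replicate means of such components sit above the
  truth even though the estimator is correct. Medians are more robust
  summaries in that regime.
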