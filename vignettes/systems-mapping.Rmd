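---
title: "Systems mapping of multiphasic growth QTLs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systems mapping of multiphasic growth QTLs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpqtl)
```

## The scientific problem

Tree stems grow in phases: a juvenile phase in which primary (height) and
secondary (radial) growth compete for or share resources, and an adult
phase in which the two traits develop essentially independently.  A locus
that matters for forestry is not one that shifts height at a single age
but one that reshapes this whole program — the timing of the phase
transition, the strength of the height–diameter interaction, the adult
asymptotes.  `mpqtl` tests markers against genotype-specific *growth
programs* rather than genotype-specific scalar means.

## The biphasic mean model

For one genotype, height $H$ and diameter $D$ at age $t$ (years) are sums
of two phases, $H(t) = H_1(t) + H_2(t)$ and $D(t) = D_1(t) + D_2(t)$.
The juvenile phase couples the traits Lotka–Volterra style,

$$
\frac{dH_1}{dt} = \alpha_H\Big(1 - \frac{H_1}{K_{H1}}\Big)H_1
  + \alpha_H\,\beta_{H\leftarrow D}\,H_1 D_1, \qquad
\frac{dD_1}{dt} = \alpha_D\Big(1 - \frac{D_1}{K_{D1}}\Big)D_1
  + \alpha_D\,\beta_{D\leftarrow H}\,D_1 H_1,
$$

so the sign of each $\beta$ decides competition versus cooperation, and
setting both $\beta$ to zero recovers two independent logistic curves —
that decoupled system is what the package reports as "independent growth",
and the difference between coupled and independent curves is the
interaction component.  The adult phase is Gompertz per trait,
$H_2(t) = K_{H2}\exp(-\exp(p_H - q_H t))$.  Twelve parameters
($\alpha_H, K_{H1}, \beta_{H\leftarrow D}, \alpha_D, K_{D1},
\beta_{D\leftarrow H}, K_{H2}, p_H, q_H, K_{D2}, p_D, q_D$) describe a
genotype.  Units: $\alpha$ and $q$ in 1/year, asymptotes in trait units
(meters for height, centimeters for diameter), $\beta$ and $p$
dimensionless.

Two modeling conventions are ours, because a 12-parameter set cannot pin
them down:

* **Initial conditions.**  The juvenile system is integrated from $t = 0$
  with $H_1(0) = D_1(0) = \varepsilon$, default $\varepsilon = 0.01$ trait
  units (configurable via `fit_control(init_eps=)`).  The parameter set
  contains no initial values, so they must be fixed constants; results
  are insensitive to $\varepsilon$ well below the first-year trait values.
* **Solver.**  Classical fixed-step fourth-order Runge–Kutta, default
  step 0.05 year, linearly interpolated at the annual measurement grid
  $1..T$.  At this step the integration error (checked against a
  $10^{-4}$-step reference) is orders of magnitude below measurement
  noise; the tests verify the expected fourth-order error decay.

The multiphasic logistic alternatives (`kphasic_logistic`) use the
parameterization $K/(1 + e^{p - qt})$ per phase, summed over 1–3 phases,
which makes a phase's $(p, q, K)$ triplet directly interpretable:
$p/q$ is the phase midpoint and $K$ its asymptote.

## Likelihood, covariance, and fitting

Samples are bivariate longitudinal vectors $y_i \in \mathbb{R}^{2T}$
(height years $1..T$ stacked over diameter years $1..T$), modeled as
multivariate normal around the genotype curve with a SAD(1) covariance:
residuals follow $e_k(t) = \phi_k e_k(t-1) + \epsilon_k(t)$ with
innovation SDs $\gamma_k$ and a within-year cross-trait innovation
correlation $\rho$.  Five parameters give the full $2T \times 2T$ matrix.
The printed cross-covariance formula defines only the upper triangle
(trait 1 earlier, trait 2 later); we complete it with its equal-time limit
and the $\phi$-swapped mirror, which is exactly the covariance of the
generating process above — hence the matrix is symmetric and positive
definite for all admissible parameters ($|\phi_k| < 1$, $\gamma_k > 0$,
$|\rho| < 1$), and the Monte-Carlo process oracle in the tests confirms
every entry.

The null model $L_0$ fits one curve to all samples; the QTL model $L_1$
fits one curve per genotype class at a marker with a **single shared**
SAD parameter set across classes.  Maximization exploits the Gaussian
factorization: given the covariance, the ML curve parameters solve a
weighted least-squares problem against the (responsibility-weighted)
genotype mean trajectories; given the curves, the SAD parameters maximize
a 5-dimensional profile likelihood of the residual scatter matrix.  We
alternate these two Nelder–Mead sub-problems until the log-likelihood
changes by less than $10^{-6}$ (relative).  This coordinate ascent is
monotone, which the tests assert.  For markers with missing genotype
codes the same loop becomes EM, with prior-weighted responsibilities
(testcross 1:1, intercross 1:2:1) computed by log-sum-exp.

Numerical choices that matter:

* Unconstrained parameterization: $\log$ for rates and asymptotes and for
  the innovation SDs, $\mathrm{atanh}$ for $\phi$ and $\rho$; $\beta$,
  $p$, $q$ unconstrained.  This keeps the simplex inside the valid region
  without penalty hacks.
* The Nelder–Mead engine is compiled, with a configurable initial simplex
  span: cold fits start wide (0.1 on the transformed scale, with
  multi-start jitter), warm refinements inside the ascent loop start
  narrow (0.03), and "polish" passes restart the simplex around the
  current solution to escape premature collapse.  The compiled engine is
  verified against `stats::optim`'s Nelder–Mead in the tests.
* The curve search is boxed to a generous biological range scaled to the
  data (asymptotes within 3x the observed trait maxima, growth rates in
  (0.02, 5) per year, interaction coefficients in (-0.3, 0.3)).  The
  likelihood is nearly flat along directions where an asymptote and an
  interaction coefficient blow up together while the 24-year curve barely
  changes; unboxed, the simplex occasionally walks that ridge to
  astronomically unphysical values.  The box leaves the fitted curves and
  LR statistics untouched and keeps parameter estimates interpretable.
* Null fits seed the genotype-specific fits, so the alternative can never
  fall below the null and the LR statistic is non-negative by
  construction; residual negative noise below $10^{-6}$ is clamped with a
  warning.

The scan statistic is $LR = 2(\ell_1 - \ell_0)$ with the shared SAD
parameters re-estimated under $L_1$.  Holding them at the null estimate
(option `covariance = "fixed"`) is cheaper and is used as the first pass
of the large false-positive-rate studies, but it deflates the statistic
when a real QTL inflates the null-fit residual covariance, and its null
distribution sits visibly below $\chi^2_{12}$; the re-estimated statistic
matches the $\chi^2_{12}$ reference in our calibration tests, so it is
the default and the final arbiter for any marker near a detection
threshold.  Degrees of freedom follow the parameter-count difference,
$12(J-1)$ for the overall test; phase-specific sub-hypotheses constrain a
named block (juvenile block of 6, adult block of 3 per trait, or a single
parameter) to be equal across genotypes and compare against the full
genotype-specific model.

## Genetic architecture conventions

The printed sources for this methodology do not give formulas for the
genetic effect or the explained variance, so the standard
quantitative-genetics definitions are adopted: for two genotypes the
effect is half the genotype-mean difference, applied separately to each
curve component (total, juvenile, independent, interaction, adult); for
three genotypes the additive effect is half the homozygote difference and
dominance is the heterozygote deviation from the homozygote midpoint.
PVE at a time point is the between-genotype variance of the fitted curves
over the phenotypic variance, clipped to $[0,1]$ with a warning.
Genotype frequencies are observed counts, not theoretical ratios.  Phase
clustering of PVE trajectories uses Euclidean distance with Ward linkage
(`ward.D2`), cut at two clusters and relabeled so year 1 is cluster 1 —
deterministic, as `hclust`'s agglomeration breaks ties by index.

Curve features need an operational threshold for "reaching the
asymptote": we use 95% (configurable `fraction`).  The juvenile
asymptote is the coupled equilibrium
$H^* = K_{H1}(1 + \beta_{H\leftarrow D} K_{D1}) /
(1 - K_{H1}K_{D1}\beta_{H\leftarrow D}\beta_{D\leftarrow H})$, the
independent asymptote is $K_1$, and their difference is the
inhibition/promotion magnitude.  Adult onset and offset come from the
Gompertz inverse in closed form (and may legitimately exceed the
measurement window); a juvenile offset not reached within the grid is
right-censored at the grid end and flagged.

## What the simulation engine emulates

The generator reproduces the statistical structure of the motivating
24-year poplar study: $T = 24$ annual measurements of height and
diameter, testcross markers segregating 1:1 (intercross 1:2:1 supported),
$M = 1000$ markers with a single causal locus, sample sizes
$n \in \{66, 100, 200\}$, and two-genotype truth taken from the published
generating parameters.  The antedependence shape is not printed in that
source; we fix $\phi_1 = \phi_2 = 0.8$, $\rho = 0.3$ — strong year-to-year
residual memory and moderate cross-trait correlation, typical of repeated
stem measurements — and scale the innovation SDs so that the mean over
time of $\sigma^2_g(t) / (\sigma^2_g(t) + \sigma^2_e(t))$ equals the
target heritability $H^2 \in \{0.05, 0.1\}$, per trait, by 1-D
root-finding.  The large-$n$ round trip of this calibration is tested to
within 0.01.

One printed truth value deserves a flag: the heterozygote's adult-phase
location $p_H(\mathrm{Aa}) = 0.0034$ sits three orders of magnitude below
its homozygote counterpart (1.9779) and duplicates a printed interaction
coefficient — almost certainly a typesetting artifact.  The default
fixture keeps the printed value; `sim_true_params(corrected = TRUE)`
provides the plausible variant ($p_H = 2.0$).  Under the printed fixture
our power at $(H^2 = 0.05, n = 66)$ is $\approx 0.38$ against a published
0.49; under the corrected variant it is $\approx 0.50$ — consistent with
the artifact interpretation, but we report the printed-fixture numbers.

What passing these studies does **not** show about real data: the
generator has no linkage disequilibrium between markers, one causal locus
only, no polygenic background, no missing measurements, and Gaussian
residuals exactly matching the fitted covariance family.  Power and FPR
on real material will be worse than simulated whenever those assumptions
break.

Detection in the power and FPR studies uses the chi-square threshold at
the Bonferroni level $0.05/M$ (the published per-dataset thresholds are
dataset-specific choices; a `threshold` override is exposed).  The
default "fast" power mode evaluates the statistic at the causal marker
only — the detection rule is identical to a full scan at ~1/1000 of the
cost; a full-scan mode exists.  Study sizes in the shipped tests (100
power replicates per condition; FPR at 200 markers x 50 replicates per
condition; recovery at 30 replicates; null-calibration at 100 replicates)
were chosen so the whole suite runs on one CPU in tens of minutes while
keeping Monte-Carlo error within the stated tolerances.

## Known limitations

* The juvenile/adult asymptotes trade off along a near-flat likelihood
  direction ($K_{H1}$ up, $K_{H2}$ down leaves the summed curve almost
  unchanged over 24 years).  Single-trajectory estimates of individual
  asymptotes therefore scatter widely even at low noise — the published
  recovery tables show the same — while fitted curves, LR statistics,
  effect curves and PVE are stable.  Interpret individual parameter
  estimates with their replicate SDs.
* SAD(1) assumes a first-order antedependence; seasonal measurement
  artifacts or irregular grids need a richer covariance (out of scope).
* Missing phenotype values are rejected at load: the SAD structure is
  defined on the complete grid and imputation is deliberately not
  implemented.
* No interval mapping between markers and no kinship correction; markers
  are tested marginally.
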