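---
title: "Dirichlet regression association scans for longitudinal blood-pressure states: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dirichlet regression association scans: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirichscan)
```

## The problem

Genetic association studies usually test a scalar trait. Longitudinal
blood-pressure records carry more information than a single dichotomy
("hypertensive at last visit"): a subject's history constrains where they
are likely to go next. `dirichscan` turns that history into a compositional
phenotype — the probability vector of the subject's next transition among
three clinical states — and tests markers against that vector with Dirichlet
regression.

The pipeline has four statistical layers, each exposed as a fitting function
returning a classed object:

1. **State assignment** (`assign_state`, `build_state_sequences`): exam
   records are classified as state 1 (normotensive, SBP < 120 and DBP < 80
   mm Hg), state 2 (prehypertensive, not state 1 but SBP < 140 and DBP <
   90), or state 3 (hypertensive, everything else, and any exam with
   antihypertensive medication regardless of the measured pressures).
   Thresholds are strict inequalities, so a reading of exactly 120/80 or
   140/90 belongs to the higher state. An exam missing any clinical
   variable (SBP, DBP, medication flag, sex, smoking, age) is dropped; a
   missing medication flag is treated as a missing variable, not as "no
   medication".

2. **Transition models** (`transition_models`): for each previous state
   $l$, a generalized-logit (baseline-category multinomial) model
   $$\log\frac{y_{ilj}}{y_{ill}} = z_{il}^\top \gamma_{lj}, \qquad j \ne l,$$
   where $z_{il}$ holds sex, smoking status, age at the earlier exam of each
   consecutive pair, and optionally a categorical examination-time term.
   All nine transitions are permitted. The subject-specific transition
   probability matrix (TPM) follows by the softmax identity
   $y_{ill} = 1/(1 + \sum_{j\ne l} e^{z^\top\gamma_{lj}})$, so each row sums
   to one by construction.

3. **Response extraction** (`extract_responses`): the subject's response is
   the TPM row indexed by the *last available observed state*, evaluated at
   the last exam's covariates. A subject with a single retained exam
   contributes no transition to fitting but still has a conditioning state
   and covariates, so they receive a response.

4. **Dirichlet regression** (`dirichreg`, `snp_scan`,
   `dirichreg_penalized`): the simplex responses $y_i$ are modelled as
   Dirichlet with log-linked concentrations,
   $\log \lambda_{ij} = s_i^\top \theta_j$, all three components free (no
   reference category). The single-SNP scan fits the base model M1
   ($\log\lambda_{ij} = \alpha_j + \beta_j g_{ik}$, $g_{ik}$ the minor-allele
   dosage) and the family-adjusted model M2 (adding treatment-coded pedigree
   contrasts), and tests $H_0: (\beta_1,\beta_2,\beta_3) = 0$ with a joint
   3-df Wald statistic. Gene-level selection maximizes the penalized
   likelihood
   $$\ell(\eta) - c\,\kappa \sum_l \lVert\eta_{\cdot l}\rVert_2^2
     - (1-c)\,\kappa \sum_l \lVert\eta_{\cdot l}\rVert_1,$$
   ridge on each SNP's coefficient block at $c = 1$, lasso at $c = 0$.

## Key modelling decisions

**Examination time.** Time is a categorical factor of the earlier exam
index (treatment coding, first exam as reference). Three shapes are
entertained per previous state: no time term, a time main effect, and an
age-by-time interaction (an age slope that varies by exam; the reference
exam's slope doubles as the age main effect — the only well-defined reading
of "age × categorical time" under treatment coding). By default
`transition_models` chooses among them by likelihood-ratio tests at
$\alpha = 0.05$ against the no-time model, picking the stronger candidate
when both reject. With `time_effect = "fixed"` the user gets the
conventional shapes (age-by-time out of state 1, time main effect out of
state 2, none out of state 3) without selection; `"none"` disables time
altogether — the right choice for data, like the bundled simulator's, whose
generating mechanism has no exam effect.

A subject's *last* exam index is a time level the transition fits never saw
(fitting only uses earlier exams of pairs). `build_tpm` refuses unseen
levels, naming the offender; `extract_responses` by default clamps such
levels to the highest fitted one, since treatment-coded exam effects are
only identified over fitted levels. Set `clamp_time = FALSE` to make this
an error instead.

**Coefficient cap.** Transitions never observed in the data (an empty
destination category) push the corresponding $\gamma$ to $-\infty$.
Optimization is box-constrained to $|\gamma| \le 30$, which keeps every TPM
entry strictly inside $(0,1)$; the staying probability then differs from 1
by less than $10^{-9}$, indistinguishable in any downstream quantity. The
optimizer may stop short of the box when the gradient norm is already below
$10^{-8}$ — the fitted probabilities, the quantity of scientific interest,
are unaffected.

**Dirichlet optimization and covariance.** The likelihood
$\sum_i [\log\Gamma(\Lambda_i) - \sum_j \log\Gamma(\lambda_{ij}) +
\sum_j (\lambda_{ij}-1)\log y_{ij}]$ is maximized by BFGS with the analytic
digamma gradient, then polished with damped Newton steps using the analytic
Hessian until the gradient norm falls under $10^{-6}$. The coefficient
covariance is the inverse *analytic* observed information — exact rather
than finite-differenced, which both tightens the Wald test and makes
2000-replicate calibration studies cheap. Moment-based intercept starts
(slopes at zero) make convergence reliable across the simplex.

**Boundary responses.** Dirichlet support is the open simplex. Responses
produced by the transition layer are strictly interior by construction;
user-supplied responses with a component within $10^{-10}$ of 0 or 1 are
shrunk toward the centroid by the standard transform
$y' = (y(n-1) + 1/3)/n$ (`compress_simplex`).

**Wald degrees of freedom.** The additive model yields one SNP coefficient
per component, so the joint test has 3 df. Markers whose fit fails to
converge are flagged and reported with `NA` p-values rather than imputed.

**Families.** Pedigree enters M2 as fixed treatment-coded contrasts with
the largest family as reference; families below `min_family_size`
(default 2) are pooled into the reference to avoid near-empty columns.
Fitted SNP effects are invariant to family relabeling. Note that with many
small families the contrast count grows with $n$ and the M2 Wald test
becomes anticonservative — M2 is meant for cohorts with a modest number of
sizeable pedigrees. The scan reports raw p-values and flags markers below a
configurable genome-wide threshold (default $5\times10^{-8}$); no FDR
machinery is added.

**Penalty and optimization.** Because the group-L2 norm enters *squared*,
both penalty terms separate over individual coefficients, and the proximal
operator is the elementwise elastic-net map
$z \mapsto \mathrm{soft}(z, t(1-c)\kappa) / (1 + 2tc\kappa)$. Fitting is
proximal-gradient ascent with a backtracking line search on the
majorization condition (the objective trace is monotone and stored in the
fit), followed by a damped Newton polish on the active set with steps
shrunk so no active coefficient crosses zero. Convergence is declared at a
relative objective change below $10^{-8}$; `c = 0` solutions satisfy the
lasso KKT conditions to well under $10^{-6}$. SNP dosages are centered and
scaled before penalization (penalties are scale-sensitive); coefficients
are reported on both scales, and the selection tolerance ($10^{-6}$)
applies to the standardized scale. Intercepts and family contrasts are
never penalized: they are adjustment, not selection targets. When no
$\kappa$ is given, $0.1\,\kappa_{\max}$ is used, $\kappa_{\max}$ being the
smallest lasso weight that zeroes every SNP score at the null fit.
Selection counts are reported both as coefficients and as SNP groups, since
a "parameter" in a gene-level report can mean either.

**QC conventions.** The marker cascade runs call rate, then the exact
Hardy-Weinberg test, then MAF, each marker removed at its first failing
stage so the report partitions the input. "Call rate 95%" means
missingness at most 5% — the reading under which the filter removes a small
fraction of markers rather than nearly none. HWE uses the exact conditional
test (stable recurrence over heterozygote counts, as in modern PLINK), is
applied to hard calls only, and is skipped with a notice for fractional
dosages, where genotype counts are undefined. MAF is
$\min(m, 1-m)$ with $m = \mathrm{mean(dosage)}/2$, invariant to allele
relabeling. The sample call-rate filter runs before marker filters.

## The synthetic cohort

`sim_config` / `simulate_cohort` generate the study conditions used
throughout the tests: 171 nuclear families of 5 (855 subjects — two
founders drawn under HWE at marker-specific MAFs in $[0.05, 0.5]$,
offspring by gene-dropping), four exams per subject five years apart,
baseline age uniform on $[30, 60]$, 2% per-variable clinical missingness
and 0.2% genotype missingness. States evolve by the multinomial transition
mechanism with diagonally dominant defaults (`default_gamma`) in which
hypertension risk rises with age and smoking; the initial distribution is
(0.55, 0.30, 0.15). Blood pressures are drawn uniformly inside the assigned
state's rectangle (state 1: $[90,120)\times[50,80)$; state 2: the
complement within $[90,140)\times[50,90)$; state 3:
$[140,180]\times[90,110]$), so re-assigning states from the generated
pressures reproduces the truth exactly for unmedicated exams — the paper
trail between generator and pipeline is an identity, not an approximation.
Thirty percent of hypertensive exams carry the medication flag, with
pressures then drawn over the full range (treatment may control the
measured values).

An optional causal marker shifts the log-odds of moving *into* state 3 by
`causal_effect` per minor-allele copy (and, for subjects already
hypertensive, lowers the log-odds of leaving). The generative effect lives
on the transition scale while the scan estimates effects on the Dirichlet
concentration scale, so recovery studies assert detection, ranking and
calibration — not numerical equality of generative and fitted coefficients.

What the simulator does *not* emulate: linkage disequilibrium (markers are
independent), extended pedigrees, measurement replicates, informative
missingness, and medication carry-over between exams (each exam's flag is
independent). Passing tests therefore demonstrate correctness of the
machinery and calibration under these idealized conditions, not performance
on real cohort data.

## Numerical choices and problem sizes

Test and verification runs use sizes chosen to keep Monte-Carlo error
meaningful at interactive runtimes: transition-coefficient recovery at
$n = 5000$ transitions and Dirichlet recovery at $n = 2000$ subjects (both
within 3 SE of truth); Wald-test calibration with 2000 null replicates at
$n = 300$ (99% binomial band $[0.037, 0.063]$ around $0.05$); power
monotonicity on a three-point effect grid; HWE equality with an
enumeration oracle exhaustively for all genotype configurations up to
$n = 200$ samples; end-to-end determinism on a 200-subject cohort (reruns
are byte-identical because every stage is a pure function of inputs,
config and seed — no timestamps enter numeric artifacts).

## Known limitations

- The transition layer is a discrete-time first-order model; interval
  censoring and continuous-time intensities are out of scope.
- M2 adjusts for family by fixed effects only. A kinship-based random
  effect (a latent $u_i \sim \mathrm{MVN}(0, 2K)$ on the linear predictor)
  is the natural next step but changes the estimation problem
  substantially and is not implemented.
- $\kappa$ is user-chosen (grid plus an optional default); no
  cross-validation is wired into `selection_path`.
- The Wald test relies on asymptotic normality of the MLE; very small
  cohorts or near-monomorphic markers (which QC should remove) can defeat
  it, and such fits are flagged rather than rescued.
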