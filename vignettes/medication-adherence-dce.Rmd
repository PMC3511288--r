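---
title: "Designing and analysing medication-adherence choice experiments with dcemix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing medication-adherence choice experiments with dcemix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcemix)
```

## The problem

Roughly half of the patients prescribed long-term medications do not take
them as prescribed, and a substantial share of that non-adherence is
*intentional*: a deliberate weighing of a medication's harms, benefits,
cost and inconvenience. A discrete choice experiment (DCE) makes that
weighing measurable. Respondents repeatedly choose between two hypothetical
medications, A and B, each described by the same set of attributes at
varying levels; the pattern of choices reveals how much weight each
attribute carries, what trade-offs respondents will accept, and how much
preferences differ across people.

`dcemix` implements the full workflow for paired-alternative DCEs of this
kind: efficient choice-set design with embedded validity tasks, simulation
of heterogeneous respondent panels, estimation of a panel mixed
multinomial logit by maximum simulated likelihood, response-validity
scoring, and the post-estimation analytics (relative importance,
individual-level classification, marginal rates of substitution) that turn
coefficients into interpretable statements.

## The utility model

Each alternative $j$ in task $t$ gives respondent $i$ utility

$$U_{itj} = \alpha\,\mathbb{1}[j = A] + \beta_i' x_{itj} + \varepsilon_{itj},$$

with $x_{itj}$ the vector of attribute levels (entering linearly, in
natural units), $\alpha$ an alternative-specific constant capturing
left-right position bias, and $\varepsilon$ i.i.d. extreme value, so that
choice probabilities are logit. The coefficient vector $\beta_i$ is
respondent-specific ("mixed" logit): each coefficient is either

* **fixed** — identical for everyone,
* **normal** — $\beta_{ik} \sim N(\mu_k, \sigma_k^2)$, or
* **constrained triangular** — $\beta_{ik} = \mu_k T_i$ with $T_i$
  symmetric triangular on $[0, 2]$, i.e. a triangular distribution whose
  spread is tied to its mean so every draw has the mean's sign. This is
  the conventional way to force a cost coefficient to be non-positive for
  every respondent while still allowing heterogeneity, and it costs no
  extra parameter.

The *panel* structure matters: one draw of $\beta_i$ governs all of a
respondent's tasks, so the likelihood contribution of respondent $i$ is
the mixing-distribution expectation of the *product* of their task
probabilities,

$$L_i = E_\beta\!\left[\prod_t P_{it}(\text{chosen} \mid \beta)\right],$$

which is what induces the within-respondent correlation that distinguishes
a panel from pooled independent choices.

## Maximum simulated likelihood

The expectation has no closed form, so it is replaced by an average over
$R$ quasi-random draws (Halton sequences): dimension $k$ uses the radical
inverse in the $k$-th prime base, the first 10 points are discarded (the
early points of Halton sequences in neighbouring bases are strongly
collinear), and each respondent receives their own contiguous
sub-sequence. Halton draws cover the unit interval far more evenly than
pseudo-random numbers, so a few hundred draws do the work of several
thousand random ones; `draw_type = "pseudo_random"` is available for
comparison. Normal coefficients transform draws by
$\mu + \sigma \Phi^{-1}(u)$, triangular ones by the triangular inverse
CDF.

With two alternatives per task the likelihood depends on the data only
through the chosen-minus-other attribute differences, so the whole
objective reduces to dense matrix arithmetic over one difference matrix,
and the analytic score is cheap to compute alongside it. Numerical
choices, all overridable:

* Each difference-matrix column is internally rescaled to unit root mean
  square before optimization. Attribute units differ by orders of
  magnitude (dollars vs. doses per day), and an unconditioned quasi-Newton
  search stalls badly on such surfaces; estimates are mapped back to
  natural units on exit.
* BFGS with the analytic gradient, restarted (which resets the inverse
  Hessian approximation) and then polished with damped Newton steps until
  the gradient sup-norm (in the preconditioned space) falls below
  `gtol = 1e-5`; the `converged` flag honestly reports whether that
  criterion was met. Maximum 500 iterations.
* Simulated task probabilities are floored at $10^{-300}$ before logs;
  occurrences are counted in `prob_floor_count`.
* Standard errors come from the inverse numerical Hessian by default
  (`se = "bhhh"` gives the outer-product estimator); p-values are
  two-sided asymptotic z-tests without multiplicity correction, matching
  conventional choice-model reporting.
* Spreads are reported as magnitudes, since the likelihood is symmetric in
  the sign of $\sigma$; `$theta` keeps the raw optimizer so refits are
  exact fixed points.
* Starting values are zero means and spreads of 0.1 unless `start` is
  supplied.

With all spreads fixed at zero the simulated likelihood collapses to the
conditional logit exactly; the test suite exploits this by checking the
estimator against `survival::clogit` (an independent implementation via
the stratified-Cox equivalence) to numerical precision.

## Efficient designs with validity tasks

`generate_efficient_design()` minimizes the D-error
$\det(I(\beta)^{-1})^{1/K}$ of the multinomial logit information matrix
over the design's tasks, by default at zero priors (where probabilities
are 1/2 and the criterion is utility-neutral). The search is a random-start
coordinate swap — modified Fedorov with an accept-if-better rule — over a
fixed, seeded iteration budget, so a searched design can never end worse
than its random start. Tasks are then assigned to blocks (survey versions)
greedily to keep per-block level counts even, and `level_balance()`
reports any level appearing more than one occurrence away from perfect
balance. We chose zero-prior D-efficiency because it is the standard
default when no pilot estimates exist; priors can be supplied when they
do.

`add_validity_tasks()` appends to each block one *repeat* of a randomly
chosen design task (choice consistency) and one constructed *dominance*
task in which alternative A takes the direction-best level of every
attribute with a stated preference direction (monotonicity). Dominance is
verified against the factor directions at construction time, and the
design-role tasks are never altered. The default 32-task, 4-block design
therefore fields 10 tasks per version: 8 design tasks plus the two
validity tasks.

## The synthetic respondent generator

No individual-level survey data are distributed with studies of this kind,
so the generator is a first-class module: it draws respondent coefficient
vectors from the stated mixing distributions, binary covariates (private
health insurance, concession card, low income) as independent Bernoulli
draws, and choices by a single logistic comparison of $V_A - V_B$ per task
— distributionally identical to independent Gumbel errors per alternative
but cheaper and easier to reproduce. All randomness flows from one seed
through labelled child seeds, so a dataset is a pure function of
(population, design, n, seed).

`study_emulation_preset()` encodes the study conditions the package
documents itself against: 161 respondents over 4 versions of 10 tasks, 8
linear attributes (side-effect severity, 10-year risk of future medication
harm, symptom frequency, 10-year risk of death, monthly out-of-pocket
cost, symptom severity, doses per day, alcohol restriction), normal mixing
on the four harm/benefit coefficients, constrained-triangular cost, a
cost-by-insurance interaction of +0.004, and covariate prevalences 0.48
(insurance), 0.61 (concession), 0.37 (low income). The published
coefficient table for this study is not available, so the preset's
magnitudes are illustrative defaults chosen once to reproduce the
qualitative structure reported for such panels: death-risk reduction the
most important attribute, then current side-effect severity, then future
risk; regimen least important among significant attributes; and the
printed trade-off anchor that moving from four doses per day to one raises
utility by 0.2811 (so $\beta_{\text{regimen}} = -0.0937$) while a
20-point drop in future risk offsets it (so
$\beta_{\text{risk}} \approx -0.0141$). Cost levels are centred about
typical 2010 Australian prescription co-payments ($5–$50/month).

What the generator deliberately does **not** emulate: respondent fatigue
and learning, attribute non-attendance, left-right inattention beyond the
constant, correlated covariates, and continuous covariate effects. Passing
tests therefore demonstrate that the estimator and analytics recover the
truth *under the model's own assumptions* — the appropriate standard for
verifying an implementation — not that the model is true of any real
panel.

## Validity scoring and what exclusion does

`monotonicity_test()` flags respondents who choose the dominated
alternative; `repeat_consistency()` compares the repeated task against its
original (detecting relabelled alternatives automatically) and reports the
pass rate and Cohen's kappa from the pooled 2x2 first-vs-repeat table.
The default analysis *retains* failing respondents — deleting them has
been argued to discard valid preferences, and random utility theory is
compatible with occasional inconsistency — but `refit_excluding()` makes
the sensitivity analysis explicit, reporting sign and rank-of-magnitude
agreement between the full and restricted fits.

## Post-estimation analytics

* `fit_statistics()`: AIC, McFadden's $\rho^2 = 1 - LL/LL_0$, and the
  likelihood-ratio test against the average-utility null that predicts
  with the observed choice shares; the test's degrees of freedom equal the
  fitted parameter count, matching the convention in the applied
  literature.
* `hit_rate()`: the share of observations whose predicted probability
  favours the chosen alternative, with ties at 1/2 counting half so an
  uninformative model scores exactly 50%. Both unconditional
  (mixing-averaged) and conditional probabilities are supported because
  published hit rates rarely say which was used.
* `conditional_individual_coefficients()`: simulation-based conditional
  means $E[\beta_i \mid \text{choices}_i]$, the standard individual-level
  construction for mixed logit; "individual beta estimates" in applied
  papers are interpreted this way.
* `relative_importance()`: $|\beta_k| \times$ level range, normalized to
  percentage shares — scale-free and exactly summing to 100.
* `classify_harm_benefit()`: counts respondents whose summed harm
  importance exceeds their summed benefit importance, and the
  immediate-vs-long-term splits, from a configurable factor grouping.
* `tradeoff()`: $\Delta U$ for a stated attribute move and the
  compensating move in a second attribute, $-\Delta U / \beta_b$, with an
  explicit error when the denominator coefficient is zero.

## Problem sizes and reproducibility

The package's own checks run at the scales its documentation quotes: the
conditional-logit equivalence at 161 respondents x 10 tasks; parameter
recovery at 1000 respondents with 500 Halton draws (all means and spreads
within three estimated standard errors of truth, interaction sign
recovered); Monte-Carlo distributional checks at $10^5$ draws; and
discrepancy checks at $10^4$ Halton points. These sizes were chosen so a
single desktop core completes the full suite in a few minutes while
leaving the statistical assertions well-powered. Every simulation,
search and fit is a deterministic function of its seed; the pipeline
writes a config-hash manifest and refuses to silently overwrite artifacts
from a different configuration.

## Known limitations

* Only paired alternatives (no opt-out, no 3+ alternative sets) and linear
  attribute coding, matching the design this package targets.
* No correlated random coefficients, latent classes, WTP-space estimation
  or Bayesian posterior simulation.
* Bayesian-efficient design over prior *distributions* is out of scope;
  the D-error search takes point priors only.
* The stepwise covariate search inherits the usual caveats of stepwise
  procedures; it reports its full trace so the path is auditable.
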