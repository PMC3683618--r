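---
title: "Methods: quantifying the Guttman-scale property of an ordered task battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the Guttman-scale property of an ordered task battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomscale)
```

## The problem

Theory-of-Mind (ToM) batteries of the Wellman–Liu type present children
with a fixed sequence of tasks — Diverse Desires (DD), Diverse Beliefs
(DB), Knowledge Access (KA), Contents False Belief (FB), Explicit False
Belief (EFB), Belief vs. Emotion (BE) — each scored pass/fail on a target
question. The battery is claimed to form a *Guttman scale*: a child who
passes task $k$ should pass every earlier task. `tomscale` provides the
statistical machinery to test that claim on a cohort of school-age
children and to relate performance to demographics and temperament.

Four analysis stages are implemented, tied together by `run_pipeline()`:

1. **Scores and correlates.** A child's score $z_i$ is the count of
   correct target answers (alternative weightings: progressive in the
   task number, or one minus the task's observed mean performance).
   Associations with age, siblings, birth order and the three CBQ
   temperament scores are tested non-parametrically: the score vector is
   shuffled $B$ times and the two-sided permutation p-value is
   $p = (1 + \#\{|r_b| \ge |r_{\mathrm{obs}}|\})/(1 + B)$. The add-one
   correction keeps $p > 0$; the shuffle target is the dependent variable
   with predictors fixed, which for a single pair is equivalent to
   shuffling the assignment between them.
2. **Set-inclusion scaling.** With pass sets
   $G_k = \{i : x_{ik} = 1\}$ for the four scale tasks, the figure of
   merit is $M = \sum_{k=1}^{3} |G_{k+1} \setminus G_k|$ — the number of
   cases in which a child passed a task without passing the previous
   one. $M = 0$ iff the inclusion chain
   $G_4 \subseteq G_3 \subseteq G_2 \subseteq G_1$ holds; lower is
   better. Significance comes from a shuffle null (below).
3. **Covariate logistic model.** All $6n$ task responses are stacked and
   modelled by maximum-likelihood logistic regression on centred age,
   gender, a joint (sibling count, birth order) categorical, task
   dummies and a minimal subject disambiguator. Factor importance is a
   likelihood-ratio test (LRT): twice the log-likelihood drop on removal,
   referred to $\chi^2$ with the removed-column count as df. A sex
   $\times$ task interaction (5 df) tests whether the gender effect is
   task-specific.
4. **Model progression.** Per task $k$, three nested logistic models:
   *Pointwise* (covariates only), *Markov* (plus the response to task
   $k-1$) and *Cumulative* (plus the whole response history). In a
   well-scaled battery the previous response is informative
   (Pointwise vs Markov rejects at $k = 2$) but deeper history is not
   (Markov vs Cumulative stays null).

## The shuffle null for M

The wording "shuffle kids and tasks" admits several nulls, and the
resulting p-values differ, so all three are implemented and the choice is
exposed rather than hidden (`scaling_test(scheme = ...)`):

* `global` (default): all $4n$ cells permuted jointly, destroying row and
  column structure at once — the most literal reading of shuffling both.
* `within_child`: each child's four answers permuted, preserving
  individual totals while destroying task order.
* `within_task`: each column permuted, preserving task difficulty while
  destroying child identity.

Every scheme conserves the grand total of passes; `within_task`
additionally conserves each task's pass count, `within_child` each
child's score. The test is one-sided with small $M$ extreme,
$p = (1 + \#\{M_b \le M_{\mathrm{obs}}\})/(1 + B)$. The source study's
reported shuffle p-value is internally inconsistent (a sub-1% proportion
alongside p = 0.059) and its scheme cannot be inferred, so no numeric
reproduction of it is attempted; on the reconstructed cohort matrix the
global scheme gives a far smaller p than 0.059.

## The cohort fixture

Individual-level study data are unpublished, but every aggregate needed
by the scaling analysis is printed: 76 children, pass counts 62/56/48/36
for DD/DB/KA/FB, and successive violations 6/11/10 (hence $M = 27$).
`fixture_battery()` reconstructs a deterministic 76 x 4 matrix satisfying
all of them: DD passes are children 1–62; DB, 1–50 plus 63–68; KA, 1–37
plus 51–61; FB, 1–26 plus 38–47. Non-successive overlaps (e.g.
$|G_3 \cap G_1|$) are not printed and fall where this scheme puts them —
no analysis that depends on them may be validated against the fixture.

```{r}
s <- battery_summary(fixture_battery())
s
```

## The synthetic cohort generator

`sim_config()` / `simulate_battery()` generate cohorts with known
structure for calibration, power and recovery studies. Child $i$ receives
a latent ability

$$a_i = \beta_{\mathrm{age}}(\mathrm{age}_i - \overline{\mathrm{age}})
      + \beta_{\mathrm{gender}}\,\mathrm{girl}_i
      + \beta_{\mathrm{sib}}\,\mathrm{sib}_i
      + \varepsilon_i,\qquad \varepsilon_i \sim N(0, \sigma_a^2),$$

and passes task $k$ (difficulty $d_k$, $d_1 \le \dots \le d_6$) with
probability
$P_{ik} = g + (1 - g - s)\,\mathrm{logit}^{-1}(a_i - d_k)$ —
a four-parameter-IRT-style guessing floor $g$ and slip ceiling $s$, the
simplest mechanism that produces the small violation rates seen in real
cohorts. The study itself reports no violation-generating mechanism;
slip/guess is this package's modelling choice. Age is centred at the
sample mean so $\beta_{\mathrm{age}}$ keeps its meaning whatever the age
window. `perfect_guttman()` removes the Bernoulli noise and thresholds
the ability directly, so its pass sets are exactly nested on every draw.

Default parameters are the study conditions: $n = 76$ children, ages
uniform on 73–103 whole months, half girls, Poisson(1.2) siblings
truncated at 6, uniform birth order, standard-normal temperament scores.
The difficulties $d = (-2.168, -1.382, -0.626, 0.315, 0.510, 0.686)$
were frozen once from a large-sample (2 x 10^6) Monte-Carlo inversion so
that the expected scale-task pass rates equal the observed proportions
62/76, 56/76, 48/76, 36/76; EFB and BE are kept hardest (expected rates
0.44 and 0.41) because the generator's difficulty ordering is total,
whereas the study's raw EFB/BE rates sat above FB's — those two tasks
take no part in scaling analyses, so only their ordering constraint
matters here. Default effects $\beta_{\mathrm{age}} = 0.05$/month and
$\beta_{\mathrm{gender}} = 0.5$ (girl advantage) reproduce positive
age and gender findings at realistic strength; $\beta_{\mathrm{sib}} = 0$,
$s = 0.08$, $g = 0.05$, $\sigma_a = 1$.

Every operation draws from a named deterministic substream of the single
seed (`children`, `responses`, `shuffle_<scheme>`, ...), so outputs are
bit-identical across runs and unaffected by call order, and adding a
pipeline stage never perturbs another stage's draws.

What the generator emulates: monotone difficulty, approximate Guttman
structure with a tunable violation rate, a positive age effect, a girl
advantage, null sibling/birth-order/temperament effects, and the
duplicate-demographics collisions that motivate the subject
disambiguator. What it does not: response-time structure, item content,
learning or fatigue across the session, and any dependence between tasks
beyond the shared latent ability. Passing tests on synthetic cohorts
therefore validates the machinery, not the developmental claims.

## Numerical and design choices

* **IRLS fitter.** The logistic likelihood is maximised by
  Newton/IRLS with step-halving; convergence when the log-likelihood
  changes by less than 1e-8, cap 100 iterations. Separation
  (quasi-)complete — expected in Markov models on strongly scaled data,
  where failing task $k-1$ almost implies failing task $k$ — is detected
  when a coefficient passes 15 in absolute value while the likelihood is
  still moving; a ridge of 1e-8 then stabilises the normal equations,
  the fit is flagged, and the unpenalised likelihood is reported. The
  flag propagates to every LRT and table that uses the fit. `stats::glm`
  is used as an independent cross-check in the test suite, never as the
  fitter.
* **LRT clamping.** Nested statistics are mathematically nonnegative;
  values in $(-10^{-6}, 0)$ — noise near ridge-stabilised optima — are
  clamped to 0, anything lower raises an error.
* **Constant history columns.** If every child passed (or failed) an
  earlier task, its history column is aliased with the intercept; the
  per-task design drops it and records the fact, and a comparison whose
  extra columns all vanish degenerates to statistic 0, p = 1 — the
  correct answer, since the constant carries no information.
* **Permutation ties.** Surrogate statistics within 1e-12 of the
  observed one count as extreme, so exact ties on discrete data do not
  flip the verdict; all empirical p-values carry the +1 correction.
* **Scoring scope.** The default score uses all six tasks (the EFB/BE
  correlates are reported alongside the others in the source analysis);
  `tasks = 1:4` restricts to the scale tasks.
* **Siblings coding.** Sibling count and birth order are interdependent
  (birth order $\le$ siblings + 1), so they enter as one categorical
  factor over observed pairs, reference = most frequent pair — the
  least-assumption joint coding; df follows from the observed categories.
* **Subject disambiguator.** Age, sex, siblings and birth order almost
  identify children; colliding children are told apart by a single
  categorical index (order of participation), not a per-subject
  intercept, which would absorb all covariates.
* **No random effects.** The all-task model treats a child's six rows as
  independent given the covariates, as the source analysis does. This is
  a known limitation: with substantial child-level latent variance the
  plain LRT for between-child factors is anticonservative. For exactly
  that reason the null-calibration and recovery simulations in the test
  suite use $\sigma_a = 0$ (and, for recovery, $s = g = 0$), the regime
  in which the plain model is correctly specified; the anticonservatism
  under $\sigma_a > 0$ is a property of the modelling choice, not a bug
  in the fitter.
* **CBQ scores** are deliberately excluded from the logistic model and
  appear only in the correlation stage.

## Problem sizes in the test suite

The suite validates each stage at sizes chosen to make Monte-Carlo error
negligible relative to the tolerance while keeping a full run under a
minute: enumeration oracles on 5-child (120 permutations) and 4 x 3
((3!)^4 = 1296 surrogates) toys against B = 10000/20000 Monte-Carlo
runs; law-of-large-numbers and quadrature checks at n = 10000–50000;
LRT null calibration over 500 replicate cohorts of the study size
(n = 76); coefficient recovery over 100 replicates at n = 1000; power
checks at n = 300–500.

## Limitations

* The fixture pins only printed aggregates; any statistic sensitive to
  non-successive overlaps or to individual rows is not validated by it.
* The shuffle-null p-value is scheme-dependent and the source scheme is
  unknowable; report the scheme with the p-value.
* Plain logistic modelling of repeated measures (above) understates
  uncertainty when the latent child effect is large.
* The generator's slip/guess mechanism is one of many that produce
  violations; conclusions about mechanism are outside its scope.
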