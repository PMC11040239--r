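---
title: "Models and methods behind udsamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind udsamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(udsamp)
```

## The experiment being modelled

`udsamp` simulates and analyses a word-learning experiment with a
metacognitive twist. Each participant:

1. is trained on six novel object–label associations through ambiguous
   co-occurrence (cross-situational learning);
2. gives a binary **knowledge judgement** per object ("I know / I don't know
   the label");
3. makes exactly three **sampling choices** among the six objects to hear
   labels again;
4. answers one test trial per object (pick the named object out of all six,
   so guessing succeeds with probability 1/6), each followed by a binary
   **confidence rating**;
5. additionally judges nine control items (five familiar, four unfamiliar),
   which feed an exclusion filter.

The scientific questions are whether participants' sampling is
*uncertainty-driven* (directed at objects they judged unknown) and whether
such sampling improves test accuracy.

## The generative model

The simulator draws, per participant $p$ and object $o$:

$$\text{learned}_{po} \sim \mathrm{Bern}\!\left(\mathrm{logit}^{-1}(\mathrm{logit}(\pi_{\text{learn}}) + u_p + v_o)\right),
\quad u_p \sim N(0, \sigma_p^2),\; v_o \sim N(0, \sigma_o^2)$$

with the *same* participant and object intercepts re-entering the
test-accuracy stage, so one "ability" effect induces the crossed clustering
the analysis models assume. Judgements are conditionally Bernoulli given the
learned state (with `judge_known_given_unlearned > 0` encoding
overconfidence); sampling is a Plackett–Luce scheme — three sequential draws
without replacement with weight $e^{w}$ on judged-unknown objects and $1$
otherwise; accuracy is Bernoulli on the logit scale with a per-sample boost;
confidence is conditionally Bernoulli given correctness. Latent knowledge is
drawn directly: no trial-by-trial learning dynamics are simulated, because
no analysis consumes trial-level data.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `p_learn` | 0.31 / 0.44 / 0.81 by preset group | mirrors typical published group accuracies (younger children learn least); illustrative, not fitted |
| `sampling_preference_w` | 0 / 0.36 / 0.61 | younger children sample at random; older children and adults prefer judged-unknown objects |
| `judge_known_given_learned` / `..._unlearned` | 0.85 / 0.30 | good but imperfect calibration with substantial overconfidence |
| `p_sure_given_correct` / `..._incorrect` | 0.88 / 0.55 | high confidence overall, higher after correct answers |
| `sd_participant`, `sd_object` | 1, 0.5 | participant heterogeneity dominates object heterogeneity |
| `control_lapse` | 0.15 | children's mean control scores around 7/9 |

Custom group labels fall back to neutral values (`p_learn = 0.5`, `w = 0`).
Each participant draws from an own RNG substream derived from the master
seed, so enlarging a group never perturbs existing participants, and
identical configurations are bit-reproducible.

**What a green test does and does not establish.** The simulator reproduces
the *statistical* structure the analyses assume — binary outcomes with
crossed logit-normal random intercepts, a fixed per-participant sampling
total, conditionally independent confidence. It does not emulate screen
positions, reaction times, label phonology, learning curves, or feedback
effects; green tests therefore validate the estimators under a
correctly-specified world, not the psychology.

## Analysis stages

All group analyses are fitted separately per age group; there is no pooled
age model.

**Exclusion filter.** The control score counts familiar items judged known
plus unfamiliar items judged unknown (of 9). Scores below 5 exclude the
participant; exactly 5 is included.

**Overall accuracy.** `test_correct ~ 1 + (1|participant) + (1|object)`,
with a Wald *z*-test of the intercept against the chance level
$\mathrm{logit}(1/6) = -1.609$ in link space, two-tailed standard-normal
*p* (not *t*).

**Confidence–accuracy.** `confidence ~ accuracy` with random intercepts and,
where identifiable, random slopes of accuracy within participant and object.
Significance comes from a likelihood-ratio test against the model lacking
the fixed effect *but otherwise identical* — the reduced model keeps the
random-slope structure. A slope whose variance estimate hits the boundary is
dropped automatically and the decision recorded in the report notes (the
adult convention starts without the participant slope). Fitted probabilities
of a "sure" rating after correct and incorrect answers get parametric
bootstrap intervals.

**Preferential sampling.** The response is the aggregated pair
(times sampled, 3 − times sampled) per object — the "two-column matrix" —
regressed on the knowledge judgement with `(1|participant)` and
`(1 + judgement|object)` (plus a judgement slope within participant for
adults). Because six response rows encode only three real decisions, the
naive binomial Wald *p* is not trusted; inference uses a permutation test
that shuffles each participant's response rows across their objects
(judgements fixed), refits, and locates the observed absolute judgement
estimate in the permutation distribution. The observed data count as one of
the `n_perm = 1000` permutations, so $p \ge 1/n_{\text{perm}}$, and ties
count toward $p$ ("at least as large"). Non-convergent permutation refits
are discarded and counted, with an error above 10% — discarding is
conservative and logged.

*Sign convention:* with judged-known coded 1, uncertainty-driven sampling
appears as a **negative** judgement coefficient. Reports state the direction
in probability terms next to the estimate, and the permutation statistic
uses the absolute estimate, which is coding-invariant. (Published tables in
this paradigm print positive estimates alongside preferential sampling of
unknown objects, which is irreconcilable with the stated coding; this
package reports magnitude plus explicit direction and does not guess.)

**Chance-corrected sampling statistic.** Per participant,
$$r = \frac{u_s/\min(u_a, 3) - u_a/6}{2} + \frac12,$$
where $u_s$ is the number of unique judged-unknown objects sampled and $u_a$
the number available. Participants judging all or no objects unknown are
excluded (they carry no information). The statistic is analysed with an
intercept-only beta regression (logit link, scalar precision, joint ML) and
a Wald test against $0$ in link space, since $\mathrm{logit}(0.5) = 0$.

A caveat the implementation surfaces honestly: under chance-level sampling
$E[r] = 0.5$ **only for participants with $u_a \ge 3$**. Three draws from
six objects touch each object with probability $1/2$, so for $u_a \in
\{1, 2\}$ the hypergeometric expectation gives $E[r] = 2/3$ and $7/12$.
In worlds with many near-ceiling participants the intercept test is
therefore anticonservative; the test suite freezes the exact conditional
expectations.

**Sampling benefit.** Test accuracy regressed on the z-standardized
proportion of judged-unknown objects sampled; the preregistered predictor
divides by the three possible choices, the post-hoc predictor by $u_a$
(removing $u_a = 0$ participants). Standardization happens after all
exclusions, so the predictor has mean 0 and SD 1 in the fitted table.

**Sampling × judgement interaction.** Accuracy on times sampled, judgement
and their interaction (random intercepts only). Three nested fits: full,
null (no sampling terms), reduced (no interaction); reported are the
interaction Wald *p*, the full-vs-null LRT, the reduced model's sampling
effect, and fitted cell probabilities with unobserved cells flagged as
extrapolations.

## Estimation machinery

GLMMs are fitted by Laplace-approximated ML via `lme4::glmer` (crossed
random factors preclude straightforward quadrature); an adaptive-quadrature
path (`nAGQ > 1`) exists for single-factor models and is exercised against
an independent 40-node Gauss–Hermite oracle in the tests. Variance
components reaching the zero boundary flag the fit `singular`; pipeline
stages respond by refitting without the offending slope and recording the
decision. Non-convergence is never silent: fits carry a `converged` flag and
bootstrap/permutation machinery discards and counts failed refits (errors
above 20% / 10% respectively). Beta regression is fitted by joint ML over
logit-mean coefficients and a log-precision, with observed-information
standard errors — written in-package because no beta-regression dependency
is available.

Permutation loops default to the fast `nAGQ = 0` penalized-likelihood step
in simulation studies; the observed statistic is always computed with the
same approximation as the permuted ones, preserving exchangeability.

Parametric bootstrap intervals simulate from the fitted model, refit, and
take percentile bounds (2.5/97.5 at the 95% level), with `n_boot = 1000` for
headline analyses.

## Numerical findings the tests document

Three properties claimed for this design did not survive quantification;
the corresponding literal acceptance assertions are kept and fail visibly:

- **Laplace vs exact deviance.** With clusters of four binary observations
  the Laplace and exact marginal deviances can differ by ~0.2 — inherent
  approximation bias, not an implementation defect. What does hold (and is
  asserted green) is that the quadrature path matches the independent
  oracle to < 10⁻², and the Laplace estimates near-maximize the exact
  likelihood.
- **Naive Wald inflation.** The two-column construction pretends 18
  decisions per participant, which motivated the permutation test. Under
  the null simulated here the naive Wald test is in fact *conservative*
  (rejection ≈ 0.01 at α = 0.05): the fixed per-participant sampling total
  induces negative dependence (underdispersion) across the six rows. The
  permutation test stays nominal either way — the practical advice (trust
  the permutation *p*) is unchanged, only the direction of the naive bias
  differs from the motivating worry.
- **Effect recovery.** The generating Luce weight `w` is a single-draw
  log-odds preference; the two-column model estimates a marginal
  aggregated-binomial contrast attenuated by choice-set normalization and
  without-replacement depletion (≈ 0.64 at `w = 1` with adult-like
  learning). Recovery is therefore asserted against the model-implied
  marginal effect computed from a large simulation, not against `w`.

Simulation-based tests are scaled to a single-CPU budget (40–80 replicates,
`n_perm = 100`) with statistical bounds recomputed for the reduced counts.

## Known limitations

- Only binomial-logit and beta-logit families; no REML, no Satterthwaite or
  Kenward–Roger corrections (Wald tests use the standard normal).
- The simulator exposes a single judgement-based sampling weight; real
  sampling may also depend on salience or position, which nothing here
  represents.
- Importing deposited data is a documented column-mapping step
  (`records.csv` / `controls.csv` schemas), not auto-detection.
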