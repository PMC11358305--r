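---
title: "Models and methods: experience- and inference-based value updating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: experience- and inference-based value updating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revalr)
library(dplyr)
```

## The behavioral setting

Five visual stimuli are each worth 1–5 drops of juice; every trial offers a
pair and the subject takes one. Pairs are scheduled so that each of the ten
unordered pairs appears exactly once per 10-trial block, shuffled within
the block, with the left/right screen placement randomized per trial.

Two task regimes probe different updating strategies:

- **NOVEL**: a new stimulus set per session. 90 acquisition trials under
  reward pattern A (`S_i` worth `i` drops), then a single forced reversal
  to pattern B (`6 - i` drops) and 210 post-reversal trials. Values must be
  learned, and re-learned, from outcomes.
- **FAMILIAR**: a fixed, well-known stimulus set whose map alternates
  between the same two patterns. A reversal fires whenever the trailing 30
  completed trials contain at least 23 optimal choices (the smallest count
  strictly above 76%); the window never spans a reversal, so successive
  reversals are at least 30 trials apart. Here a single surprising outcome
  identifies the pattern in force, and the values of all five stimuli can
  be inferred at once.

`sim_novel_session()` and `sim_familiar_session()` run these loops with a
generative agent in the loop; every simulated trial records the offered
pair, both rewards under the in-force map, the choice, the delivered
reward, and the reversal markers, in a tidy one-row-per-trial tibble that
every other function consumes.

## The two choice models

**EXP** (experience-based) is a Rescorla–Wagner learner over subjective
values $V_i$ (drops units, all zero at session start):

$$P(S_i \mid S_i, S_j) = \frac{e^{\beta V_i}}{e^{\beta V_i} + e^{\beta V_j}},
\qquad V_i \leftarrow V_i - \alpha\,(V_i - r_{obs})$$

only the chosen stimulus's value moves. $\alpha \in [0,1]$ is the learning
rate; $\beta \ge 0$ the inverse temperature ($\beta = 0$ is uniform
choice). We use the symmetric softmax throughout; it is the only form
consistent with the uniform $\beta = 0$ limit and with the mixture model
below.

**INF** (inference-based) assumes the learner knows both candidate maps,
$V^A_i = i$ and $V^B_i = 6 - i$, and carries a single belief state: the
confidence $w \in [0,1]$ that pattern A is in force ($w = 0.5$ at session
start). Choice follows the $w$-mixture of the two softmax distributions,
and $w$ takes a gradient step on the squared reward-prediction error of
the chosen stimulus:

$$w \leftarrow \mathrm{clip}_{[0,1]}\!\left[w - \alpha\,\big\{(w V^A_i +
(1-w)V^B_i) - r_{obs}\big\}(V^A_i - V^B_i)\right]$$

Choosing the 3-drop stimulus is uninformative ($V^A = V^B = 3$); choosing
an extreme stimulus moves $w$ fast, which is what makes one post-reversal
outcome sufficient to flip the belief. Because the tables are exact
complements, the balanced mixture at $w = 1/2$ equals $1/2$ for every
pair; the implementation returns that case exactly.

## Likelihood, fitting, and the post-reversal learning rate

`negloglik()` evaluates $-\sum_t \log P(\text{choice}_t)$ with the state
before trial $t$'s update, evolving the state with the *delivered* rewards
(inner loops in C++; an independent plain-R oracle cross-checks them in the
test suite to $10^{-10}$). Two variants are fitted per session:

- `basic`: $(\alpha, \beta)$;
- `modified`: $(\alpha_{post}, \alpha_{other}, \beta)$, where
  $\alpha_{post}$ applies to updates on post-reversal trials — all trials
  from the reversal onward in NOVEL, the five trials from each reversal
  onward in FAMILIAR (truncated at session end) — and $\alpha_{other}$
  elsewhere. $\alpha_{post}$ is the reported learning rate in summaries,
  since it is the parameter that reflects updating after contingencies
  change.

`fit_session()` minimizes the negative log-likelihood with L-BFGS-B from 10
starting points drawn from a seeded Latin hypercube over the bounds
$\alpha \in [0,1]$, $\beta \in [0,10]$. The bounds are a design choice, not
a fact about the models: $\alpha > 1$ makes the INF gradient step wildly
unstable (the gradient factor reaches $4 \times 4 = 16$), and $\beta = 10$
is effectively deterministic choice at unit value differences. Both are
overridable via `bounds`. Multi-start matters in practice: roughly half the
starts on a typical session terminate on the $\beta = 0$ plateau (where
the likelihood is exactly $n\log 2$ and $\alpha$ is unidentifiable), and
the multi-start minimum verifiably attains the optimum of a dense
$200 \times 200$ parameter lattice in the acceptance suite. When the best
fit itself lands on $\beta \approx 0$, the `flat` flag marks the learning
rate as unidentifiable rather than re-parameterizing.

Model comparison uses `BIC = k log n - 2 logL` per session ($k = 2$ or 3,
$n$ = completed trials) and Bayesian posteriors $\propto e^{-BIC/2}$ under
a uniform prior (configurable), computed per session and averaged;
`compare_models(method = "summed")` instead sums BIC within a group first.
The EXP-vs-INF question is asked of the basic variants, which keeps the
comparison about the updating mechanism rather than the phase split.

## Behavioral statistics

All metrics are model-agnostic functions of the trial log. A choice is
*optimal* iff it takes the larger in-force reward of the offered pair — so
immediately after a reversal the previously better stimulus no longer
counts. Phase windows: NOVEL Pre/PoE/PoL = trials 1–90 / 91–190 / 191–300;
FAMILIAR Pre/PoE/PoL = 10 before / first 5 after / next 5 after each
reversal, computed per reversal and then averaged across reversals (never
pooled), truncated rather than overlapped when reversals crowd the session
edges.

`experience_events()` extracts the updating probes from the PoE phase:

- *positive*: the first choice of a high-valued option (4–5 drops under the
  in-force map) whose most recent earlier presentation had it offered as
  the pair's better option and yet not chosen;
- *negative*: the first suboptimal choice of a low-valued option (1–2
  drops, taken although it was the pair's worse option) whose most recent
  earlier presentation had it offered and not chosen.

In both cases the defining error is suboptimal behavior — a perfectly
optimal chooser generates no events — and the "preceding trial" is the most
recent presentation of that option, not the immediately preceding trial
(intervening trials with other pairs are expected). One event per option
per session; the evaluation trial is that option's next presentation. By
default the whole chain is confined to PoE (`within = "poe"`); the
full-post-reversal alternative is available because the boundary between
the two readings is genuinely underdetermined.

`inference_trials()` formalizes the inference probe in FAMILIAR sessions:
the 1st trial after a reversal, and the earliest later trial (before the
next reversal) whose pair is disjoint from the 1st trial's pair. An
optimal choice there cannot rest on direct post-reversal experience with
either offered stimulus. With an INF agent at the defaults, the
inference-trial optimal rate is far above the 1st-trial rate (about 59%
vs 11% in the control arm of the shipped cohort), reproducing the
direction of the effect this probe was designed to show; no search-window
cap is applied beyond the next reversal.

`proportion_shifted()` is the devaluation index
$((F1N - F1D) + (F2N - F2D))/(F1N + F2N)$: 0 for identical baseline and
devaluation choices, 1 for a complete shift away from the devalued food's
objects.

## Synthetic cohorts and what they do (not) show

`cohort_design()` lays out study-shaped cohorts: two subjects, control and
treated arms, NOVEL sessions generated by EXP agents and FAMILIAR sessions
by INF agents — matching which model explains which task — with 300-trial
sessions for the first subject and 400-trial FAMILIAR sessions for the
second. Session counts per treatment per subject: 7 NOVEL / 6 FAMILIAR for
the `"ofc"` preset, 5 everywhere for the pathway presets. Silencing is
modeled *only* as a multiplicative reduction (default 0.5) of the
post-reversal learning rate in the treated arm of the affected task(s) —
`"ofc"`: both tasks; `"rmcd"`: NOVEL only; `"mdm"`: FAMILIAR only — with
$\beta$ untouched, mirroring the finding that silencing changes updating,
not exploration. Generating parameters default to $\alpha = 0.15,
\beta = 1.5$ (EXP) and $\alpha = 0.05, \beta = 1.5$ (INF); these are
package constants chosen to produce learning curves of realistic shape
(acquisition to ~85% optimal within a session; recovery within a few
trials of a FAMILIAR reversal), not values fitted to any subject.

Ground truth (parameters and seeds per session) is emitted alongside the
sessions and never consumed by fitting. `recovery_report()` joins fits to
truth and reports per-arm recovery plus treated-vs-control contrasts; group
contrasts use means ± s.e.m. and label-permutation tests (one-sided for
$\alpha_{post}$, whose predicted direction is a decrease; two-sided for
$\beta$) rather than ANOVA — a distribution-free check suits synthetic
validation with 10 sessions per arm.

What passing tests on these cohorts show: the estimator recovers the
generating parameters at study-sized sessions, model selection identifies
the generating model, and the analysis chain detects a halved
post-reversal learning rate where (and only where) it was injected. What
they cannot show: anything about real monkeys — the generator has no
motivational drift, no reaction times, no aborted trials, no
session-to-session parameter variability, and its agents are exactly the
models later fitted to them, so fit quality is an upper bound.

## Numerical and design notes

- Softmax probabilities are computed as logistics of value differences, so
  large $\beta$ saturates gracefully instead of overflowing; symmetric
  cases (equal values, $\beta = 0$, balanced mixture) return exactly 0.5.
- Trial indices are 1-based and contiguous; stimulus ids are the fixed
  strings `S1`–`S5`. A NOVEL session's "new stimulus set" is represented by
  resetting values to zero at session start — the only consequence of
  stimulus novelty visible to either model — rather than by minting new
  ids.
- Session metadata (subject, task, treatment) travels as columns of the
  tidy one-row-per-trial CSV written by `write_sessions()`, keeping a
  session file self-contained; `read_sessions()` re-validates every
  invariant (contiguous trials, distinct pair rewards, delivered reward
  equal to the chosen side's, pattern changes only at reversal markers) and
  names the offending session and trial on failure.
- The FAMILIAR criterion is evaluated on a sliding per-trial window of
  completed trials; whether the original task evaluated per trial or per
  block is not knowable from the outside, and per-trial is the stricter
  reading. The initial pattern of a FAMILIAR session is a coin flip unless
  configured.
- No session or trial exclusion logic exists: the data model contains
  completed trials only.
- Problem sizes used by the shipped checks (20-trial oracle fixtures, 20
  recovery sessions per model, 40 sessions per model-selection arm, 10
  master seeds per preset contrast) were chosen as the smallest sizes at
  which the corresponding properties are stable, so the whole suite runs
  in a few minutes on a laptop.
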