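# revalr

Simulation and model-based analysis of multi-reward reversal-learning
behavior, for researchers studying how subjects update stimulus values —
from direct experience versus by inference over known task structure.

Macaques (and models of them) can solve a five-stimulus value task two
ways. In the **NOVEL** task, a fresh stimulus set is learned each session
(stimuli worth 1–5 drops of juice), with the stimulus–reward map reversed
mid-session (`r -> 6 - r`): values must be re-learned from experience. In
the **FAMILIAR** task, the same five stimuli alternate between two known
reward patterns whenever performance passes a criterion (more than 76%
optimal choices over the trailing 30 trials): a single surprising outcome
lets the subject *infer* the values of every other stimulus.

`revalr` implements both tasks as closed-loop simulators and two
trial-by-trial choice models:

- **EXP** — a Rescorla–Wagner learner. Subjective values update as
  `V_i <- V_i - alpha (V_i - r_obs)` and choices follow a softmax
  `P(S_i) = exp(beta V_i) / (exp(beta V_i) + exp(beta V_j))`.
- **INF** — an inference learner that knows the two candidate patterns
  (`V^A_i = i`, `V^B_i = 6 - i`) and maintains a confidence weight `w` that
  pattern A is in force; choices follow the `w`-mixture of the two softmax
  distributions, and `w` moves by a gradient step on the reward-prediction
  error, clipped to [0, 1].

Both models are fitted per session by multi-start bounded maximum
likelihood, either with one learning rate (`basic`, 2 parameters) or with a
separate post-reversal learning rate (`modified`, 3 parameters) — the
post-reversal rate is the quantity of interest when a manipulation is
expected to impair value updating. Models are compared per session via BIC
posterior probabilities (`posterior ∝ exp(-BIC/2)`). A synthetic-cohort
generator emulates silencing experiments as a multiplicative reduction of
the post-reversal learning rate in the treated arm, with ground truth kept
separate from fitting.

## Worked example

```r
library(revalr)

# one NOVEL session generated by an EXP agent (alpha 0.15, beta 1.5)
s <- sim_novel_session("exp", alpha = 0.15, beta = 1.5, seed = 1)

# fit the modified EXP variant: separate post-reversal learning rate
fit <- fit_session(s, "exp", "modified")
fit
#> <rl_fit> EXP/modified  session novel-1 (NOVEL, vehicle, 300 trials)
#>   estimates: alpha_post = 0.1225, alpha_other = 0.4849, beta = 1.5436
#>   logLik = -101.838  (10/10 starts converged)
glance(fit)
#> # A tibble: 1 × 6
#>   logLik    df  nobs   BIC n_converged flat
#>    <dbl> <int> <int> <dbl>       <int> <lgl>
#> 1  -102.     3   300  221.          10 FALSE
```

The fitted `alpha_post` (0.12) and `beta` (1.54) sit near the generating
values; `alpha_other` is looser because the 90 acquisition trials constrain
it only weakly. `BIC = 3 log(300) - 2 logLik`.

The full analysis chain — cohort generation, fitting, model comparison,
phase-wise optimal-choice rates, permutation contrasts — runs as one call.
The `"rmcd"` preset emulates a pathway silencing that halves the
post-reversal learning rate in the NOVEL task only:

```r
rep <- run_pipeline("rmcd", seed = 42, n_perm = 1000)
glance(rep)
#>   preset  seed novel_poe_deficit familiar_poe_deficit novel_alpha_post_diff
#> 1 rmcd      42             0.171             -0.00667               -0.0783
#>   novel_alpha_post_p familiar_alpha_post_diff familiar_alpha_post_p ...
#> 1           0.000999                 -0.00479                0.0949
```

Read: the treated arm loses 17 percentage points of optimal choice in the
early post-reversal phase of the NOVEL task (none in FAMILIAR), the fitted
post-reversal learning rate drops by 0.078 (true reduction 0.075;
permutation p = 0.001), and no spurious contrast appears in the FAMILIAR
task. `autoplot(rep)` draws the block-averaged learning curves per arm.

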