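# metatutor

Computational core of an intelligent tutor for far-sighted planning in
Mouselab-MDP process-tracing tasks.

In these tasks a participant steers an agent through a reward tree from
root to leaf. Rewards are concealed; each click reveals one node's value
for a small fee, so the click sequence externalizes the planning process
itself. metatutor answers three questions about such tasks:

1. **What is the optimal way to plan here?** Planning is formalized as a
   *metalevel MDP*: states are beliefs (the values observed so far),
   actions are computations (click an unobserved node, or terminate and
   act). `solve_meta()` computes the state-action value function exactly
   by backward induction,

   *Q*(b, click n) = −λ + Σ_v P(v) · V(b ∪ {n: v}),  
   *Q*(b, ⊥) = max over paths of E[return | b],  V(b) = max_c Q(b, c),

   using a compiled canonical-state core (exchangeable branches, and of a
   branch's observed final values only the count and maximum matter) that
   collapses the three-step training environment from ~2.4 × 10⁸ raw
   beliefs to ~1.9 × 10⁶ canonical states. An independent brute-force
   oracle verifies the reduction on small fixtures.

2. **How should a tutor react to each planning operation?** Every click
   or stop decision is scored by its regret,
   loss(b, c) = max_c′ Q(b, c′) − Q(b, c), and translated into a delay
   penalty of 2 + a · loss seconds plus instruction (highlighted optimal
   clicks, "You should have inspected one of the highlighted nodes.",
   …). `calibrate_scaling()` fixes *a* so that acting without any
   planning costs exactly 42 s. Delay-only, info-only, action-feedback
   and no-feedback control conditions are included.

3. **How good was a participant?** Raw scores are normalized so that 0 =
   chance (random path, no clicks) and 100 = optimal:
   relative(s) = 100 · (s − s̄_rand) / (s̄_opt − s̄_rand), with exact
   anchors where the environment is solvable and an optimized
   goal-setting approximation where it is not.

A synthetic-session generator (`simulate_participant()`,
`make_fixture_suite()`) produces complete scripted training/test sessions
so the entire pipeline runs and is tested without human data.

## Worked example

```r
library(metatutor)

env <- preset_env("training_3step")   # 3-step web, rewards ±4/±8/±48, $1/click
q   <- solve_meta(env)
q
#> <meta_q> training_3step (fork solver)
#>   V(empty belief): 39.96530151
#>   states solved: 1,923,825
```

The value of planning optimally from scratch is ≈ $39.97 per trial. The
optimal first computations are all final-step clicks — the solved policy
plans backward from potential goals:

```r
dplyr::arrange(tidy(q), dplyr::desc(q)) |> head(4)
#> # A tibble: 4 × 4
#>   computation     q  loss optimal
#>   <chr>       <dbl> <dbl> <lgl>
#> 1 d3_1         40.0     0 TRUE
#> 2 d3_2         40.0     0 TRUE
#> 3 d3_3         40.0     0 TRUE
#> 4 d3_4         40.0     0 TRUE
```

Calibrate the tutor and ask it about a myopic first click on an
immediate-reward node:

```r
cfg <- calibrate_scaling(env, q, feedback_config("metacognitive_full"))
ev  <- metacognitive_feedback(q, empty_belief(), "d1_1", cfg)
ev[, c("loss", "delay", "message_key")]
#> # A tibble: 1 × 3
#>    loss delay message_key
#>   <dbl> <dbl> <chr>
#> 1 0.514  2.51 should_have_inspected
ev$highlighted[[1]]
#> [1] "d3_1" "d3_2" "d3_3" "d3_4" "d3_5" "d3_6"
```

The myopic click costs about half a dollar of expected return, earns a
2.5-s delay, and the tutor points at the six final-step nodes it should
have inspected instead. Terminating immediately at the empty belief —
acting without planning — draws the full calibrated 42-s delay.

Scoring closes the loop: Monte-Carlo rollouts of the optimal policy
average ≈ 100 relative points,

```r
norm <- score_norm(env, "exact", q = q)
pe   <- evaluate_policy(optimal_policy(q), env, n = 10000, seed = 1)
mean(relative_score(pe$scores, norm))
#> [1] 99.83886   # within 3 SE of 100 (SE ≈ 0.37 points)
```

and simulated sessions (`simulate_participant()`, `summarize_trials()`)
report per-condition relative scores and backward-planning rates with
bootstrap CIs. `autoplot()` methods cover the Q table, the threshold
search and the session summaries; `tidy()`/`glance()` methods return
tibbles throughout.

## Command-line use

A thin wrapper for shell pipelines lives at `inst/cli/tutor.R`:

```sh
Rscript inst/cli/tutor.R solve    --env toy2 --out q.json
Rscript inst/cli/tutor.R simulate --env training_3step \
    --condition metacognitive_full --strategy optimal --seed 7 --out s.jsonl
Rscript inst/cli/tutor.R score    --env training_3step --sessions s.jsonl
```
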