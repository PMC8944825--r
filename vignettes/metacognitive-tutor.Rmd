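---
title: "Discovering and teaching optimal planning strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and teaching optimal planning strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metatutor)
```

## The problem this package addresses

In Mouselab-MDP process-tracing tasks, a participant steers an agent from
the root of a reward tree to one of its leaves. Every node holds a
concealed reward; the participant may pay a small fee to click a node and
reveal its value before committing to a path. Because each click is a
proxy for one planning operation, the click sequence externalizes *how* a
decision was reached, not just what was decided. metatutor implements the
computational core of an intelligent tutor for such tasks: it formalizes
planning as a metalevel Markov decision process, solves that MDP exactly,
converts the regret of each observed planning operation into calibrated
feedback, and normalizes performance against chance and optimal anchors.
A synthetic-session generator makes the whole pipeline testable without
human data.

## The metalevel MDP

The state of the metalevel MDP is a *belief*: the set of node values
observed so far (all other nodes carry their prior distribution). The
actions are *computations*: one click per unobserved node, plus
termination (`terminate`), which ends deliberation and takes the path with
the highest expected sum under the current belief. Rewards are the
negative click cost for each click and, on termination, the expected
return of the chosen path. The state-action value function satisfies

$$Q(b, \mathrm{click}\ n) = -\lambda + \sum_v P_n(v)\, V(b \cup \{n\!:\!v\}),
\qquad Q(b, \perp) = \max_{\text{paths } p} \mathbb{E}[R(p) \mid b],$$

with $V(b) = \max_c Q(b, c)$ and $\lambda$ the click cost. `solve_meta()`
computes $Q$ by backward induction over beliefs; the recursion is finite
because each click observes one node, so the belief graph is a DAG whose
depth is the number of reward-bearing nodes.

### Assumptions

* Rewards are independent across nodes and identically distributed within
  a depth.
* Clicks are truthful and irreversible: a clicked node stays revealed.
* Re-clicking an observed node is excluded from the action set. It is
  strictly dominated (it pays the fee and changes nothing), and removing
  it keeps the formalism clean.
* All clicks precede the first move. With deterministic transitions there
  is never an incentive to click after moving.

### Canonical states and exactness

The raw belief space of the three-step training environment has $5^{12}
\approx 2.4 \times 10^8$ states; the solver reduces it to about $1.9
\times 10^6$ canonical states by exploiting two facts. First, sibling
branches with identical topology and reward distributions are
exchangeable, so a belief and any branch permutation of it have the same
value. Second, within a branch, once several final-step values are
observed only their count and maximum can influence any later decision:
termination routes through the best leaf, and future leaf clicks compare
against the best observed value. The reduction is a bisimulation — every
canonical state has exactly the same continuation problem as each of its
members — so the solved values are exact, not approximate. The test suite
verifies this by comparing `solve_meta()` against
`brute_force_oracle()`, an independent dense enumeration of concrete
beliefs with no symmetry reduction, on three fixtures (maximum absolute Q
difference below 1e-9).

`solve_meta()` accepts trees of the shape *root fan-out, single-successor
chain, final fork* (branching profiles like 3-1-2 or 3-1-1-1-2), which
covers all presets and reduced variants; other small trees can be solved
with the oracle. Gaussian environments have continuous belief spaces and
are rejected with a pointer to the goal-setting approximation.

### Numerical choices

Values are doubles; supports and costs are small rationals, and error
growth is bounded by tree depth, so a 1e-9 tie tolerance cleanly
separates genuinely tied computations from numerical noise. Where a
single "the" optimal computation is needed (policy rollouts), ties break
deterministically: terminate first, then the first unobserved node in
depth/index order. The feedback engine always works with the full argmax
set, so tie-breaking never affects feedback.

## Environments

The tutor's training environment (`training_3step`) draws rewards from
uniform supports $\{-4,-2,+2,+4\}$, $\{-8,-4,+4,+8\}$ and
$\{-48,-24,+24,+48\}$ at depths 1–3 with a \$1 click cost, so the range
of outcomes grows steeply with depth and far-sighted planning pays. The
unstructured variant (`constant_3step`) uses $\{-10,-5,+5,+10\}$ at every
depth. The transfer environment (`transfer_5step`) has five steps,
zero-mean Gaussian rewards with sd $2^{i-1}$ at depths 1–4 and $2^5 = 32$
at the final step, and a \$3 click cost.

The webs' exact topologies are only shown as rendered figures in the
experimental literature, so the tree shapes here are the package's own
interpretation: branching 3-1-2 for the three-step web (three first
moves, one successor each, two final states per branch; 12 reward nodes)
and 3-1-1-1-2 for the five-step task. Both are configurable via
`make_env()` or the `branching` argument of `preset_env()`; the 3-1-2
default keeps the exact solve tractable while preserving the multi-branch
structure that makes goal setting meaningful.

Ground truths are sampled with a per-node sub-seed derived from the trial
seed and the node's position, so each node's draw is independent of the
order in which nodes are processed and fully reproducible.

## From loss to feedback

Each inferred planning operation $c$ in belief $b$ is scored by its loss
$\mathrm{loss}(b, c) = \max_{c'} Q(b, c') - Q(b, c)$, the regret relative
to the best available computation. The tutor translates loss into a delay
penalty of $2 + a \cdot \mathrm{loss}(b, c)$ seconds for suboptimal
operations and no delay for optimal ones. The scaling factor $a$ is
calibrated per environment by `calibrate_scaling()` so that the worst
planning decision — terminating at the empty belief, i.e. acting without
any planning — costs exactly 42 s. In information-bearing modes the tutor
also highlights the click targets of the optimal computation set and
shows one of two instructions ("You should have inspected one of the
highlighted nodes." / "You shouldn't have inspected any more nodes.");
optimal operations earn "Good job!". Terminating when clicking was
optimal, and clicking when terminating was optimal, are both scored by
the same loss formula through the terminate computation — no special
case.

The component-analysis variants decompose this feedback: delay-only drops
the instruction, info-only shows the instruction for at least 1 s without
a loss-proportional delay, and both can sit on top of a 1-s unconditional
click delay with post-trial delays of 11 s (delay-bearing cells) or 1 s.
The full condition adds the penalty to the unconditional delay
(additive); the alternative reading (taking the maximum) differs only in
a constant second and was rejected because the penalty is described as
*additional*. Delays are recorded in the feedback events, never slept —
a session runner may interpret them.

Action feedback, the conventional control, evaluates only the first move
with the task-level loss: the best full-information path total minus the
best total among paths starting with the chosen move. It reuses the same
delay equation and the same calibrated $a$; whether the original tutor
re-calibrated the scaling for task-level losses is not specified, and
reusing it is the reading most consistent with "same equation, same
constants". Direction labels default to left/up/right for three first
moves and are configurable, since screen geometry is not part of the
model.

## Scoring

Raw scores (path sum minus click fees) are normalized as

$$\mathrm{relative}(s) = 100 \cdot \frac{s - \bar{s}_{\mathrm{rand}}}
{\bar{s}_{\mathrm{opt}} - \bar{s}_{\mathrm{rand}}},$$

so 0 is the expected score of picking a path uniformly with no clicks and
100 is optimal. In solvable environments both anchors are exact:
$\bar{s}_{\mathrm{opt}}$ is the solver's value of the empty belief and
$\bar{s}_{\mathrm{rand}}$ is the mean over paths of the prior depth means
(zero for every symmetric preset). In environments too large to solve,
$\bar{s}_{\mathrm{opt}}$ is approximated by the goal-setting strategy:
check final states in random order until one exceeds a threshold, commit
to it, otherwise take the best final state seen. "Above the threshold" is
read strictly, so with support $\{-48,-24,+24,+48\}$ a threshold of 24
stops only at the best possible value — which is exactly the behavior the
optimized threshold selects in the training environment. The threshold is
optimized by Monte-Carlo search over the final-step support values plus
midpoints (or 17 evenly spaced quantiles for Gaussian rewards), with
common random numbers across candidates for variance reduction; whether
the original evaluation used common random numbers is unstated, and the
choice only reduces comparison noise. Since the goal-setting strategy is
a feasible policy, its mean score lower-bounds the true optimum; using it
as the score ceiling therefore slightly inflates relative scores in
environments where it is the only available anchor.

Per-trial relative scores are not clipped to $[0, 100]$: averaging
happens on the raw normalized scale, first within participant, then
across participants, with percentile bootstrap CIs from participant-level
resampling (1,000 resamples, seeded). Endowments and bonus conversions
are excluded from raw scores; a constant offset would have to be added to
both anchors to cancel, so exclusion is the internally consistent choice.

Backward planning — the signature of the discovered strategy — is
operationalized as the first click landing on a final-step node; trials
with no clicks count as not planning backward.

## Synthetic sessions

`simulate_participant()` produces complete training + test sessions for
four scripted strategies: `optimal` (the solved policy), `backward_lapse`
(optimal with a per-operation lapse probability, defaulting to 0.1, that
substitutes a uniformly random legal computation — a minimal stand-in for
imperfect execution), `forward_satisficer` (clicks first-step nodes in
order and moves at the first value at or above a threshold, defaulting to
0, i.e. any non-negative immediate reward — a myopic foil), and
`non_planner` (no clicks, random path). Defaults for block sizes are 10
training and 20 test trials.

These scripts are fixtures, not models of human participants: they do not
learn across trials (no learning model is part of this package's scope),
their parameters are not fitted to any human data, and their purpose is
to give the feedback engine and the scoring pipeline inputs with known
properties — e.g. the optimal cohort must show a backward-planning rate
of exactly 1.0 and a mean relative score near 100, and the non-planner
must draw the full 42-s delay on every training trial. Passing tests on
these cohorts validates the machinery, not any claim about real
participants, whose variability, learning dynamics and lapses are far
richer than these scripts.

`make_fixture_suite()` writes environment configs, a solved toy Q table,
and one session log per feedback condition × strategy, with an MD5
manifest; identical seeds reproduce byte-identical files.

## Problem sizes used for validation

The package's own test and acceptance runs use: the full 3-1-2 training
solve (~1.9 M canonical states, a few seconds) plus a 2-1-2 reduced
variant for fast qualitative checks; Monte-Carlo policy evaluations at
n = 10,000 with 3-standard-error bands; threshold optimization at
n_sim = 10,000 with common random numbers; and 1,000 bootstrap resamples
throughout. These sizes make the Monte-Carlo bands a few tenths of a
point wide on the relative-score scale — tight enough to detect any real
inconsistency between the simulated policies and the exact solver.

## Known limitations

* The exact solver covers fork-shaped trees with up to four root
  branches; wider or irregularly branched trees need either the
  brute-force oracle (small) or an approximate solver (out of scope).
* Gaussian environments are handled only through the goal-setting
  approximation; their metalevel MDP is not solved.
* Observed planning operations are limited to clicks; planning that
  happens without clicking is invisible to the loss computation, exactly
  as it is to the original tutor.
* The serialized Q-table format is intended for toy environments;
  large tables are meant to be re-solved from the environment config,
  which is faster than shipping them.
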