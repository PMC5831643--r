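---
title: "Modelling rupture and repair in the multi-round trust game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rupture and repair in the multi-round trust game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trustgame)
```

## The task and its discretization

The multi-round trust task (MRT) is a 10-round economic exchange between an
*investor* and a *trustee*. Each round the investor receives an endowment of
20 monetary units and sends some of it; the amount in transit is tripled; the
trustee returns any share of what arrived. The round payoffs are

$$\chi^I = 20 - a^I + a^T, \qquad \chi^T = 3a^I - a^T,$$

so the joint payoff $20 + 2a^I$ grows with trust. The package works on a
coarse action grid: investments are fractions $\{0, \tfrac14, \tfrac12,
\tfrac34, 1\}$ of the endowment, repayments fractions $\{0, \tfrac16,
\tfrac13, \tfrac12, \tfrac23\}$ of the tripled amount. Repayment amounts are
rounded to the nearest integer, halves away from zero, which only matters for
the 1/6 and 1/3 fractions of 15 and 45 (grids are documented in
`tg_return_grid()`). A zero investment forces a zero return; the forced move
carries no information and is excluded from all inference. Raw data on a
finer monetary scale are mapped onto the grid by `round_to_grid()` (nearest
point, ties upward — a deterministic convention; ties cannot occur for
integer raw investor actions).

## Subject model

Each player is described by seven parameters (`tg_params()`):

| parameter | values | meaning |
|---|---|---|
| guilt $\alpha$ | 0, 0.4, 1 | aversion to advantageous inequality |
| plan $P$ | 1–4 | future own decision rounds considered |
| theory of mind $k$ | 0, 2, 4 (investor); 0, 1, 3 (trustee) | recursion depth of partner modelling |
| inverse temperature $\beta$ | 1, 1/2, 1/3, 1/4 | choice determinism (softmax) |
| risk aversion $\omega$ / belief $b(\omega)$ | 0.4–1.8 by 0.2 | value of kept endowment vs repaid money |
| irritability $\zeta$ | 0–1 by 0.25 | step size of the irritation weight |
| awareness $q(\zeta)$ | 0–4 | prior on the partner's irritability |

Utilities are Fehr–Schmidt with only the advantageous-inequality (guilt)
term: a player who ends the round ahead of the partner loses $\alpha$ per
point of difference. The investor additionally weights the endowment she
keeps by $\omega$:

$$r^I = \omega\,(20 - a^I) + a^T - \alpha\max\{\chi^I - \chi^T, 0\},$$

with the guilt comparison made on the *raw* payoffs: risk aversion redefines
the subjective value of money kept, not the fairness ledger. (The
alternative — comparing $\omega$-weighted payoffs — is a genuinely open
reading; we chose the raw comparison because the risk weighting is introduced
purely as a modification of the kept-endowment term, and we flag it as a
sensitivity-analysis candidate.) The trustee carries no risk parameter; she
instead assumes a fixed value $b(\omega)$ for the investor's, which is common
knowledge within her model (both players are modelled as consistent, so one
$\omega$ value propagates unchanged down the whole recursive stack).

Choices are softmax in action values, $\pi(a) \propto e^{\beta Q(a)}$, with
$\beta = \infty$ accepted as a diagnostic sentinel for the argmax limit
(ties resolved uniformly over maximizers, preserving the symmetry of the
softmax it limits).

## Opponent inference

Players learn about two partner traits simultaneously and independently:
guilt and irritability. Both use the same approximate conjugate scheme
(`tg_belief()`, `update_guilt()`, `update_irritability()`): a Dirichlet
weight per candidate value, incremented after every informative observation
by the probability the corresponding partner model assigned to the observed
action. The guilt prior is flat, $(1,1,1)$. The irritability prior is
selected by the awareness parameter $q$ (`irritability_prior()`), ranging
from *ignorant* (effectively certain the partner cannot become irritated)
through *optimistic*, *realistic* and *pessimistic* to *fatalistic*.
Factorizing the two beliefs is a deliberate simplification: the irritability
inference is specified as a parallel copy of the guilt inference, never a
joint distribution.

Alongside the posterior over irritability, the observer deterministically
tracks, for every candidate $\zeta$, the partner's hypothetical current
irritation weight $v_\iota(\zeta)$ (`update_partner_irritation()`), so the
predicted partner policy (`predicted_partner_policy()`) is a mixture over
guilt values and irritability hypotheses, with each hypothesis blending the
planned partner policy and the irritated policy at its tracked weight.

## Irritation

Irritation is an internal state shift, not a preference: an irritated player
behaves as a different, simpler agent. The irritated configuration
(`irritated_params()`) is myopic ($P = 0$), guilt-free ($\alpha = 0$),
moderately deterministic ($\beta = 1/2$), ignores all accumulated beliefs,
and for investors has risk aversion bounded below at 1, which guarantees
punitive (zero-investment-leaning) behaviour. A player's behavioural policy
is the convex mixture $(1 - v_\iota)\tilde\pi + v_\iota \pi_\iota$ of planned
and irritated policies at the current irritation weight.

The weight starts at 0 and moves in steps of the player's irritability:
$v_\iota \leftarrow \min\{v_\iota + \zeta, 1\}$ when the partner's action
falls short of the value the player expected, and
$v_\iota \leftarrow \max\{v_\iota - \zeta, 0\}$ when it exceeds it (repair).
"Expected value" is the posterior-predictive mean monetary amount of the
partner's action under the player's full partner model, including the
partner's potential irritation — not the modal action. An action exactly at
expectation, or a forced move, changes nothing: the dynamics are defined
only for strict shortfall and strict excess.

Two design choices here were genuinely open and deserve explanation:

* **What an irritated player assumes about the partner.** We let irritated
  players assume maximal distrust: the investor expects nothing back, the
  trustee attaches no value beyond the current round. With a uniform partner
  assumption and $\omega_\iota = 1$ the irritated investor's utilities would
  be flat across investments, contradicting the requirement that bounding
  $\omega_\iota$ below at 1 produce punishing behaviour; under maximal
  distrust, investing nothing is strictly optimal for every
  $\omega_\iota \ge 1$. The uniform alternative is retained behind
  `irritated_expectation = "uniform"` for comparison.
* **What "complete disregard of beliefs" erases.** Beliefs are ignored
  *while* irritated but keep updating; nothing is deleted. Repair
  presupposes a persistent model to return to.

Players never plan over their own future irritation, and are unaware of
their own irritability: a "cold" agent cannot simulate its own "hot"
behaviour. Their partners, however, may model it — which is exactly how an
aware trustee anticipates and defuses a brewing rupture.

## Planning: one shared tree, one pass per level

A level-$k$ player models a level-$(k-1)$ partner, down to the level $-1$
agent, which holds a uniform belief over partner guilt and neither learns
nor plans (immediate expected utility only). Investor behaviour gains
nothing from odd levels nor trustee behaviour from even ones, hence the
role-specific level grids.

`tg_policy()` computes action values by building a single game tree of depth
$H = \min(P, \text{rounds left})$ from the current decision. Along every
branch, the full nested belief stack (the player's beliefs, the modelled
partner's beliefs, and so on down the hierarchy) is filtered exactly as it
would be for real observations, and hypothetical actions move the partner
irritation tracks, so the planner anticipates rupture and repair. Values are
then computed by backward induction — at every level, future own choices are
weighted by the own softmax policy.

The computation is organised the way the memory-for-computation trade-off
demands: levels are evaluated bottom-up *inside the same tree*, each level's
policies stored at every node for the level above. Cost is therefore linear
in $k$ (one forward and one backward pass per level over a fixed node set;
`tg_tree_stats()` exposes both quantities) instead of exponential. The
price is a horizon approximation: an embedded lower-level agent sitting $d$
rounds into the tree plans only over the remaining $H - d$ rounds rather
than its own full horizon. At the root — where the policy is actually read
off — the horizon is exact. Two further bottom-outs close the recursion:
the level $-1$ agent supplies no expectation of its partner, so the
favourability of actions judged from its viewpoint is referenced to the
unweighted mean of the legal amounts (10 for investments, the return-grid
mean for repayments); and the awareness index $q$ propagates unchanged down
the stack, since a dyad has only two awareness parameters.

Everything is closed-form and deterministic — no Monte Carlo enters the
planner — so identical queries return bit-identical policies, and the
compiled engine is required (by test) to agree with a naive reference
implementation written in plain R on every node and level of small
configurations. A node-budget guard refuses configurations whose tree would
exceed a configurable node count rather than silently approximating; the
largest canonical configuration ($k = 4$, $P = 4$) stays well inside the
default budget.

## Simulation and the synthetic cohort

`tg_simulate()` plays dyads forward: each round the acting player samples
from their behavioural mixture policy; both players then update. Scenarios
(`tg_scenario()`) force selected actions by fiat — forced actions are
observed and drive inference exactly like chosen ones. The shipped rupture
probe (`tg_scenario_rupture()`) scripts a cooperative first round (20 in, 30
back) and a subpar second-round repayment (10 of 60), then frees play; with
an irritable investor ($\zeta = 0.5$) the second round raises $v_\iota^I$ to
exactly 0.5. The precise forced amounts of the original probe are not
published; ours are a documented parameterization chosen so that the
expected repayment (about half the tripled amount) is undershot by the 1/6
fraction.

`generate_cohort()` draws dyads from group specifications. The shipped
presets emulate only the *model-based composition* attributed to clinical
cohorts — a "perilous" trustee prevalence of 0.29 (healthy-control-like) or
0.60 (borderline-like), where perilous means guilt-free ($\alpha^T = 0$) or
irritation-unaware ($q^T = 0$) — with all other parameters drawn uniformly
from desk-scale subgrids. Perilousness is sampled exactly at the target
rate (guilt-free only / unaware only / both, at 0.4/0.4/0.2). The generator
emulates none of the demographic structure of real cohorts (age, IQ, SES,
diagnosis), no within-subject nonstationarity beyond the modelled state
shift, and its play is model-generated by construction — so passing
recovery tests demonstrates internal consistency of the estimator, not
clinical fidelity. Per-dyad seeds derive from the master seed by counter, so
any single dyad regenerates in isolation.

## Fitting and model comparison

`tg_fit()` is an exhaustive maximum-likelihood grid search over
`tg_grid()`. The likelihood is one-step-ahead: at each round the behavioural
policy given the dyad's *actual* prior history is evaluated at the action
the subject actually took; forced trustee rounds contribute nothing.
Predictive probabilities are floored at $10^{-12}$ before the log — the
floor cannot bind for finite $\beta$ on the softmax grid, so hitting it
(possible only with the $\beta = \infty$ sentinel) warns loudly. NLL ties
are broken by the grid's lexicographic order (alpha, plan, tom, beta, omega,
zeta, awareness), making fits reproducible across platforms regardless of
how the grid was specified.

Model comparison uses likelihood-ratio tests across nested grids
(`tg_lrt()`; the statistic $\sum_s 2(\mathrm{NLL}^s_{\text{simple}} -
\mathrm{NLL}^s_{\text{rich}})$ against a $\chi^2$ quantile) and a BIC with a
small-sample correction, per subject $2\,\mathrm{NLL} + n(\log m - \log
2\pi)$ with $m = 10$ choices (`tg_bic()`). `recovery_study()` closes the
loop: simulate a cohort with known parameters, refit, and tabulate
confusion matrices.

```{r recovery-example}
coh <- generate_cohort(tg_group_spec("demo", perilous_prevalence = 0.3),
                       n_per_group = 8, seed = 11)
grid <- tg_grid("investor", alpha = c(0, 0.4, 1), plan = 1, tom = 0,
                beta = 1/3, omega = c(0.6, 1.0, 1.4, 1.8),
                zeta = c(0, 0.5, 1), awareness = 2)
rec <- recovery_study(coh, "investor", grid)
rec$confusion$zeta
```

## Problem sizes and numerical conventions

The package's own studies run at desk scale, chosen to exercise every
mechanism while keeping any single check in the minutes range: rupture/repair
contrasts use 200 seeded runs per arm of the paired scenario at $k = 2/1$,
$P = 4$; recovery uses 50 simulated subjects fitted on a reduced grid
($k \le 2$, $P \le 2$, $\zeta \in \{0, 0.5, 1\}$, four $\omega$ values, one
$\beta$). The guilt value 0.4 is behaviourally close to 0 in myopic play
(the inequality penalty rarely binds for low returns), so its recovery
leans on planning-horizon effects and is the weakest of the three traits —
visible in the off-diagonal mass of its confusion matrix.

Numerical conventions, collected in one place: repayment grids round halves
away from zero; `round_to_grid()` breaks ties upward; argmax ties in the
$\beta = \infty$ limit are uniform over maximizers (tolerance $10^{-10}$);
predictive probabilities clamp at $10^{-12}$ with a warning; neutral
favourability (action exactly at expectation) updates nothing; forced moves
update nothing; Dirichlet weights are carried at full precision (updates are
additive and games are short, so no quantization is needed for cache
correctness).

## Known limitations

* Embedded lower-level agents have truncated horizons near the tree
  boundary (exact at the root); this is the cost of linear-in-$k$ planning.
* The action space is coarse (5 × 5) and the parameter grids discrete;
  everything downstream (fits, recovery) inherits that granularity.
* Irritation is symmetric (same step up and down), undiscounted, and
  unaware of itself; richer affective dynamics are out of scope.
* The synthetic cohorts are stand-ins for undeposited behavioural data;
  conclusions about real populations cannot be drawn from them.
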