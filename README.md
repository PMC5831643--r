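# trustgame

Generative modelling of dyadic behaviour in the 10-round **multi-round trust
game** (MRT): an investor repeatedly decides how much of a 20-unit endowment
to entrust to a partner, the amount is tripled, and the trustee decides how
much to return. The package is for computational-psychiatry and
behavioural-economics researchers who want to *simulate*, *fit* and
*classify* play in this task with an interactive POMDP (I-POMDP) subject
model.

## The model

Each player is a level-*k* theory-of-mind agent described by seven discrete
parameters: guilt α ∈ {0, 0.4, 1} (Fehr–Schmidt advantageous-inequality
aversion), planning horizon P ∈ {1..4}, theory-of-mind level k (investors
0/2/4, trustees 0/1/3), softmax inverse temperature β ∈ {1, ½, ⅓, ¼},
social risk aversion ω ∈ {0.4, …, 1.8} (the trustee instead assumes a fixed
value b(ω)), irritability ζ ∈ {0, 0.25, 0.5, 0.75, 1}, and irritability
awareness q(ζ) ∈ {0..4}.

Round payoffs are χ<sup>I</sup> = 20 − a<sup>I</sup> + a<sup>T</sup> and
χ<sup>T</sup> = 3a<sup>I</sup> − a<sup>T</sup>; the investor's utility
weights kept endowment by ω and both roles pay a guilt penalty
α·max{own − partner, 0} on raw payoffs. Players infer each other's guilt
*and* irritability with additive Dirichlet-multinomial updates, while
deterministically tracking the partner's hypothetical irritation weight
v<sub>ι</sub>(ζ). Irritation is an internal state shift: after a
worse-than-expected partner action, v<sub>ι</sub> rises by ζ (clipped at 1)
and the behavioural policy mixes toward a myopic, guilt-free, punitive
policy; better-than-expected actions repair it. Planning runs over a single
deterministic shared game tree of depth min(P, rounds left), with every
lower theory-of-mind level evaluated bottom-up inside the same tree — cost
linear in k — and with belief updates and irritation dynamics propagated
along every hypothetical branch, so agents can foresee (and defuse)
ruptures.

On top of the planner sit: a dyad simulator with scriptable "by fiat"
scenarios, synthetic cohort generation (including presets enriched for
"perilous" trustees: guilt-free or irritation-unaware), one-step-ahead
maximum-likelihood fitting over the discrete parameter grid,
likelihood-ratio and BIC model comparison, parameter-recovery studies, and
the perilous-trustee classifier.

## Worked example

Simulate the shipped rupture/repair probe — a cooperative first round, a
scripted subpar repayment in round 2 — for an irritability-aware dyad with
an irritable investor, then refit the investor from the behaviour alone:

```r
library(trustgame)

investor <- tg_params("investor", alpha = 0.4, plan = 4, tom = 2, beta = 1/3,
                      omega = 1, zeta = 0.5, awareness = 2)
trustee  <- tg_params("trustee",  alpha = 0.4, plan = 4, tom = 1, beta = 1/3,
                      omega = 1, zeta = 0, awareness = 2)

sim <- tg_simulate(investor, trustee, tg_scenario_rupture(),
                   n_runs = 1, seed = 2)
d <- tg_dyad(sim)
data.frame(round = d$round, investment = d$investment,
           repayment = d$repayment, v_investor = attr(d, "v_investor"))
#>    round investment repayment v_investor
#> 1      1         20        30        0.0
#> 2      2         20        10        0.0
#> 3      3          0         0        0.5
#> 4      4         20        30        0.5
#> 5      5         15        23        0.0
#> 6      6         20        20        0.0
#> 7      7         20        30        0.5
#> 8      8         20        30        0.0
#> 9      9         20        30        0.0
#> 10    10          5         0        0.0
```

The round-2 defection (10 of 60 returned) raises the investor's irritation
weight to 0.5; she retaliates with zero investment in round 3. The aware
trustee infers the irritation and repays generously (30 of 60) in round 4 —
the irritation repairs back to 0 and cooperation resumes until the usual
end-game unravelling.

```r
fit <- tg_fit(d, role = "investor",
              grid = tg_grid("investor", alpha = c(0, 0.4, 1), plan = 4,
                             tom = 2, beta = 1/3, omega = c(0.6, 1.0, 1.4),
                             zeta = c(0, 0.5, 1), awareness = 2))
summary(fit)
#> Maximum-likelihood fit of a investor over 27 grid points
#> <tg_params> investor: alpha=0.4 P=4 k=2 beta=0.333333 omega=1 zeta=0.5 q=2
#>   NLL 6.2982  (chance: 10 free choices x log 5 = 16.0944)
#>   BIC 13.9905 with 3 free parameters, m = 10
#>   mean per-choice predictive probability 0.602
```

The fit recovers the generating guilt (0.4), risk aversion (1.0) and
irritability (0.5) exactly, with an NLL of 6.30 against a chance level of
16.09 (10 choices × log 5); the mean per-choice predictive probability is
0.60 versus 0.20 at chance. `predict()`, `simulate()` (one-step-ahead
trajectory regeneration), `residuals()` and `plot()` methods give the usual
model-object workflow; `classify_perilous()`, `generate_cohort()`,
`recovery_study()`, `tg_lrt()` and `tg_bic()` cover cohort-level analyses.

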