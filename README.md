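# pufval

**Personal utility functions for health-state valuation.**

Health-economic evaluation needs *value sets*: a utility for every state a
patient-reported outcome instrument can describe, anchored at full health = 1
and dead = 0, so that quality-adjusted life years (QALYs) can be computed.
Conventional valuation methods (time trade-off, discrete choice experiments)
value a subset of states and infer the rest by regression. The *personal
utility function* (PUF) approach instead asks each respondent directly about
the relative importance of the instrument's dimensions and severity levels,
builds that respondent's complete utility function, anchors it at dead, and
averages the individual functions into a social value set.

`pufval` implements this approach for a simplified EQ-5D descriptive system:
five dimensions — mobility (MO), self-care (SC), usual activities (UA),
pain/discomfort (PD), anxiety/depression (AD) — with three levels each
(1 = no, 2 = moderate, 3 = extreme problems), a space of 3^5 = 243 states
coded as digit strings like `"21312"`. It is intended for researchers
designing or analysing PUF-style elicitation studies, and for simulation
work on the method itself.

## The model

For respondent *i*, section C swing ratings `r_d` (0–100, most valued swing
= 100) give relative dimension weights

    w_d = r_d / Σ_e r_e ,   Σ_d w_d = 1 ,

and section D point allocations `p_d` (0–100 for the extreme→moderate
improvement) give level-2 fractions. Utility of state *s* with level
`l_d(s)` on dimension *d* is

    u(s) = 1 − Σ_d δ_{d, l_d(s)} ,   δ_{d,1} = 0 ,
    δ_{d,3} = w_d ,   δ_{d,2} = w_d · p_d / 100   (default convention),

so `u("11111") = 1` and `u("33333") = 0`. Ranking all 243 states by `u`
drives the adaptive tasks: two non-dominating validation pairs (one easy,
one hard), and a five-task bisection search comparing 10 years in a state
against dying now, which brackets the respondent's location of dead within
15–16 ranks. Anchoring sets the bracket midpoint `u_dead` to zero:

    v(s) = (u(s) − u_dead) / (1 − u_dead) ,

and the social utility function (value set) is the mean (or median) of the
anchored decrements across respondents.

## Worked example

```r
library(pufval)

fit <- puf(swing = c(100, 80, 80, 90, 82), allocation = c(55, 50, 50, 60, 45))
fit
#> <puf> level-2 mapping: share_of_swing
#>    weight level2_fraction decrement2 decrement3
#> MO 0.2315            0.55     0.1273     0.2315
#> SC 0.1852            0.50     0.0926     0.1852
#> UA 0.1852            0.50     0.0926     0.1852
#> PD 0.2083            0.60     0.1250     0.2083
#> AD 0.1898            0.45     0.0854     0.1898
```

The swing ratings sum to 432, so mobility's weight is 100/432 ≈ 0.2315;
its level-3 decrement equals that weight, and its level-2 decrement is the
weight times the 55/100 allocation. Utilities follow directly:

```r
predict(fit, c("11111", "21111", "31112", "33333"))
#>   11111   21111   31112   33333
#>  1.0000  0.8727  0.6831  0.0000
```

Rank the 243 states and run the bisection search for dead. A respondent who
prefers dying now over `"33333"` but 10 years in every milder state
presented ends up with dead bracketed between their 228th- and 243rd-ranked
states:

```r
rk <- rank_states(fit)
ans <- local({ i <- 0; function(s) { i <<- i + 1; if (i == 1) "B" else "A" } })
search <- run_dead_search(rk, ans)
search$bracket
#> <dead_bracket>bracketed lower rank 228 upper rank 243

u_dead <- dead_utility(fit, search$bracket, rk)   # 0.0984: bracket midpoint
anchored <- anchor_puf(fit, u_dead)
predict(anchored, c("11111", "33333"))
#>  11111  33333
#>  1.000 -0.109
```

After anchoring, full health stays at 1, the dead midpoint maps to 0, and
`"33333"` is worse than dead for this respondent (−0.109). Aggregating the
published pilot decrement table into a value set:

```r
vs <- value_set(pilot_table("table9"), central = "mean")
round(vs$values[c("11112", "33333")], 3)
#>  11112  33333
#>  0.846 -0.667
```

The mildest impaired state `"11112"` is valued 0.85 and the worst state
−0.667, the minimum of this value set. For a whole study file, the one-shot
pipeline is `estimate_value_set(read_study("study.json"))`; synthetic
cohorts come from `simulate_cohort(simulation_config(...))`, and
`recovery_report()` quantifies how well the pipeline recovers known latent
preferences. A thin command-line wrapper over these functions ships in
`inst/cli/puf-valuation.R` (subcommands `simulate`, `validate`, `puf`,
`tasks`, `anchor`, `valueset`).

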