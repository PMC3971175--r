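# aitrust

Active-inference agents for the iterated two-choice Trust game.

## What this is for

How do people decide whether to trust a stranger — and how do beliefs about
*what kind of person* the other is shape that decision? `aitrust`
implements a computational account for researchers in computational
psychiatry and social decision-making: a discrete-state active-inference
agent that plays an iterated Trust game against a partner whose prosocial
or antisocial disposition ("esteem") is a hidden trait. The agent's goals
are prior beliefs over outcomes; inferring the partner's trait from
observed exchanges is ordinary Bayesian inference in the same model — a
minimal, fully formal version of mentalizing.

## The model in brief

Each round, the self earns a wage *w* and cooperates (high investment) or
defects (low investment); the investment is multiplied by a gain *g* and
the partner returns a fraction of it, giving monetary returns
`r^s = w − w f^s + w f^s f^o`, `r^o = w f^s g − w f^s f^o` (defaults use a
worked 2×2 return table). The self's world model has 10 hidden states — 5
observable situations (start, `cc`, `dc`, `cd`, `dd`) × 2 partner traits —
with an identity-on-observables likelihood **A**, control-dependent
transitions **B**(u) that never change the trait, and a goal prior

    P(s_T | m) = softmax(utility(s_T)),   utility = β_r·return ± (e^s + e^o)

where the esteem term's sign follows the acting player's own
cooperate/defect choice (a social Pavlovian bias). Policies are scored by
the KL divergence between predicted and desired outcome distributions,

    P(ũ | s_t, γ, m) ∝ exp(−γ · KL[P(s_T | s_t, ũ) ‖ P(s_T | m)]),

and the precision γ of policy selection is itself inferred under a
gamma(α = 8, θ = 1) prior by variational message passing: cyclic
fixed-point updates of state, policy and precision expectations that
minimize free energy. The naive partner just softmaxes its own augmented
returns. Iterated play feeds each round's posterior about the partner back
as the next round's prior.

See `vignette("trust-active-inference")` for the full model, the
calibration of the esteem/sensitivity defaults, and the engine's numerical
choices.

## Worked example

```r
library(aitrust)

cfg <- trust_config()        # defaults: wage 20, gain 3, calibrated beta_r
model <- build_self_model(cfg)

# what the self wants: goal-prior preferences over the 10 states
head(self_preference_ordering(cfg), 4)
#>   state probability  utility
#> 1  cc.p   0.3244947 2.527724
#> 2  cc.n   0.1611393 1.827724
#> 3  dc.n   0.1358502 1.657008
#> 4  dd.n   0.1087578 1.434578

# before anything happens, cooperation is favored despite agnosticism
pre <- infer(model, "start")
pre$u_hat
#> [1] 0.98825984 0.01174016

# one mutual defection makes "antisocial" the better explanation
post <- infer(model, c("start", "dd"), actions = "defect")
sum(post$s_hat[[2]][6:10])   # P(antisocial)
#> [1] 0.9244641

# a 32-round game against the antisocial naive partner
trace <- run_game(cfg)
trace
#> <game_trace> 32 rounds (seed 1, other 'n')
#>   cooperation rate 0.500; final P(antisocial) 1.000
```

The first table reads: mutual cooperation with a prosocial partner is the
best outcome (`cc.p`), and with an antisocial partner the self would rather
exploit (`dc.n`) than be exploited (`cd.n`). `pre$u_hat` is the belief over
{cooperate, defect} before acting; the posterior after `dd` shows one bad
outcome already tilting the trait belief. Over a full game the agent
typically becomes confident the partner is antisocial and cooperates less
in the second half than in the first.

A command-line wrapper with `run`, `round`, `calibrate`, `validate` and
`fixtures` subcommands is installed at `inst/cli/trustgame.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/trustgame.R", package="aitrust"))')" \
    run --rounds 32 --seed 1 --out trace.csv
```

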