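---
title: "Interpersonal inference in a two-choice Trust game: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpersonal inference in a two-choice Trust game: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aitrust)
```

## The model

`aitrust` simulates a player ("self") in an iterated, two-choice Trust game
against a partner ("other") whose disposition is hidden. Each round the self
earns a wage $w$ (default 20 play-money units) and either *cooperates*
(invests a high fraction of the wage) or *defects* (invests a low fraction).
The investment is multiplied by a gain $g$ (default 3) and the other returns
a fraction of the invested amount, so the round's monetary returns are

$$r^{s} = w - w f^{s} + w f^{s} f^{o}, \qquad
  r^{o} = w f^{s} g - w f^{s} f^{o},$$

and the pot $r^s + r^o = w(1 + f^s(g-1))$ depends only on the self's
investment. Rather than fixing fractions, the default configuration uses a
$2\times 2$ table of worked returns (`payoff_config()`); a table can also be
generated from fractions through `monetary_returns()`, and supplying both
triggers a consistency check, because an arbitrary printed table need not be
realisable by any single fraction quadruple.

The self models the world as a discrete partially observed Markov decision
process. Within a round there are 5 observable situations — the start state
and the four action pairs `cc`, `dc`, `cd`, `dd` (self's action first) — and
the other carries a binary hidden trait, its *esteem*: prosocial
($e^o = p > 0$) or antisocial ($e^o = n < 0$). Crossing the 5 observables
with the 2 traits gives the 10 hidden states. The likelihood matrix $A$ is
the deterministic projection of a hidden state onto its observable
component: observations identify the situation but never the trait, which
must be inferred. Transitions $B(u)$ depend on the self's control $u$: from
a start state, cooperating or defecting leads to the corresponding outcome
pair with the probability that the other responds one way or the other;
outcome states are absorbing within a round; and no transition ever changes
the trait component (traits are traits precisely because they do not
change).

### Goals as prior beliefs

Preferences enter as a prior over outcome states,
$P(s_T \mid m) = \sigma(r(s_T), \beta)$ — a softmax of state utilities. The
self's utilities are *esteem-augmented* returns: for each cell,
$\beta_r \, r + \mathrm{sgn} \,(e^{s} + e^{o})$, where the sign is $+$ when
the acting player's own action is cooperate and $-$ when it defects. This
is a social Pavlovian bias: cooperation is intrinsically attractive in good
company and aversive in bad company, over and above the money. The two
start states are pinned to prior probability zero (they never materialise
as outcomes), and the softmax over the remaining 8 utilities is taken with
sensitivity 1, because $\beta_r$ already scales the returns inside the
utilities — exposing a second sensitivity there would double-count it.

Policies $\tilde u$ are scored by how closely the outcome distribution they
lead to, $P(s_T \mid s_t, \tilde u) = B(u_T)\cdots B(u_t)\, s_t$, matches
the desired one:

$$P(\tilde u \mid s_t, \gamma, m) = \tfrac{1}{Z}
  \exp\left(-\gamma\, D_{KL}\!\left[P(s_T \mid s_t, \tilde u)\,\|\,
  P(s_T \mid m)\right]\right).$$

The negative divergence splits exactly into an entropy term plus expected
log-goal "utility" (`value_decomposition()`), so choosing low-divergence
policies is expected-utility maximisation under a maximum-entropy
constraint. The precision $\gamma$ is not a free inverse-temperature: it is
itself inferred, under a gamma prior with shape $\alpha = 8$ and scale
$\theta = 1$, and encodes the confidence that the goals are attainable at
all.

### The naive other

The other performs no inference. It responds to the self's realised action
with a one-shot softmax of its *own* augmented returns,
$P(u^o \mid u^s) = \exp(r^o)/\sum_c \exp(r^o)$, using its true esteem and
attributing the self's (neutral) self-esteem to the self — the self, in
turn, uses exactly this rule, under each candidate trait, to build the
transition probabilities of its model. Self-knowledge thus doubles as a
model of how one is seen, which is the package's minimal form of
theory-of-mind.

## Parameters and calibration

The parameters that matter, with defaults:

| parameter | default | units / range | role |
|---|---|---|---|
| `wage` | 20 | play money | stake per round |
| `gain` | 3 | multiplier | surplus of the joint venture |
| `return_self`, `return_other` | (26,10;21,18), (26,42;7,10) | play money | worked outcome tables |
| `e_prosocial` | +0.6 | utility units | esteem value of trait *p* |
| `e_antisocial` | −0.1 | utility units | esteem value of trait *n* |
| `e_self` | 0 | utility units | the self's own (neutral) esteem |
| `beta_r` | calibrated ≈ 0.0741 | 1/money | reward sensitivity |
| `shape`, `scale` | 8, 1 | — | gamma prior over precision |
| `n_rounds` | 32 | rounds | length of iterated play |

Only the *signs* of the esteem values are dictated by the model's
assumptions; their magnitudes and $\beta_r$ jointly determine the
qualitative preference structure the model is meant to exhibit. Working
through the utility algebra with $e^s = 0$:

* "within the prosocial block, the second-best outcome is to cooperate
  while the prosocial other defects" requires $2p > 11\beta_r$;
* "within the antisocial block, mutual cooperation still beats exploiting
  the other" requires $5\beta_r > 2|n|$;

which are jointly satisfiable only when $p > 2.2\,|n|$ — the esteem values
must be asymmetric, with prosociality valued more strongly than
antisociality is disvalued. Meanwhile `calibrate_beta_r()` fixes $\beta_r$
as the largest value (bisection to $10^{-6}$) at which no response
probability of the other exceeds 0.8, keeping the partner's behaviour
informative but stochastic; with the default tables this caps
$16\beta_r + 2|n| \le \ln 4$, which is feasible only for $|n| < 0.165$. The
shipped defaults $p = 0.6$, $n = -0.1$ sit comfortably inside this region
and give the calibrated $\beta_r \approx 0.0741$, at which the binding
response probability equals 0.8 exactly (the antisocial other facing a
cooperator). These values were chosen once from this algebra; the package
treats them as the standard study conditions.

## The variational engine

Beliefs are factorized into per-timepoint state expectations
$\hat s_\tau$, a policy expectation $\hat u$, and a gamma belief over
precision with expectation $\hat\gamma$. One sweep of `infer()` applies, in
order,

1. **states** — $\hat s_\tau \propto \exp(\ln A_{o_\tau} +
   \ln(B(u_{\tau-1})\hat s_{\tau-1}) + \hat\gamma\, Q^\top \hat u)$, with
   the initial belief replacing the transition message at the first
   timepoint, and the policy-value bias $\hat\gamma\, Q^\top\hat u$ applied
   at the current (final) timepoint on every sweep;
2. **policies** — $\hat u \propto \exp(\hat\gamma\, Q\, \hat s_t)$;
3. **precision** — posterior shape stays $\alpha$; the rate is
   $1/\theta - \hat u^\top Q\, \hat s_t$, so
   $\hat\gamma = \alpha/(1/\theta - \hat u^\top Q \hat s_t) \in
   (0, \alpha\theta]$, increasing in expected value.

Here $Q_{ij} = -D_{KL}[P(s_T \mid s_j, \tilde u_i) \,\|\, P(s_T \mid m)]$
is the value matrix (`compute_value_matrix()`). Sweeps repeat until the
free energy changes by less than `tol` ($10^{-6}$) or 64 sweeps are
reached, which on the Trust model takes well under ten sweeps.

Two free-energy flavours are deliberately distinguished. The *engine
objective* (what `infer()` minimises, records in `fe_trace`, and what
`free_energy(..., normalizer = FALSE)` returns) omits the
state-and-precision-dependent normalizer of the policy prior; the three
updates above are then exact coordinate minimisers of it, which guarantees
the non-increasing trace the tests check. The *full free energy*
(`free_energy()`, default) adds the normalizer term
$E_q[\ln Z(s_t, \gamma)]$, with the expectation over the gamma belief taken
by generalized Gauss–Laguerre quadrature; this is the complete term-wise
$E_Q[\ln Q - \ln P]$, and it is the quantity that upper-bounds surprise
$-\ln P(\tilde o \mid m)$ and touches it when an exact factorizable
posterior is supplied at fixed $\gamma$. Conflating the two would either
break the monotonicity guarantee or the bound, which is why both exist.

Numerical choices: all softmaxes are computed with max-subtraction in the
log domain (utilities of order $\beta_r \cdot r$ are small here, but user
configurations can push $\beta x$ to several hundred); the goal prior's
exact zeros (start states) are floored at $10^{-16}$ inside logarithms so
that divergences stay defined for user-supplied models, while Trust-game
policies never predict those states and are unaffected; `kl_divergence()`
itself treats $0\ln(0/q)$ as 0 and signals an error on genuine support
violations; action sampling is an inverse-CDF draw over policies in
declared order from a single uniform variate, so traces replay exactly.

The state update applies the policy-value bias every sweep at the current
timepoint. An alternative would be to add the bias only at equilibrium;
with the deterministic likelihood of the Trust model both schemes converge
to the same fixed point up to the convergence tolerance, and the per-sweep
form keeps each sweep an exact coordinate descent step.

## Iterated play

`run_game()` starts from an agnostic trait prior $(0.5, 0.5)$ — people are
assumed to have no prior information about a stranger's character — and
chains rounds by `carry_over()`: the trait posterior, obtained by
marginalising the final state belief over the observable component, becomes
the next round's initial belief, and the precision posterior's
$(\alpha, \text{rate})$ becomes the next round's precision prior. The
precision carry-over is a modelling choice (toggleable via
`carry_precision = FALSE`): carrying it makes the expected precision evolve
slowly across rounds while still jumping within rounds when an outcome is
unexpectedly good, which is the behaviour the iterated simulations exhibit.
The other responds *after* observing the self's realised action
(investor-then-trustee order), since its response rule conditions on the
self's action. One root seed spawns two pre-drawn uniform substreams — one
for the self's sampled actions, one for the other's responses — so either
agent can be modified without perturbing the other's randomness.

Because the trait posterior that is carried forward comes from the full
variational agent, it is *not* pure Bayes: the precision-weighted value
bias tilts perception toward preferred outcomes. From an agnostic start
this produces an optimism bias — the start-state belief leans prosocial and
early cooperate-defect outcomes are partially "forgiven" — which fades as
the carried precision declines and accumulated evidence takes over. The
martingale property of belief updating is therefore tested on the Bayes
core (precision clamped to zero), where it holds to numerical precision by
exact enumeration of the four outcomes.

## What the simulations do and do not show

The synthetic study conditions are: the default payoff tables, the
calibrated esteem/sensitivity values above, a gamma(8, 1) precision prior,
an antisocial naive other, 32 rounds, and 100 seeds. Under them the
package's own test suite and acceptance script compute: a median final
antisocial belief above 0.9; a declining cooperation rate between game
halves; an initial policy belief favouring cooperation despite agnosticism;
and a single observed mutual defection sufficing to make the antisocial
trait the more likely one. These are properties of the model under its
default parameterisation, computed exactly as described — not measurements
of human behaviour. Real interpersonal data differ in ways the generator
does not emulate: real partners are not naive softmax responders, stakes
and fractions vary continuously, traits drift, and human choices mix in
sources of noise the model does not represent. Passing tests therefore
validate the implementation and the qualitative structure of the theory,
not its empirical adequacy.

Problem sizes used throughout the suite — 10-state game models, random
fixtures of up to 6 states for the identity and oracle checks (1,000
fixtures for the entropy/utility identity, enumeration over all state
sequences and 64-node quadrature over precision for the evidence bound),
and the 100-seed, 32-round study — were chosen so that every check runs
exactly and in minutes on a single core.

## Known limitations

* The other is memoryless and performs no inference about the self;
  two-sided mentalizing (and deeper recursion) is out of scope.
* The self's horizon is a single decision per round; multi-step policies
  are supported by the engine (`policies` may be sequences) but the Trust
  construction does not use them.
* Esteem is binary for the other and fixed for the self; inference about
  one's own esteem is not modelled.
* Model parameters are not fitted to data; the package simulates forward
  only.
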