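# Construction of the simplified two-choice Trust game: monetary returns,
# esteem-augmented utilities, the naive partner's softmax response rule, and
# the self's 10-state generative model.

ACTIONS <- c("cooperate", "defect")
TRAITS <- c("p", "n")  # prosocial / antisocial
OBS_LABELS <- c("start", "cc", "dc", "cd", "dd")  # first letter: self action

# canonical hidden-state order: observables within prosocial, then antisocial
hidden_labels_trust <- function() {
  as.vector(outer(OBS_LABELS, TRAITS, function(o, e) paste(o, e, sep = ".")))
}

action_code <- function(action) c(cooperate = "c", defect = "d")[action]

#' Outcome observation label for an action pair
#'
#' @param action_self,action_other `"cooperate"` or `"defect"`.
#' @return One of `"cc"`, `"cd"`, `"dc"`, `"dd"` (self's action first).
#' @export
outcome_label <- function(action_self, action_other) {
  action_self <- match.arg(action_self, ACTIONS)
  action_other <- match.arg(action_other, ACTIONS)
  paste0(action_code(action_self), action_code(action_other))
}

# ---- configuration types ----------------------------------------------------

#' Monetary payoff configuration for the two-choice Trust game
#'
#' The `2 x 2` return tables are indexed `[self action, other action]` with
#' action 1 = cooperate, 2 = defect. They may be supplied directly (the
#' default tables are the worked example values), or generated from a wage,
#' gain and investment/return fractions via [monetary_returns()]; when both
#' are supplied they must agree.
#'
#' @param wage Per-round wage `w` of the self in play-money units.
#' @param gain Multiplier `g` applied to the invested amount.
#' @param return_self,return_other `2 x 2` numeric return tables.
#' @param fractions Optional list with `f_self = c(cooperate =, defect =)`
#'   (self's invested fraction per action, in `(0, 1]` for cooperate) and
#'   `f_other = c(cooperate =, defect =)` (other's repaid fraction per
#'   action, `>= 0`); when given, tables are derived from them.
#' @return An object of class `payoff_config`.
#' @export
payoff_config <- function(wage = 20, gain = 3,
                          return_self = matrix(c(26, 21, 10, 18), 2, 2),
                          return_other = matrix(c(26, 7, 42, 10), 2, 2),
                          fractions = NULL) {
  stopifnot(wage > 0, gain > 0)
  check_table <- function(m, name) {
    if (!is.matrix(m) || !all(dim(m) == 2) || !all(is.finite(m))) {
      stop(sprintf("payoff_config: `%s` must be a finite 2 x 2 matrix", name))
    }
  }
  if (!is.null(fractions)) {
    fs <- fractions$f_self
    fo <- fractions$f_other
    if (length(fs) != 2 || length(fo) != 2 || any(fs < 0) || any(fs > 1) || any(fo < 0)) {
      stop("payoff_config: fractions require f_self in [0, 1] and f_other >= 0")
    }
    rs <- matrix(0, 2, 2)
    ro <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      r <- monetary_returns(wage, gain, fs[i], fo[j])
      rs[i, j] <- r[["self"]]
      ro[i, j] <- r[["other"]]
    }
    supplied <- !missing(return_self) || !missing(return_other)
    if (supplied) {
      check_table(return_self, "return_self")
      check_table(return_other, "return_other")
      if (any(abs(rs - return_self) > 1e-9) || any(abs(ro - return_other) > 1e-9)) {
        stop("payoff_config: supplied return tables disagree with the tables computed from `fractions`")
      }
    }
    return_self <- rs
    return_other <- ro
  }
  check_table(return_self, "return_self")
  check_table(return_other, "return_other")
  dimnames(return_self) <- dimnames(return_other) <- list(ACTIONS, ACTIONS)
  structure(
    list(wage = wage, gain = gain, return_self = return_self,
         return_other = return_other, fractions = fractions),
    class = "payoff_config"
  )
}

#' Esteem configuration
#'
#' Each player carries a scalar "how good one is" trait. The other's trait is
#' one of two resolvable levels, prosocial (`e_prosocial > 0`) or antisocial
#' (`e_antisocial < 0`); the self's own esteem is neutral by default. The
#' reward sensitivity `beta_r` maps monetary returns onto the utility scale
#' the esteem terms live on; when `NULL` it is set by
#' [calibrate_beta_r()] so that the partner's response probabilities stay
#' well-distributed (no entry above 0.8).
#'
#' @param e_prosocial Esteem value of trait `"p"` (> 0).
#' @param e_antisocial Esteem value of trait `"n"` (< 0).
#' @param e_self Self's own esteem (default 0, neutral).
#' @param beta_r Reward sensitivity (> 0), or `NULL` to calibrate.
#' @param payoffs [payoff_config()] used for calibration when
#'   `beta_r = NULL`.
#' @return An object of class `esteem_config`.
#' @export
esteem_config <- function(e_prosocial = 0.6, e_antisocial = -0.1, e_self = 0,
                          beta_r = NULL, payoffs = payoff_config()) {
  if (!(e_prosocial > 0 && e_antisocial < 0)) {
    stop("esteem_config: requires e_prosocial > 0 > e_antisocial")
  }
  cfg <- structure(
    list(e_prosocial = e_prosocial, e_antisocial = e_antisocial,
         e_self = e_self, beta_r = beta_r),
    class = "esteem_config"
  )
  if (is.null(beta_r)) {
    cfg$beta_r <- calibrate_beta_r(payoffs, cfg, max_prob = 0.8)
  }
  if (!(cfg$beta_r > 0)) stop("esteem_config: beta_r must be > 0")
  cfg
}

esteem_value <- function(esteem, trait) {
  trait <- match.arg(trait, TRAITS)
  if (trait == "p") esteem$e_prosocial else esteem$e_antisocial
}

#' Full configuration of one parameterized Trust game
#'
#' @param payoffs A [payoff_config()].
#' @param esteem An [esteem_config()] (calibrated against `payoffs` when its
#'   `beta_r` was left `NULL`).
#' @param precision_prior List with `shape` and `scale` of the gamma prior
#'   over policy precision.
#' @param n_rounds Number of rounds of iterated play (>= 1).
#' @param seed Root RNG seed for a game.
#' @param other_true_esteem `"p"` or `"n"`: the trait the simulated partner
#'   actually has.
#' @param carry_precision Carry the precision posterior across rounds
#'   (default) or reset to the prior each round.
#' @param tol,max_iter Variational convergence tolerance on the free energy
#'   and sweep cap, passed to [infer()].
#' @return An object of class `trust_config`.
#' @export
trust_config <- function(payoffs = payoff_config(),
                         esteem = esteem_config(payoffs = payoffs),
                         precision_prior = list(shape = 8, scale = 1),
                         n_rounds = 32, seed = 1,
                         other_true_esteem = "n",
                         carry_precision = TRUE,
                         tol = 1e-6, max_iter = 64) {
  stopifnot(inherits(payoffs, "payoff_config"), inherits(esteem, "esteem_config"))
  other_true_esteem <- match.arg(other_true_esteem, TRAITS)
  if (!is.numeric(n_rounds) || n_rounds < 1) {
    stop("trust_config: n_rounds must be >= 1")
  }
  if (!(precision_prior$shape > 0 && precision_prior$scale > 0)) {
    stop("trust_config: precision prior requires shape > 0 and scale > 0")
  }
  structure(
    list(payoffs = payoffs, esteem = esteem,
         precision_prior = precision_prior,
         n_rounds = as.integer(n_rounds), seed = as.integer(seed),
         other_true_esteem = other_true_esteem,
         carry_precision = isTRUE(carry_precision),
         tol = tol, max_iter = as.integer(max_iter)),
    class = "trust_config"
  )
}

#' @export
print.trust_config <- function(x, ...) {
  cat(sprintf("<trust_config> %d rounds, seed %d, other trait '%s'\n",
              x$n_rounds, x$seed, x$other_true_esteem))
  cat(sprintf("  wage %g, gain %g, beta_r %.6g, esteem (p = %g, n = %g, self = %g)\n",
              x$payoffs$wage, x$payoffs$gain, x$esteem$beta_r,
              x$esteem$e_prosocial, x$esteem$e_antisocial, x$esteem$e_self))
  cat(sprintf("  precision prior gamma(shape = %g, scale = %g); carry-over %s\n",
              x$precision_prior$shape, x$precision_prior$scale,
              if (x$carry_precision) "on" else "off"))
  invisible(x)
}

# ---- operations -------------------------------------------------------------

#' Monetary returns of one Trust-game round
#'
#' The self keeps the uninvested wage and receives back a fraction of the
#' invested amount; the other keeps the multiplied investment minus the
#' repayment: `r_self = w - w f_self + w f_self f_other` and
#' `r_other = w f_self g - w f_self f_other`. Their sum is
#' `w (1 + f_self (g - 1))` regardless of `f_other`.
#'
#' @param wage Wage `w` (> 0).
#' @param gain Multiplier `g` (> 0).
#' @param f_self Fraction of the wage invested, in `[0, 1]`.
#' @param f_other Fraction of the invested amount returned, `>= 0`.
#' @return Named vector `c(self =, other =)`.
#' @export
monetary_returns <- function(wage, gain, f_self, f_other) {
  if (!(wage > 0 && gain > 0)) stop("monetary_returns: wage and gain must be > 0")
  if (!is.finite(f_self) || f_self < 0 || f_self > 1) {
    stop("monetary_returns: f_self must lie in [0, 1]")
  }
  if (!is.finite(f_other) || f_other < 0) {
    stop("monetary_returns: f_other must be >= 0")
  }
  inv <- wage * f_self
  c(self = wage - inv + inv * f_other, other = inv * gain - inv * f_other)
}

#' Esteem-augmented utility of an outcome cell
#'
#' `beta_r * (monetary return)` plus the esteem term `e_self + e_other`,
#' signed by the acting player's own choice: `+` when that player's action is
#' cooperate, `-` when it is defect. Esteem thus acts as a social Pavlovian
#' bias: cooperation is intrinsically valued in good company and devalued in
#' bad company, independently of the money at stake.
#'
#' @param player `"self"` or `"other"`: whose utility.
#' @param u_self,u_other The two actions (`"cooperate"`/`"defect"`).
#' @param esteem An [esteem_config()].
#' @param payoffs A [payoff_config()].
#' @param trait `"p"` or `"n"`: the other's esteem level used in the term.
#' @return A single utility value.
#' @export
augmented_utility <- function(player, u_self, u_other, esteem, payoffs, trait) {
  player <- match.arg(player, c("self", "other"))
  i <- match(match.arg(u_self, ACTIONS), ACTIONS)
  j <- match(match.arg(u_other, ACTIONS), ACTIONS)
  e_term <- esteem$e_self + esteem_value(esteem, trait)
  if (player == "self") {
    ret <- payoffs$return_self[i, j]
    sgn <- if (i == 1) 1 else -1
  } else {
    ret <- payoffs$return_other[i, j]
    sgn <- if (j == 1) 1 else -1
  }
  esteem$beta_r * ret + sgn * e_term
}

#' The naive partner's response distribution
#'
#' The other responds to the self's realized action with a one-shot softmax
#' of its own esteem-augmented returns — no inference, no lookahead. The
#' self-esteem entering the other's utility is the self's own (believed)
#' self-esteem.
#'
#' @inheritParams augmented_utility
#' @return Named distribution `c(cooperate =, defect =)` over the other's
#'   actions.
#' @export
opponent_response <- function(u_self, esteem, payoffs, trait) {
  r <- vapply(ACTIONS, function(uo) {
    augmented_utility("other", u_self, uo, esteem, payoffs, trait)
  }, numeric(1))
  p <- softmax(r, beta = 1)
  names(p) <- ACTIONS
  p
}

# self utilities over the 10 hidden states (start states get NA)
self_state_utilities <- function(esteem, payoffs) {
  labels <- hidden_labels_trust()
  u <- rep(NA_real_, length(labels))
  names(u) <- labels
  for (trait in TRAITS) for (us in ACTIONS) for (uo in ACTIONS) {
    lab <- paste(outcome_label(us, uo), trait, sep = ".")
    u[lab] <- augmented_utility("self", us, uo, esteem, payoffs, trait)
  }
  u
}

#' Build the self's generative model of one Trust round
#'
#' Constructs the 10-hidden-state / 5-observation model: `A` projects each
#' hidden state onto its observable component; each transition page sends a
#' start state to the outcome pair selected by the self's control and the
#' other's softmax response under the corresponding trait, outcome states
#' are absorbing, and traits never change. The goal prior is the softmax
#' (sensitivity 1, since `beta_r` already scales the returns inside the
#' utilities) of the self's augmented utilities, with the two start states
#' pinned to probability 0.
#'
#' @param cfg A [trust_config()].
#' @param esteem_belief Distribution `c(p =, n =)` over the other's trait;
#'   becomes the initial belief spread over the two start states.
#' @param precision_prior Optional override of `cfg$precision_prior` (used by
#'   the iterated-play carry-over).
#' @return A validated [generative_model()] with horizon 1 and policies
#'   `{cooperate, defect}`.
#' @export
build_self_model <- function(cfg, esteem_belief = c(p = 0.5, n = 0.5),
                             precision_prior = NULL) {
  stopifnot(inherits(cfg, "trust_config"))
  check_distribution(esteem_belief, "esteem_belief")
  if (length(esteem_belief) != 2) {
    stop("build_self_model: esteem_belief must have two entries (p, n)")
  }
  labels <- hidden_labels_trust()
  ns <- length(labels)
  space <- state_space(labels, OBS_LABELS,
                       match(sub("\\..*$", "", labels), OBS_LABELS))

  A <- matrix(0, length(OBS_LABELS), ns,
              dimnames = list(OBS_LABELS, labels))
  A[cbind(space$obs_of_hidden, seq_len(ns))] <- 1

  B <- array(0, dim = c(ns, ns, 2),
             dimnames = list(labels, labels, ACTIONS))
  for (u in 1:2) {
    us <- ACTIONS[u]
    for (trait in TRAITS) {
      from <- paste("start", trait, sep = ".")
      resp <- opponent_response(us, cfg$esteem, cfg$payoffs, trait)
      for (uo in ACTIONS) {
        to <- paste(outcome_label(us, uo), trait, sep = ".")
        B[to, from, u] <- resp[[uo]]
      }
    }
    for (lab in labels) {  # outcome states are absorbing within a round
      if (!startsWith(lab, "start.")) B[lab, lab, u] <- 1
    }
  }

  utils <- self_state_utilities(cfg$esteem, cfg$payoffs)
  p_final <- ifelse(is.na(utils), 0, exp(utils - max(utils, na.rm = TRUE)))
  p_final <- p_final / sum(p_final)
  names(p_final) <- labels

  d <- stats::setNames(numeric(ns), labels)
  d["start.p"] <- esteem_belief[["p"]]
  d["start.n"] <- esteem_belief[["n"]]

  generative_model(
    space = space, A = A, B = B,
    goal = list(p_final = p_final, beta = 1, returns = utils),
    precision = if (is.null(precision_prior)) cfg$precision_prior else precision_prior,
    horizon = 1L,
    initial_belief = d,
    policies = matrix(1:2, ncol = 1),
    control_labels = ACTIONS
  )
}

#' Goal-prior preference ordering of the self
#'
#' @param cfg A [trust_config()].
#' @return Data frame with columns `state`, `probability`, `utility`, sorted
#'   by decreasing goal-prior probability (start states, pinned at 0, last).
#' @export
self_preference_ordering <- function(cfg) {
  model <- build_self_model(cfg)
  ord <- order(model$goal$p_final, decreasing = TRUE)
  data.frame(
    state = model$space$hidden[ord],
    probability = unname(model$goal$p_final[ord]),
    utility = unname(model$goal$returns[ord]),
    row.names = NULL
  )
}

#' Calibrate the reward sensitivity
#'
#' Returns the largest `beta_r` (bisection to 1e-6) such that no entry of the
#' other's response distribution exceeds `max_prob` across all four
#' (self action, trait) combinations — keeping the partner's behaviour
#' informative but stochastic. When even `beta_r = 0` exceeds the cap the
#' request is infeasible and an error is signalled; when no finite `beta_r`
#' ever exceeds it (degenerate symmetric payoffs) the search upper bound is
#' returned.
#'
#' @param payoffs A [payoff_config()].
#' @param esteem An [esteem_config()] (its `beta_r` is ignored).
#' @param max_prob Cap in `(0.5, 1)`; default 0.8.
#' @param upper Upper end of the search interval.
#' @return The calibrated `beta_r`.
#' @export
calibrate_beta_r <- function(payoffs, esteem, max_prob = 0.8, upper = 100) {
  if (!(max_prob > 0.5 && max_prob < 1)) {
    stop("calibrate_beta_r: max_prob must lie in (0.5, 1)")
  }
  probe <- esteem
  max_entry <- function(beta_r) {
    probe$beta_r <- beta_r
    max(vapply(ACTIONS, function(us) {
      max(vapply(TRAITS, function(tr) {
        max(opponent_response(us, probe, payoffs, tr))
      }, numeric(1)))
    }, numeric(1)))
  }
  if (max_entry(0) > max_prob + 1e-12) {
    stop(sprintf(
      "calibrate_beta_r: infeasible — response probability %.4f exceeds max_prob %.4f already at beta_r = 0",
      max_entry(0), max_prob))
  }
  # last feasible grid point, then bisect the bracketing interval
  grid <- seq(0, upper, length.out = 2001L)
  feas <- vapply(grid, function(b) max_entry(b) <= max_prob, logical(1))
  last <- max(which(feas))
  if (last == length(grid)) return(upper)
  lo <- grid[last]
  hi <- grid[last + 1L]
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (max_entry(mid) <= max_prob) lo <- mid else hi <- mid
  }
  lo
}
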