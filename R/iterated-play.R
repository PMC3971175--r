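# Single rounds and multi-round games: the self acts by active inference,
# the naive other responds by its one-shot softmax rule, and posteriors
# about the partner become the next round's priors.

#' The naive partner
#'
#' An opponent with a fixed true trait who responds to the self's realized
#' action with a one-shot softmax of its own esteem-augmented returns
#' ([opponent_response()]) — no inference, no memory.
#'
#' @param trait `"p"` (prosocial) or `"n"` (antisocial).
#' @param esteem_value The trait's esteem value; sign must match the trait.
#' @param beta_r Reward sensitivity of the other.
#' @param believed_self_esteem The self-esteem value the other attributes to
#'   the self (default 0, matching the self's neutral self-esteem).
#' @return An object of class `other_agent`.
#' @export
other_agent <- function(trait, esteem_value, beta_r, believed_self_esteem = 0) {
  trait <- match.arg(trait, TRAITS)
  if ((trait == "p") != (esteem_value > 0)) {
    stop("other_agent: trait and esteem_value sign must agree (p > 0 > n)")
  }
  structure(
    list(trait = trait, esteem_value = esteem_value, beta_r = beta_r,
         believed_self_esteem = believed_self_esteem),
    class = "other_agent"
  )
}

# esteem_config view of the other's utility parameters (used for its response)
other_esteem_view <- function(cfg, other) {
  es <- cfg$esteem
  es$e_self <- other$believed_self_esteem
  es$beta_r <- other$beta_r
  es
}

default_other <- function(cfg) {
  other_agent(
    trait = cfg$other_true_esteem,
    esteem_value = esteem_value(cfg$esteem, cfg$other_true_esteem),
    beta_r = cfg$esteem$beta_r
  )
}

#' Play one round of the Trust game
#'
#' Builds the self's model from the current trait prior, infers beliefs on
#' the start observation, samples the self's action from the policy belief,
#' draws the other's response from its softmax rule under its true trait,
#' then re-runs inference on the full (start, outcome) sequence and
#' marginalizes the final state belief over the observable component to get
#' the trait posterior.
#'
#' @param trait_prior Distribution `c(p =, n =)` over the other's trait.
#' @param cfg A [trust_config()].
#' @param other An [other_agent()]; defaults to the one `cfg` describes.
#' @param carry Precision carry-over from the previous round (list with
#'   `rate`), or `NULL` for the configured prior.
#' @param u_self,u_other Uniform(0, 1) draws deciding the two actions
#'   (defaults consume the current RNG stream; [run_game()] feeds two
#'   independent pre-drawn substreams).
#' @return List with `record` (one round's results), `trait_posterior`, and
#'   `carry` for the next round.
#' @export
play_round <- function(trait_prior, cfg, other = default_other(cfg),
                       carry = NULL,
                       u_self = stats::runif(1), u_other = stats::runif(1)) {
  check_distribution(trait_prior, "trait_prior")
  prior <- cfg$precision_prior
  if (!is.null(carry)) {
    prior <- list(shape = prior$shape, scale = 1 / carry$rate)
  }
  model <- build_self_model(cfg, esteem_belief = trait_prior,
                            precision_prior = prior)

  pre <- infer(model, "start", tol = cfg$tol, max_iter = cfg$max_iter)
  action_self <- sample_action(pre, u = u_self, model = model)

  resp <- opponent_response(action_self, other_esteem_view(cfg, other),
                            cfg$payoffs, other$trait)
  action_other <- ACTIONS[min(findInterval(u_other, cumsum(resp),
                                           left.open = TRUE) + 1L, 2L)]
  obs <- outcome_label(action_self, action_other)

  post <- infer(model, c("start", obs), actions = action_self,
                tol = cfg$tol, max_iter = cfg$max_iter)

  s_final <- post$s_hat[[length(post$s_hat)]]
  traits <- trait_of_labels(model$space$hidden)
  trait_posterior <- c(p = sum(s_final[traits == "p"]),
                       n = sum(s_final[traits == "n"]))
  trait_posterior <- trait_posterior / sum(trait_posterior)

  record <- list(
    action_self = action_self,
    action_other = action_other,
    observation = obs,
    trait_posterior = trait_posterior,
    policy_probs = stats::setNames(pre$u_hat, ACTIONS),
    gamma_hat = post$gamma_hat,
    gamma_hat_pre = pre$gamma_hat,
    free_energy_final = post$fe_trace[length(post$fe_trace)],
    n_vb_iterations = length(pre$fe_trace) + length(post$fe_trace)
  )
  list(record = record, trait_posterior = trait_posterior,
       carry = list(rate = post$gamma_posterior[["rate"]]))
}

#' Posterior-to-prior carry-over between rounds
#'
#' The trait posterior becomes the next round's initial belief (spread over
#' the two start states by [build_self_model()]); the precision posterior's
#' `(shape, rate)` becomes the next round's precision prior when the game is
#' configured to carry it.
#'
#' @param trait_posterior Distribution `c(p =, n =)`.
#' @param carry Precision carry (list with `rate`) or `NULL`.
#' @param cfg A [trust_config()]; with `carry_precision = FALSE` the
#'   precision carry is dropped.
#' @return List with `trait_prior` and `carry` for the next round.
#' @export
carry_over <- function(trait_posterior, carry = NULL, cfg = NULL) {
  check_distribution(trait_posterior, "trait_posterior")
  if (!is.null(cfg) && !cfg$carry_precision) carry <- NULL
  list(trait_prior = trait_posterior, carry = carry)
}

#' Run an iterated Trust game
#'
#' Plays `cfg$n_rounds` sequential [play_round()] / [carry_over()] cycles
#' from an agnostic (uniform) trait prior. One root seed spawns two
#' independent uniform substreams, one deciding the self's sampled actions
#' and one the other's responses, so the trace is bit-reproducible and
#' either agent can be toggled without perturbing the other's stream.
#'
#' @param cfg A [trust_config()].
#' @param other Optional [other_agent()] override.
#' @return An object of class `game_trace` with the config, seed and one
#'   record per round.
#' @export
run_game <- function(cfg, other = default_other(cfg)) {
  stopifnot(inherits(cfg, "trust_config"))
  n <- cfg$n_rounds
  set.seed(cfg$seed)
  u_self_stream <- stats::runif(n)
  u_other_stream <- stats::runif(n)

  trait_prior <- c(p = 0.5, n = 0.5)
  carry <- NULL
  records <- vector("list", n)
  for (k in seq_len(n)) {
    out <- play_round(trait_prior, cfg, other, carry,
                      u_self = u_self_stream[k], u_other = u_other_stream[k])
    out$record$round <- k
    records[[k]] <- out$record
    nxt <- carry_over(out$trait_posterior, out$carry, cfg)
    trait_prior <- nxt$trait_prior
    carry <- nxt$carry
  }
  structure(
    list(config = cfg, seed = cfg$seed, records = records,
         version = as.character(utils::packageVersion("aitrust"))),
    class = "game_trace"
  )
}

#' @export
print.game_trace <- function(x, ...) {
  s <- summarize_trace(x)
  cat(sprintf("<game_trace> %d rounds (seed %d, other '%s')\n",
              length(x$records), x$seed, x$config$other_true_esteem))
  cat(sprintf("  cooperation rate %.3f; final P(antisocial) %.3f\n",
              s$aggregates$cooperation_rate,
              s$rounds$p_antisocial[nrow(s$rounds)]))
  invisible(x)
}

#' Tidy summary of a game trace
#'
#' @param trace A [run_game()] trace.
#' @param confidence Trait-belief threshold for the rounds-to-confidence
#'   aggregate (default 0.9).
#' @return List with `rounds` (one tidy row per round) and `aggregates`
#'   (`cooperation_rate`, `rounds_to_confidence`: first round whose
#'   posterior on the other's true trait reaches the threshold, `NA` if
#'   never).
#' @export
summarize_trace <- function(trace, confidence = 0.9) {
  stopifnot(inherits(trace, "game_trace"))
  rec <- trace$records
  rounds <- data.frame(
    round = vapply(rec, `[[`, integer(1), "round"),
    action_self = vapply(rec, `[[`, character(1), "action_self"),
    action_other = vapply(rec, `[[`, character(1), "action_other"),
    observation = vapply(rec, `[[`, character(1), "observation"),
    p_prosocial = vapply(rec, function(r) r$trait_posterior[["p"]], numeric(1)),
    p_antisocial = vapply(rec, function(r) r$trait_posterior[["n"]], numeric(1)),
    p_cooperate = vapply(rec, function(r) r$policy_probs[["cooperate"]], numeric(1)),
    gamma_hat = vapply(rec, `[[`, numeric(1), "gamma_hat"),
    free_energy = vapply(rec, `[[`, numeric(1), "free_energy_final"),
    n_iter = vapply(rec, `[[`, integer(1), "n_vb_iterations")
  )
  true_col <- if (trace$config$other_true_esteem == "n") {
    rounds$p_antisocial
  } else {
    rounds$p_prosocial
  }
  hit <- which(true_col >= confidence)
  list(
    rounds = rounds,
    aggregates = list(
      cooperation_rate = mean(rounds$action_self == "cooperate"),
      rounds_to_confidence = if (length(hit)) hit[1] else NA_integer_,
      confidence_threshold = confidence
    )
  )
}
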