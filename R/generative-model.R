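#' aitrust: active-inference agents for the iterated Trust game
#'
#' The package is organised in layers: generic model algebra
#' ([generative_model()], [softmax()], [kl_divergence()], [policy_prior()]),
#' the Trust-game construction ([trust_config()], [build_self_model()]), the
#' variational engine ([infer()]), the iterated-play driver ([run_game()])
#' and configuration/trace I/O ([load_config()], [write_trace()]).
#'
#' @keywords internal
"_PACKAGE"

# Floor substituted for zero goal-prior entries before taking logs, so that
# KL-based policy values stay defined for user-supplied models whose
# predictions leak onto zero-probability goals. Trust-game policies never
# predict the zeroed start states, so the floor is inert there.
GOAL_FLOOR <- 1e-16

# ---- elementary probability algebra -----------------------------------------

#' Gibbs softmax over a vector of values
#'
#' Maps values \eqn{x_i} to probabilities proportional to
#' \eqn{\exp(\beta x_i)}. Computed with max-subtraction in the log domain so
#' that \eqn{|\beta x|} up to several hundred does not overflow.
#'
#' @param values Numeric vector of finite values (log-potentials, returns,
#'   utilities...).
#' @param beta Non-negative sensitivity (inverse temperature). `beta = 0`
#'   returns the uniform distribution.
#' @return Numeric vector of the same length summing to 1.
#' @examples
#' softmax(c(26, 10, 21, 18), beta = 0.1)
#' @export
softmax <- function(values, beta = 1) {
  if (!is.numeric(values) || length(values) == 0 || !all(is.finite(values))) {
    stop("softmax: `values` must be a non-empty finite numeric vector")
  }
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta < 0) {
    stop("softmax: `beta` must be a single finite value >= 0")
  }
  x <- beta * values
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

# softmax of log-potentials that may contain -Inf (impossible entries).
# All--Inf input is an error at call sites that can produce it.
softmax_log <- function(logw) {
  m <- max(logw)
  if (!is.finite(m)) return(rep(NaN, length(logw)))
  e <- exp(logw - m)
  e / sum(e)
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' \eqn{D_{KL}[p \| q] = \sum_i p_i \ln(p_i / q_i)} with the convention
#' \eqn{0 \ln(0/q) = 0}. Signals an error when `p` puts mass where `q` has
#' none (the divergence is undefined there).
#'
#' @param p,q Numeric probability vectors of equal length, each summing to 1.
#' @return A single non-negative number; 0 iff `p == q`.
#' @export
kl_divergence <- function(p, q) {
  check_distribution(p, "p")
  check_distribution(q, "q")
  if (length(p) != length(q)) stop("kl_divergence: p and q differ in length")
  pos <- p > 0
  if (any(q[pos] == 0)) {
    stop("kl_divergence: divergence undefined (p has support where q is zero)")
  }
  sum(p[pos] * (log(p[pos]) - log(q[pos])))
}

check_distribution <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || !all(is.finite(x))) {
    stop(sprintf("`%s` must be a finite numeric vector", name))
  }
  if (any(x < -1e-12) || abs(sum(x) - 1) > 1e-8) {
    stop(sprintf("`%s` must be a normalized probability vector", name))
  }
  invisible(TRUE)
}

# x * log(y) with 0 * log(0) = 0; used in entropy / free-energy sums
xlogy <- function(x, y) {
  out <- numeric(length(x))
  nz <- x > 0
  out[nz] <- x[nz] * log(y[nz])
  out
}

# ---- domain types -----------------------------------------------------------

#' State space of a discrete generative model
#'
#' Hidden states are pairs of an observable component and a latent trait
#' component; each hidden state projects deterministically onto exactly one
#' observation label.
#'
#' @param hidden Character vector of hidden-state labels (duplicate-free).
#' @param observable Character vector of observation labels (duplicate-free).
#' @param obs_of_hidden Integer vector, one entry per hidden state, giving the
#'   index of the observation that hidden state projects to.
#' @return An object of class `state_space`.
#' @export
state_space <- function(hidden, observable, obs_of_hidden) {
  stopifnot(is.character(hidden), is.character(observable))
  if (length(hidden) == 0 || length(observable) == 0) {
    stop("state_space: label lists must be non-empty")
  }
  if (anyDuplicated(hidden) || anyDuplicated(observable)) {
    stop("state_space: labels must be duplicate-free")
  }
  obs_of_hidden <- as.integer(obs_of_hidden)
  if (length(obs_of_hidden) != length(hidden) ||
      any(is.na(obs_of_hidden)) ||
      any(obs_of_hidden < 1L) || any(obs_of_hidden > length(observable))) {
    stop("state_space: obs_of_hidden must map every hidden state to one observation")
  }
  structure(
    list(hidden = hidden, observable = observable,
         obs_of_hidden = obs_of_hidden),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> %d hidden states, %d observations\n",
              length(x$hidden), length(x$observable)))
  invisible(x)
}

#' Assemble a discrete generative model
#'
#' Bundles the state space, likelihood matrix `A` (rows = observations,
#' columns = hidden states), transition array `B` (one column-stochastic page
#' per control state), the goal (outcome) prior, the gamma precision prior,
#' the planning horizon, the initial state belief and the policy set.
#'
#' @param space A [state_space()].
#' @param A Likelihood matrix, `n_obs x n_hidden`, column-stochastic.
#' @param B Transition array `n_hidden x n_hidden x n_controls`; page `u` has
#'   `P(s_{t+1} | s_t, u)` with columns indexing `s_t`.
#' @param goal List with `p_final` (distribution over hidden states at the
#'   horizon; "never-an-outcome" states carry exactly 0), `beta` (outcome
#'   sensitivity used to build `p_final`) and optionally `returns`
#'   (per-state returns/utilities `p_final` was derived from).
#' @param precision List with `shape` (\eqn{\alpha}) and `scale`
#'   (\eqn{\theta}) of the gamma prior over policy precision \eqn{\gamma};
#'   prior mean \eqn{\alpha\theta}.
#' @param horizon Number of remaining decisions (policy length).
#' @param initial_belief Distribution over hidden states at the first
#'   timepoint.
#' @param policies Integer matrix, one row per policy, `horizon` columns of
#'   control indices.
#' @param control_labels Character vector naming the control states.
#' @param validate If `TRUE` (default) abort with the full violation report
#'   when [validate_model()] finds problems.
#' @return An object of class `generative_model`.
#' @export
generative_model <- function(space, A, B, goal, precision, horizon,
                             initial_belief, policies, control_labels,
                             validate = TRUE) {
  if (is.matrix(B)) B <- array(B, dim = c(nrow(B), ncol(B), 1L))
  policies <- matrix(as.integer(policies), nrow = NROW(policies))
  model <- structure(
    list(space = space, A = A, B = B, goal = goal, precision = precision,
         horizon = as.integer(horizon), initial_belief = initial_belief,
         policies = policies, control_labels = control_labels),
    class = "generative_model"
  )
  if (validate) {
    report <- validate_model(model)
    if (length(report) > 0) {
      stop("generative_model: invalid model:\n  - ",
           paste(report, collapse = "\n  - "))
    }
  }
  model
}

#' @export
print.generative_model <- function(x, ...) {
  cat(sprintf(
    "<generative_model> %d hidden states, %d observations, %d controls, %d policies, horizon %d\n",
    length(x$space$hidden), length(x$space$observable), dim(x$B)[3],
    nrow(x$policies), x$horizon))
  cat(sprintf("  precision prior: gamma(shape = %g, scale = %g), mean %g\n",
              x$precision$shape, x$precision$scale,
              x$precision$shape * x$precision$scale))
  invisible(x)
}

#' Validate a generative model
#'
#' Reports (rather than raises) every violated invariant: column sums off by
#' more than 1e-9 in `A` or any `B` page, unnormalized goal prior or initial
#' belief, dimension mismatches, malformed precision prior and, when hidden
#' labels carry a trait component separated by `"."`, transitions that mix
#' traits.
#'
#' @param model A [generative_model()] (possibly malformed).
#' @return Character vector of violation messages; empty iff well-formed.
#' @export
validate_model <- function(model) {
  v <- character(0)
  ns <- length(model$space$hidden)
  no <- length(model$space$observable)
  tol <- 1e-9

  if (!is.matrix(model$A) || nrow(model$A) != no || ncol(model$A) != ns) {
    v <- c(v, sprintf("A must be %d x %d", no, ns))
  } else {
    if (any(model$A < -tol) || any(model$A > 1 + tol)) {
      v <- c(v, "A entries must lie in [0, 1]")
    }
    bad <- which(abs(colSums(model$A) - 1) > tol)
    for (j in bad) v <- c(v, sprintf("A column %d sums to %.6g, not 1", j, sum(model$A[, j])))
  }

  if (length(dim(model$B)) != 3 || dim(model$B)[1] != ns || dim(model$B)[2] != ns) {
    v <- c(v, sprintf("B pages must be %d x %d", ns, ns))
  } else {
    for (u in seq_len(dim(model$B)[3])) {
      page <- model$B[, , u]
      if (any(page < -tol) || any(page > 1 + tol)) {
        v <- c(v, sprintf("B page %d has entries outside [0, 1]", u))
      }
      bad <- which(abs(colSums(page) - 1) > tol)
      for (j in bad) {
        v <- c(v, sprintf("B page %d column %d sums to %.6g, not 1", u, j, sum(page[, j])))
      }
    }
    traits <- trait_of_labels(model$space$hidden)
    if (!anyNA(traits) && length(unique(traits)) > 1) {
      for (u in seq_len(dim(model$B)[3])) {
        mix <- model$B[, , u] * outer(traits, traits, "!=")
        if (any(mix != 0)) {
          v <- c(v, sprintf("B page %d contains trait-mixing transitions", u))
        }
      }
    }
  }

  g <- model$goal$p_final
  if (length(g) != ns || any(g < -tol) || abs(sum(g) - 1) > tol) {
    v <- c(v, "goal$p_final must be a normalized distribution over hidden states")
  }
  d <- model$initial_belief
  if (length(d) != ns || any(d < -tol) || abs(sum(d) - 1) > tol) {
    v <- c(v, "initial_belief must be a normalized distribution over hidden states")
  }
  pr <- model$precision
  if (!is.list(pr) || !is.numeric(pr$shape) || !is.numeric(pr$scale) ||
      pr$shape <= 0 || pr$scale <= 0) {
    v <- c(v, "precision prior requires shape > 0 and scale > 0")
  }
  if (!is.matrix(model$policies) || ncol(model$policies) != model$horizon) {
    v <- c(v, "policies must be a matrix with `horizon` columns")
  } else if (any(model$policies < 1) || any(model$policies > dim(model$B)[3])) {
    v <- c(v, "policy entries must index B pages")
  }
  v
}

# Trait component of "obs.trait" labels; NA when labels carry no trait.
trait_of_labels <- function(labels) {
  parts <- strsplit(labels, ".", fixed = TRUE)
  vapply(parts, function(p) if (length(p) == 2) p[2] else NA_character_, "")
}

# ---- model algebra ----------------------------------------------------------

#' Predicted distribution over final states under a policy
#'
#' Applies the transition pages of the policy's control sequence in order:
#' \eqn{P(s_T | s_t, \tilde u) = B(u_T) \cdots B(u_t) s_t}.
#'
#' @param model A [generative_model()].
#' @param s_now Current state distribution.
#' @param policy Integer vector of control indices, length = remaining
#'   horizon (defaults drawn from `model$policies` rows elsewhere).
#' @return Normalized distribution over hidden states at the horizon.
#' @export
predicted_final_distribution <- function(model, s_now, policy) {
  check_distribution(s_now, "s_now")
  if (length(s_now) != length(model$space$hidden)) {
    stop("predicted_final_distribution: s_now has wrong length")
  }
  policy <- as.integer(policy)
  if (any(policy < 1) || any(policy > dim(model$B)[3])) {
    stop("predicted_final_distribution: policy indexes a missing B page")
  }
  s <- s_now
  for (u in policy) s <- as.vector(model$B[, , u] %*% s)
  s / sum(s)
}

# log goal prior with the numerical floor on exact zeros
log_goal <- function(model) {
  g <- model$goal$p_final
  log(pmax(g, GOAL_FLOOR))
}

# -KL[pred || goal] per policy from distribution s_now
policy_values_from <- function(model, s_now) {
  lg <- log_goal(model)
  vapply(seq_len(nrow(model$policies)), function(i) {
    pred <- predicted_final_distribution(model, s_now, model$policies[i, ])
    sum(xlogy(pred, pred)) - sum(pred * lg)
  }, numeric(1)) * -1
}

#' Prior over policies given current beliefs and precision
#'
#' \eqn{P(\tilde u | s_t, \gamma, m) \propto
#' \exp(-\gamma D_{KL}[P(s_T|s_t,\tilde u) \| P(s_T|m)])}: policies are
#' preferred to the extent that the outcome distribution they lead to matches
#' the desired one, with confidence \eqn{\gamma}.
#'
#' @inheritParams predicted_final_distribution
#' @param gamma Non-negative precision; `gamma = 0` gives a uniform prior.
#' @return Distribution over the rows of `model$policies`.
#' @export
policy_prior <- function(model, s_now, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) || gamma < 0) {
    stop("policy_prior: `gamma` must be a single finite value >= 0")
  }
  values <- policy_values_from(model, s_now)  # -KL <= 0
  softmax_log(gamma * values)
}

#' Entropy / expected-utility decomposition of a policy's value
#'
#' The negative divergence that scores a policy splits exactly into the
#' entropy of the predicted outcome distribution plus the expected
#' log goal-prior ("utility"):
#' \eqn{-D_{KL}[P(s_T|s_t,\tilde u) \| P(s_T|m)] =
#' H[P(s_T|s_t,\tilde u)] + E_{P(s_T|s_t,\tilde u)}[\ln P(s_T|m)]}.
#'
#' @inheritParams predicted_final_distribution
#' @return List with `entropy`, `expected_utility` and their `sum`.
#' @export
value_decomposition <- function(model, s_now, policy) {
  pred <- predicted_final_distribution(model, s_now, policy)
  lg <- log_goal(model)
  entropy <- -sum(xlogy(pred, pred))
  expected_utility <- sum(pred * lg)
  list(entropy = entropy, expected_utility = expected_utility,
       sum = entropy + expected_utility)
}
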