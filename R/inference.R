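# Variational message passing: fixed-point updates of state, policy and
# precision expectations that minimize free energy, plus free-energy
# evaluation and action sampling.
#
# The engine objective (recorded in fe_trace and used for convergence) is
#
#   F0 = sum_tau s_tau' (ln s_tau - m_tau)            state terms, filtering
#      + u' ln u - gamma * u' Q s_t                   policy term
#      + a ln(b/b0) + a (b0 - b)/b                    KL of gamma posterior
#
# with m_tau the pure evidence message (ln A-row + ln B s_{tau-1}; the
# initial belief at tau = 1). The three update rules below are exact
# coordinate minimizers of F0, so the trace is non-increasing once the
# filtering pass has stabilized (after the first sweep). The exported
# free_energy() adds the policy-prior normalizer E_q[ln Z(s_t, gamma)] that
# F0 omits, making it the full term-wise expectation E_Q[ln Q - ln P] and
# hence an upper bound on surprise that is tight at an exact posterior.

#' Belief state: variational sufficient statistics
#'
#' @param model A [generative_model()].
#' @param n_time Number of timepoints (observations) the state covers.
#' @param gamma_rate Optional initial rate of the gamma precision belief
#'   (defaults to the prior rate `1/scale`).
#' @return An object of class `belief_state` with per-timepoint state
#'   expectations `s_hat`, policy expectation `u_hat`, precision expectation
#'   `gamma_hat` with its `(shape, rate)` posterior, and `fe_trace`.
#' @export
belief_state <- function(model, n_time = 1L, gamma_rate = NULL) {
  ns <- length(model$space$hidden)
  np <- nrow(model$policies)
  shape <- model$precision$shape
  rate <- if (is.null(gamma_rate)) 1 / model$precision$scale else gamma_rate
  structure(
    list(
      s_hat = replicate(n_time, rep(1 / ns, ns), simplify = FALSE),
      u_hat = rep(1 / np, np),
      gamma_hat = shape / rate,
      gamma_posterior = c(shape = shape, rate = rate),
      fe_trace = numeric(0),
      converged = NA
    ),
    class = "belief_state"
  )
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("<belief_state> %d timepoint(s); gamma_hat = %.4g; %s\n",
              length(x$s_hat), x$gamma_hat,
              if (isTRUE(x$converged)) {
                sprintf("converged in %d sweep(s)", length(x$fe_trace))
              } else "not converged"))
  invisible(x)
}

#' Policy value matrix
#'
#' `Q[i, j] = -KL[P(s_T | s_j, policy_i) || P(s_T | m)]`: the value of
#' running policy `i` from a point mass on state `j`, measured as the
#' (negative) divergence between the predicted and desired outcome
#' distributions. All entries are `<= 0`, with 0 exactly when the prediction
#' matches the goal prior.
#'
#' @param model A [generative_model()].
#' @return Matrix, rows = policies, columns = hidden states.
#' @export
compute_value_matrix <- function(model) {
  ns <- length(model$space$hidden)
  np <- nrow(model$policies)
  Q <- matrix(0, np, ns, dimnames = list(NULL, model$space$hidden))
  for (j in seq_len(ns)) {
    e_j <- numeric(ns)
    e_j[j] <- 1
    Q[, j] <- policy_values_from(model, e_j)
  }
  Q
}

obs_index <- function(model, observations) {
  if (is.character(observations)) {
    idx <- match(observations, model$space$observable)
    if (anyNA(idx)) {
      stop("unknown observation label(s): ",
           paste(observations[is.na(idx)], collapse = ", "))
    }
    idx
  } else {
    as.integer(observations)
  }
}

control_index <- function(model, actions) {
  if (length(actions) == 0) return(integer(0))
  if (is.character(actions)) {
    idx <- match(actions, model$control_labels)
    if (anyNA(idx)) stop("unknown control label(s)")
    idx
  } else {
    as.integer(actions)
  }
}

# pure evidence message for timepoint tau (no policy bias)
state_message <- function(model, o_idx, tau, s_prev, a_idx) {
  lik <- model$A[o_idx[tau], ]
  if (all(lik == 0)) {
    stop("inference failure: observation impossible under every hidden state")
  }
  prior <- if (tau == 1L) {
    model$initial_belief
  } else {
    as.vector(model$B[, , a_idx[tau - 1L]] %*% s_prev)
  }
  log(lik) + log(prior)
}

#' State update of the variational sweep
#'
#' Combines the likelihood of the current observation, the transition
#' message from the previous state under the realized action (the initial
#' belief at the first timepoint), and — at the current timepoint — the
#' precision-weighted policy value bias `gamma_hat * t(Q) %*% u_hat`, then
#' renormalizes in the log domain. The bias is what lets preferences colour
#' perception (the optimism / self-serving effect).
#'
#' @param b A [belief_state()].
#' @param observations Observation labels (or indices) up to now.
#' @param model A [generative_model()].
#' @param actions Realized controls between successive observations
#'   (`length(observations) - 1`).
#' @param Q Value matrix from [compute_value_matrix()].
#' @return `b` with all `s_hat` timepoints updated (forward pass).
#' @export
update_states <- function(b, observations, model, actions = NULL, Q) {
  o_idx <- obs_index(model, observations)
  a_idx <- control_index(model, actions)
  Tt <- length(o_idx)
  if (length(a_idx) != Tt - 1L) {
    stop("update_states: need one action per observation gap")
  }
  for (tau in seq_len(Tt)) {
    m <- state_message(model, o_idx, tau,
                       if (tau > 1L) b$s_hat[[tau - 1L]] else NULL, a_idx)
    if (tau == Tt) m <- m + b$gamma_hat * as.vector(crossprod(Q, b$u_hat))
    s <- softmax_log(m)
    if (anyNA(s)) {
      stop("inference failure: zero evidence for an observation")
    }
    b$s_hat[[tau]] <- s
  }
  b
}

#' Policy update of the variational sweep
#'
#' `u_hat <- softmax(gamma_hat * Q %*% s_t)`: policies are preferred in
#' proportion to their expected value under the current state belief,
#' sharpened by the precision expectation.
#'
#' @inheritParams update_states
#' @return `b` with `u_hat` updated.
#' @export
update_policies <- function(b, Q) {
  s_t <- b$s_hat[[length(b$s_hat)]]
  b$u_hat <- softmax_log(b$gamma_hat * as.vector(Q %*% s_t))
  b
}

#' Precision update of the variational sweep
#'
#' The gamma posterior keeps the prior shape `alpha`; its rate is the prior
#' rate minus the expected policy value, `rate = 1/theta - u' Q s_t`, so
#' `gamma_hat = alpha / rate` increases monotonically with expected value
#' (confidence that goals are attainable) and is bounded by the prior mean
#' `alpha * theta` since `Q <= 0`.
#'
#' @inheritParams update_states
#' @param prior List with `shape` and `scale` of the gamma precision prior.
#' @return `b` with `gamma_posterior` and `gamma_hat` updated.
#' @export
update_precision <- function(b, Q, prior) {
  s_t <- b$s_hat[[length(b$s_hat)]]
  value <- as.numeric(crossprod(b$u_hat, Q %*% s_t))
  rate <- 1 / prior$scale - value
  b$gamma_posterior <- c(shape = prior$shape, rate = rate)
  b$gamma_hat <- prior$shape / rate
  b
}

# engine objective F0 (see header comment)
engine_free_energy <- function(b, model, o_idx, a_idx, Q, fix_gamma = NULL) {
  Tt <- length(o_idx)
  Fs <- 0
  for (tau in seq_len(Tt)) {
    m <- state_message(model, o_idx, tau,
                       if (tau > 1L) b$s_hat[[tau - 1L]] else NULL, a_idx)
    s <- b$s_hat[[tau]]
    Fs <- Fs + sum(xlogy(s, s)) - sum(s[s > 0] * m[s > 0])
  }
  s_t <- b$s_hat[[Tt]]
  u <- b$u_hat
  Fu <- sum(xlogy(u, u)) - b$gamma_hat * as.numeric(crossprod(u, Q %*% s_t))
  Fg <- 0
  if (is.null(fix_gamma)) {
    a <- model$precision$shape
    b0 <- 1 / model$precision$scale
    rate <- b$gamma_posterior[["rate"]]
    Fg <- a * log(rate / b0) + a * (b0 - rate) / rate
  }
  Fs + Fu + Fg
}

#' Variational inference over a sequence of observations
#'
#' Cycles state, policy and precision updates until the free-energy change
#' per sweep falls below `tol` or `max_iter` sweeps are reached. The result
#' is deterministic given its inputs; only [sample_action()] consumes
#' randomness.
#'
#' @param model A [generative_model()].
#' @param observations Observation labels (or indices), in time order.
#' @param actions Realized controls between successive observations; needed
#'   whenever more than one observation is supplied.
#' @param init Optional [belief_state()] to start from (e.g. carrying a
#'   precision posterior); defaults to uniform beliefs and the prior-mean
#'   precision.
#' @param tol Convergence tolerance on the free energy (default 1e-6).
#' @param max_iter Sweep cap (default 64); hitting it returns the best
#'   iterate flagged `converged = FALSE`.
#' @param fix_gamma Optional fixed precision value; clamps `gamma_hat`,
#'   skips the precision update and drops its free-energy term.
#'   `fix_gamma = 0` reduces the engine to exact Bayesian filtering with a
#'   uniform policy belief.
#' @return A converged [belief_state()] with its `fe_trace`.
#' @export
infer <- function(model, observations, actions = NULL, init = NULL,
                  tol = 1e-6, max_iter = 64, fix_gamma = NULL) {
  o_idx <- obs_index(model, observations)
  a_idx <- control_index(model, actions)
  Tt <- length(o_idx)
  if (length(a_idx) != Tt - 1L) {
    stop("infer: need one action per observation gap")
  }
  Q <- compute_value_matrix(model)
  b <- if (is.null(init)) belief_state(model, n_time = Tt) else init
  if (length(b$s_hat) != Tt) {
    b$s_hat <- replicate(Tt, rep(1 / length(model$space$hidden),
                                 length(model$space$hidden)),
                         simplify = FALSE)
  }
  if (!is.null(fix_gamma)) {
    b$gamma_hat <- fix_gamma
    b$gamma_posterior <- c(shape = NA_real_, rate = NA_real_)
  }
  b$fe_trace <- numeric(0)
  f_prev <- Inf
  b$converged <- FALSE
  for (iter in seq_len(max_iter)) {
    b <- update_states(b, o_idx, model, a_idx, Q)
    b <- update_policies(b, Q)
    if (is.null(fix_gamma)) b <- update_precision(b, Q, model$precision)
    f <- engine_free_energy(b, model, o_idx, a_idx, Q, fix_gamma)
    b$fe_trace <- c(b$fe_trace, f)
    if (is.finite(f_prev) && abs(f_prev - f) < tol) {
      b$converged <- TRUE
      break
    }
    f_prev <- f
  }
  b
}

#' Full variational free energy of a belief state
#'
#' The term-wise expectation `E_Q[ln Q - ln P(obs, states, policies,
#' precision | m)]` under the factorized posterior: the engine objective
#' plus the policy-prior normalizer `E_q[ln Z(s_t, gamma)]`, with the
#' expectation over the gamma belief taken by generalized Gauss-Laguerre
#' quadrature (exact at a fixed `gamma`). Upper-bounds `-ln P(obs | m)` and
#' is tight when the supplied beliefs are an exact factorizable posterior.
#'
#' @inheritParams infer
#' @param b A [belief_state()].
#' @param n_quad Number of quadrature nodes for the gamma expectation.
#' @param normalizer If `FALSE`, drop the normalizer term and return the
#'   engine objective itself — the quantity [infer()] minimizes, whose trace
#'   is non-increasing and whose converged beliefs are coordinate-wise
#'   optimal.
#' @return A single finite value.
#' @export
free_energy <- function(b, observations, model, actions = NULL,
                        fix_gamma = NULL, n_quad = 64, normalizer = TRUE) {
  o_idx <- obs_index(model, observations)
  a_idx <- control_index(model, actions)
  Q <- compute_value_matrix(model)
  if (!is.null(fix_gamma)) b$gamma_hat <- fix_gamma
  f0 <- engine_free_energy(b, model, o_idx, a_idx, Q, fix_gamma)
  if (!normalizer) return(f0)
  s_t <- b$s_hat[[length(b$s_hat)]]
  lnz_s <- function(gamma) {  # ln Z(s_j, gamma) for every state j
    apply(gamma * Q, 2, function(col) {
      m <- max(col)
      m + log(sum(exp(col - m)))
    })
  }
  if (!is.null(fix_gamma)) {
    e_lnz <- sum(s_t * lnz_s(fix_gamma))
  } else {
    shape <- b$gamma_posterior[["shape"]]
    rate <- b$gamma_posterior[["rate"]]
    gq <- pracma::gaussLaguerre(n_quad, shape - 1)
    w <- gq$w / gamma(shape)
    nodes <- gq$x / rate
    e_lnz <- sum(w * vapply(nodes, function(g) sum(s_t * lnz_s(g)), numeric(1)))
  }
  f0 + e_lnz
}

#' Sample an action from the policy belief
#'
#' Inverse-CDF draw over policies in their declared order using a single
#' uniform variate; returns the sampled policy's first control.
#'
#' @param b A [belief_state()].
#' @param u A uniform(0, 1) draw; defaults to consuming one from the current
#'   RNG stream.
#' @param model Optional [generative_model()]; when given, the control label
#'   is returned instead of its index.
#' @return Control index (or label) of the first step of the sampled policy.
#' @export
sample_action <- function(b, u = stats::runif(1), model = NULL) {
  p <- b$u_hat
  idx <- findInterval(u, cumsum(p), left.open = TRUE) + 1L
  idx <- min(idx, length(p))
  ctrl <- if (is.null(model)) idx else model$policies[idx, 1L]
  if (!is.null(model)) model$control_labels[ctrl] else idx
}
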