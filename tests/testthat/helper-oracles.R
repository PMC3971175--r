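# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct summation, and
# textbook recursions.

default_cfg <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- trust_config()
    cfg
  }
})

# direct-summation KL (no error handling; assumes valid support)
kl_direct <- function(p, q) {
  i <- p > 0
  sum(p[i] * log(p[i] / q[i]))
}

# predicted final distribution by explicit enumeration over intermediate
# state paths (sum over all state sequences), not matrix products
final_dist_by_enumeration <- function(model, s_now, policy) {
  ns <- length(model$space$hidden)
  steps <- length(policy)
  paths <- as.matrix(expand.grid(rep(list(seq_len(ns)), steps + 1)))
  out <- numeric(ns)
  for (r in seq_len(nrow(paths))) {
    pth <- paths[r, ]
    w <- s_now[pth[1]]
    for (k in seq_len(steps)) {
      w <- w * model$B[pth[k + 1], pth[k], policy[k]]
    }
    out[pth[steps + 1]] <- out[pth[steps + 1]] + w
  }
  out / sum(out)
}

# exact forward Bayesian filtering for an HMM slice of the model
bayes_filter_oracle <- function(model, observations, actions = NULL) {
  o <- if (is.character(observations)) {
    match(observations, model$space$observable)
  } else observations
  a <- if (is.character(actions)) {
    match(actions, model$control_labels)
  } else as.integer(actions)
  s <- model$initial_belief * model$A[o[1], ]
  s <- s / sum(s)
  posts <- list(s)
  for (tau in seq_along(o)[-1]) {
    pred <- as.vector(model$B[, , a[tau - 1]] %*% s)
    s <- pred * model$A[o[tau], ]
    s <- s / sum(s)
    posts[[tau]] <- s
  }
  posts
}

# -ln P(observations | model): exhaustive enumeration over state sequences
# and policies, generalized Gauss-Laguerre quadrature over the gamma prior.
# The policy prior P(u | s_t, gamma) is evaluated at the sequence's final
# state, mirroring the generative factorization.
neg_log_evidence_oracle <- function(model, observations, actions = NULL,
                                    fix_gamma = NULL, n_quad = 64) {
  o <- if (is.character(observations)) {
    match(observations, model$space$observable)
  } else observations
  a <- if (is.character(actions)) {
    match(actions, model$control_labels)
  } else as.integer(actions)
  ns <- length(model$space$hidden)
  np <- nrow(model$policies)
  Tt <- length(o)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(ns)), Tt)))
  # Q values recomputed here by direct composition + direct KL
  lg <- log(pmax(model$goal$p_final, 1e-16))
  Qm <- matrix(0, np, ns)
  for (j in seq_len(ns)) {
    e <- numeric(ns); e[j] <- 1
    for (i in seq_len(np)) {
      pred <- e
      for (u in model$policies[i, ]) pred <- as.vector(model$B[, , u] %*% pred)
      pos <- pred > 0
      Qm[i, j] <- -(sum(pred[pos] * log(pred[pos])) - sum(pred * lg))
    }
  }
  ev_given_gamma <- function(gamma) {
    total <- 0
    for (r in seq_len(nrow(seqs))) {
      st <- seqs[r, ]
      w <- model$initial_belief[st[1]] * model$A[o[1], st[1]]
      if (Tt > 1) {
        for (tau in 2:Tt) {
          w <- w * model$B[st[tau], st[tau - 1], a[tau - 1]] *
            model$A[o[tau], st[tau]]
        }
      }
      if (w == 0) next
      pu <- exp(gamma * Qm[, st[Tt]])
      pu <- pu / sum(pu)
      total <- total + w * sum(pu)  # sums policies out (= w)
    }
    total
  }
  if (!is.null(fix_gamma)) return(-log(ev_given_gamma(fix_gamma)))
  shape <- model$precision$shape
  rate <- 1 / model$precision$scale
  gq <- pracma::gaussLaguerre(n_quad, shape - 1)
  w <- gq$w / gamma(shape)
  ev <- sum(w * vapply(gq$x / rate, ev_given_gamma, numeric(1)))
  -log(ev)
}
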