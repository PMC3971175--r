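test_that("the value matrix is the per-state policy divergence", {
  # hand-computed 2-state model
  m <- generate_fixture(n_states = 2, n_observations = 2, n_controls = 2,
                        horizon = 1, seed = 21)
  m$goal$p_final <- c(0.75, 0.25)
  Q <- compute_value_matrix(m)
  for (i in 1:2) for (j in 1:2) {
    pred <- as.vector(m$B[, , i] %*% c(j == 1, j == 2))
    expect_equal(unname(Q[i, j]), -kl_direct(pred, m$goal$p_final),
                 tolerance = 1e-12)
  }
  expect_true(all(Q <= 1e-12))

  # a model whose predictions always equal the goal prior has Q = 0
  mg <- m
  mg$B[, , 1] <- matrix(mg$goal$p_final, 2, 2)
  mg$B[, , 2] <- matrix(mg$goal$p_final, 2, 2)
  expect_equal(compute_value_matrix(mg), matrix(0, 2, 2),
               ignore_attr = TRUE, tolerance = 1e-12)

  # Trust model: outcome-state columns are finite and non-positive
  Qt <- compute_value_matrix(build_self_model(default_cfg()))
  expect_true(all(is.finite(Qt)))
  expect_true(all(Qt <= 0))
})

test_that("policy update follows the precision-weighted expected value", {
  m <- build_self_model(default_cfg())
  Q <- compute_value_matrix(m)
  b <- belief_state(m)

  # zero values: uniform policies
  b0 <- b
  b0$s_hat <- list(m$initial_belief)
  bq <- update_policies(b0, matrix(0, 2, 10))
  expect_equal(bq$u_hat, c(0.5, 0.5))

  # expected values 0 and -ln 2 at gamma 1: (2/3, 1/3)
  b1 <- b
  b1$gamma_hat <- 1
  b1$s_hat <- list(c(1, rep(0, 9)))
  Q2 <- rbind(rep(0, 10), rep(-log(2), 10))
  expect_equal(update_policies(b1, Q2)$u_hat, c(2 / 3, 1 / 3),
               tolerance = 1e-12)
})

test_that("precision recovers the prior mean at zero value and the closed form otherwise", {
  m <- build_self_model(default_cfg())  # gamma prior shape 8, scale 1
  b <- belief_state(m)
  b$s_hat <- list(m$initial_belief)

  bz <- update_precision(b, matrix(0, 2, 10), m$precision)
  expect_equal(bz$gamma_hat, 8)

  # u'Qs = -1 with shape 8, scale 1: gamma_hat = 8 / (1 + 1) = 4
  bm <- update_precision(b, matrix(-1, 2, 10), m$precision)
  expect_equal(bm$gamma_hat, 4)

  # monotonicity: raising any Q entry never decreases gamma_hat
  set.seed(31)
  for (i in 1:25) {
    Q <- -matrix(rexp(20), 2, 10)
    b$u_hat <- softmax(rnorm(2), 1)
    s <- softmax(rnorm(10), 1)
    b$s_hat <- list(s)
    g0 <- update_precision(b, Q, m$precision)$gamma_hat
    k <- sample(20, 1)
    Q2 <- Q
    Q2[k] <- Q2[k] + runif(1, 0, 2)
    g1 <- update_precision(b, Q2, m$precision)$gamma_hat
    expect_gte(g1, g0 - 1e-12)
    expect_gt(g0, 0)
    expect_lte(g0, 8 + 1e-12)  # bounded by the prior mean since Q <= 0
  }
})

test_that("inference leaves beliefs normalized and the trace non-increasing", {
  cfg <- default_cfg()
  m <- build_self_model(cfg)
  for (obs in list("start", c("start", "dd"), c("start", "cc"))) {
    # the taken action must match the outcome's self component
    acts <- if (length(obs) == 2) {
      if (startsWith(obs[2], "c")) "cooperate" else "defect"
    }
    b <- infer(m, obs, actions = acts)
    expect_true(b$converged)
    for (s in b$s_hat) {
      expect_equal(sum(s), 1, tolerance = 1e-9)
      expect_true(all(s >= 0))
    }
    expect_equal(sum(b$u_hat), 1, tolerance = 1e-9)
    expect_true(all(diff(b$fe_trace) <= 1e-8))
  }
  # random fixtures too
  for (seed in 1:10) {
    f <- generate_fixture(n_states = 5, n_observations = 4, n_controls = 2,
                          horizon = 2, seed = seed)
    set.seed(seed)
    obs <- sample(4, 3, replace = TRUE)
    acts <- sample(2, 2, replace = TRUE)
    b <- infer(f, obs, actions = acts)
    expect_true(all(diff(b$fe_trace) <= 1e-8))
    for (s in b$s_hat) expect_equal(sum(s), 1, tolerance = 1e-9)
  }
})

test_that("inference is deterministic and only action sampling uses the RNG", {
  m <- build_self_model(default_cfg())
  b1 <- infer(m, c("start", "cd"), actions = "cooperate")
  b2 <- infer(m, c("start", "cd"), actions = "cooperate")
  expect_identical(b1, b2)
})

test_that("an uninformative observation returns the prior beliefs", {
  f <- generate_fixture(n_states = 4, n_observations = 2, n_controls = 1,
                        horizon = 1, seed = 41)
  f$A <- matrix(0.5, 2, 4)             # observations carry no information
  f$B[, , 1] <- matrix(f$goal$p_final, 4, 4)  # every value is 0: no bias
  b <- infer(f, 1)
  expect_equal(b$s_hat[[1]], f$initial_belief, tolerance = 1e-9)
  expect_equal(b$u_hat, 1)

  # with nonzero policy values the posterior equals the prior only once the
  # precision weight is clamped off
  g <- generate_fixture(n_states = 4, n_observations = 2, n_controls = 2,
                        horizon = 1, seed = 42)
  g$A <- matrix(0.5, 2, 4)
  b0 <- infer(g, 1, fix_gamma = 0)
  expect_equal(b0$s_hat[[1]], g$initial_belief, tolerance = 1e-9)
})

test_that("with gamma clamped to 0 inference is exact Bayesian filtering", {
  cfg <- default_cfg()
  m <- build_self_model(cfg)
  b <- infer(m, c("start", "dd"), actions = "defect", fix_gamma = 0)
  oracle <- bayes_filter_oracle(m, c("start", "dd"), "defect")
  expect_equal(unname(b$s_hat[[1]]), unname(oracle[[1]]), tolerance = 1e-9)
  expect_equal(unname(b$s_hat[[2]]), unname(oracle[[2]]), tolerance = 1e-9)
  expect_equal(b$u_hat, c(0.5, 0.5))

  for (seed in 1:8) {
    f <- generate_fixture(n_states = 5, n_observations = 3, n_controls = 2,
                          horizon = 1, seed = seed + 100)
    set.seed(seed)
    obs <- sample(3, 3, replace = TRUE)
    acts <- sample(2, 2, replace = TRUE)
    b <- infer(f, obs, actions = acts, fix_gamma = 0)
    oracle <- bayes_filter_oracle(f, obs, acts)
    for (tau in 1:3) {
      expect_equal(b$s_hat[[tau]], unname(oracle[[tau]]), tolerance = 1e-8)
    }
  }
})

test_that("impossible observations are rejected", {
  f <- generate_fixture(n_states = 3, n_observations = 3, n_controls = 1,
                        horizon = 1, seed = 51)
  f$A[2, ] <- 0
  f$A <- sweep(f$A, 2, colSums(f$A), "/")
  expect_error(infer(f, 2), "impossible")
  expect_error(infer(f, "o9"), "unknown observation")
})

test_that("free energy is tight at an exact factorizable posterior", {
  # single policy, fixed gamma, one observation: the exact posterior
  # factorizes, and F evaluated at it must equal -ln P(o | m)
  for (seed in 1:10) {
    f <- generate_fixture(n_states = 4, n_observations = 3, n_controls = 1,
                          horizon = 1, seed = seed + 200)
    o <- (seed %% 3) + 1
    b <- belief_state(f)
    post <- f$A[o, ] * f$initial_belief
    b$s_hat <- list(post / sum(post))  # exact posterior, supplied by hand
    b$u_hat <- 1
    fe <- free_energy(b, o, f, fix_gamma = 2)
    exact <- -log(sum(f$A[o, ] * f$initial_belief))
    expect_equal(fe, exact, tolerance = 1e-8)
    expect_equal(exact, neg_log_evidence_oracle(f, o, fix_gamma = 2),
                 tolerance = 1e-10)
  }
})

test_that("free energy upper-bounds the enumerated model evidence", {
  for (seed in 1:12) {
    f <- generate_fixture(n_states = 4, n_observations = 3, n_controls = 2,
                          horizon = 1, seed = seed + 300)
    set.seed(seed)
    obs <- sample(3, 2, replace = TRUE)
    act <- sample(2, 1)
    b <- infer(f, obs, actions = act, tol = 1e-10)
    fe <- free_energy(b, obs, f, actions = act)
    bound <- neg_log_evidence_oracle(f, obs, actions = act)
    expect_gte(fe, bound - 1e-8)
  }
})

test_that("perturbing converged beliefs increases the minimized free energy", {
  # converged beliefs are coordinate-wise optima of the engine objective:
  # perturbing any single belief factor away from them raises it
  f <- generate_fixture(n_states = 5, n_observations = 4, n_controls = 2,
                        horizon = 1, seed = 61)
  b <- infer(f, c(1, 3), actions = 1, tol = 1e-12)
  fe0 <- free_energy(b, c(1, 3), f, actions = 1, normalizer = FALSE)
  set.seed(62)
  for (i in 1:10) {
    bs <- b
    last <- length(bs$s_hat)
    bs$s_hat[[last]] <- softmax(log(bs$s_hat[[last]]) + rnorm(5, sd = 0.3), 1)
    expect_gt(free_energy(bs, c(1, 3), f, actions = 1, normalizer = FALSE), fe0)
    bu <- b
    bu$u_hat <- softmax(log(bu$u_hat) + rnorm(2, sd = 0.5), 1)
    expect_gt(free_energy(bu, c(1, 3), f, actions = 1, normalizer = FALSE), fe0)
    bg <- b
    bg$gamma_posterior[["rate"]] <- bg$gamma_posterior[["rate"]] * runif(1, 1.1, 2)
    bg$gamma_hat <- bg$gamma_posterior[["shape"]] / bg$gamma_posterior[["rate"]]
    expect_gt(free_energy(bg, c(1, 3), f, actions = 1, normalizer = FALSE), fe0)
  }
})

test_that("action sampling is an inverse-CDF draw over policies", {
  m <- build_self_model(default_cfg())
  b <- belief_state(m)

  b$u_hat <- c(1, 0)
  for (u in c(0.001, 0.5, 0.999)) {
    expect_equal(sample_action(b, u = u, model = m), "cooperate")
  }

  b$u_hat <- c(0.7, 0.3)
  expect_equal(sample_action(b, u = 0.69, model = m), "cooperate")
  expect_equal(sample_action(b, u = 0.71, model = m), "defect")

  # frequency check: 10,000 draws against the stated probabilities
  set.seed(71)
  draws <- vapply(runif(10000), function(u) sample_action(b, u = u),
                  integer(1))
  tab <- tabulate(draws, 2)
  expect_gt(stats::chisq.test(tab, p = c(0.7, 0.3))$p.value, 0.001)

  b$u_hat <- c(0.5, 0.5)
  draws <- vapply(runif(10000), function(u) sample_action(b, u = u),
                  integer(1))
  expect_lt(abs(mean(draws == 1) - 0.5), 3 * sqrt(0.25 / 10000))
})
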