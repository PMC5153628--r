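test_that("sigmoid is exact at anchors and saturates without overflow", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1), exp(1) / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(sigmoid(1), 0.7310585786, tolerance = 1e-9)
  expect_true(sigmoid(1000) < 1 && is.finite(sigmoid(1000)))
  expect_true(sigmoid(-1000) > 0 && is.finite(sigmoid(-1000)))
  # matrix input, predict path
  inst <- random_instance(3, 4, 2, seed = 1)
  P <- predict_interactions(inst$model)
  expect_true(all(P > 0 & P < 1))
})

test_that("loss has its closed form at zero factors", {
  m <- 3; n <- 4
  cfg <- cosine_config(rank = 2, lambda_f = 0, lambda_g = 0,
                       lambda_m = 0, lambda_n = 0)
  model <- cosine:::new_factor_model(matrix(0, m, 2), matrix(0, n, 2), cfg)
  R <- matrix(rbinom(m * n, 1, 0.5), m)
  val <- cosine_loss(model, R, matrix(1, m, n), matrix(0, m, n),
                     diag(m), diag(n))
  expect_equal(val, m * n * log(2), tolerance = 1e-12)
})

test_that("loss matches the scalar-loop oracle in both modes", {
  for (seed in 1:5) for (mode in c("logistic", "linear")) {
    inst <- random_instance(4, 5, 2, seed = seed, mode = mode)
    expected <- loop_loss(inst$model$F, inst$model$G, inst$R, inst$W,
                          inst$Q, inst$M, inst$N, mode = mode,
                          lambda_f = inst$cfg$lambda_f,
                          lambda_g = inst$cfg$lambda_g,
                          lambda_m = inst$cfg$lambda_m,
                          lambda_n = inst$cfg$lambda_n)
    got <- cosine_loss(inst$model, inst$R, inst$W, inst$Q, inst$M, inst$N)
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("linear loss is zero for a perfect rank-1 factorization", {
  u <- c(1, 0, 1); v <- c(0, 1, 1, 0)
  R <- outer(u, v)
  cfg <- cosine_config(rank = 1, mode = "linear", lambda_f = 0,
                       lambda_g = 0, lambda_m = 0, lambda_n = 0)
  model <- cosine:::new_factor_model(matrix(u), matrix(v), cfg)
  expect_equal(cosine_loss(model, R, matrix(1, 3, 4), matrix(0, 3, 4),
                           diag(3), diag(4)), 0)
  # and at zero factors it counts the unit targets
  model0 <- cosine:::new_factor_model(matrix(0, 3, 1), matrix(0, 4, 1), cfg)
  expect_equal(cosine_loss(model0, R, matrix(1, 3, 4), matrix(0, 3, 4),
                           diag(3), diag(4)), sum(R == 1))
})

test_that("homophily penalty: hand case, identity case, oracle, invariances", {
  L <- rbind(c(0, 0), c(1, 0))
  S <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(homophily_penalty(L, S), 1)
  expect_equal(homophily_penalty(L, diag(2)), 0)

  set.seed(9)
  L6 <- matrix(rnorm(18), 6, 3)
  S6 <- random_similarity(6)
  expect_equal(homophily_penalty(L6, S6), loop_homophily(L6, S6),
               tolerance = 1e-10)
  # rows identical within the graph => zero
  Lc <- matrix(rep(rnorm(3), each = 6), 6, 3)
  expect_equal(homophily_penalty(Lc, S6), 0, tolerance = 1e-12)
  # translation invariance: adding the same vector to all rows
  shift <- matrix(rep(rnorm(3), each = 6), 6, 3)
  expect_equal(homophily_penalty(L6 + shift, S6),
               homophily_penalty(L6, S6), tolerance = 1e-9)
  expect_error(homophily_penalty(L6, matrix(runif(36), 6)), "symmetric")
})

test_that("zero homophily contribution when all target rows coincide", {
  inst <- random_instance(4, 5, 2, seed = 3)
  inst$model$F <- matrix(rep(c(1, -2), each = 4), 4, 2)
  parts <- cosine_loss(inst$model, inst$R, inst$W, inst$Q, inst$M, inst$N,
                       parts = TRUE)
  expect_equal(unname(parts["homophily_m"]), 0, tolerance = 1e-12)
})

test_that("loss decomposes additively with nonnegative penalty parts", {
  for (seed in 1:3) {
    inst <- random_instance(5, 6, 2, seed = seed)
    parts <- cosine_loss(inst$model, inst$R, inst$W, inst$Q, inst$M, inst$N,
                         parts = TRUE)
    total <- cosine_loss(inst$model, inst$R, inst$W, inst$Q, inst$M, inst$N)
    expect_equal(sum(parts), total, tolerance = 1e-12)
    expect_true(all(parts[c("ridge_f", "ridge_g",
                            "homophily_m", "homophily_n")] >= 0))
  }
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:4) for (mode in c("logistic", "linear")) {
    inst <- random_instance(5, 4, 2, seed = seed, mode = mode)
    gr <- cosine_gradients(inst$model, inst$R, inst$W, inst$Q,
                           inst$M, inst$N)
    fdF <- fd_gradient(inst$model, inst$R, inst$W, inst$Q, inst$M, inst$N, "F")
    fdG <- fd_gradient(inst$model, inst$R, inst$W, inst$Q, inst$M, inst$N, "G")
    expect_lt(max(abs(gr$dF - fdF) / pmax(abs(fdF), 1)), 1e-5)
    expect_lt(max(abs(gr$dG - fdG) / pmax(abs(fdG), 1)), 1e-5)
  }
})

test_that("gradients vanish when no term is active", {
  inst <- random_instance(4, 4, 2, seed = 5,
                          lambdas = c(0, 0, 0, 0))
  gr <- cosine_gradients(inst$model, inst$R, inst$R * 0, inst$Q * 0,
                         inst$M, inst$N)
  expect_equal(gr$dF, inst$model$F * 0)
  expect_equal(gr$dG, inst$model$G * 0)
})

test_that("shape mismatches are rejected", {
  inst <- random_instance(4, 5, 2, seed = 6)
  expect_error(cosine_loss(inst$model, inst$R[, 1:3], inst$W, inst$Q,
                           inst$M, inst$N), "shape")
  expect_error(cosine_gradients(inst$model, inst$R, inst$W[1:2, ], inst$Q,
                                inst$M, inst$N), "shape")
})

test_that("logistic loss is the negative log posterior up to a constant", {
  # 2x2 instance: recompute from the likelihood product
  # p(t | f, g) = prod_ij p_ij^(w t) (1 - p_ij)^(w (1 - t)) and Gaussian
  # priors with precision lambda
  set.seed(12)
  cfg <- cosine_config(rank = 2, lambda_f = 0.4, lambda_g = 0.7,
                       lambda_m = 0, lambda_n = 0)
  F <- matrix(rnorm(4), 2); G <- matrix(rnorm(4), 2)
  model <- cosine:::new_factor_model(F, G, cfg)
  R <- matrix(c(1, 0, 0, 1), 2)
  W <- matrix(c(6, 1, 2, 6), 2)
  Q <- matrix(c(0, 0.3, 0.2, 0), 2)
  loglik <- 0
  for (i in 1:2) for (j in 1:2) {
    p <- 1 / (1 + exp(-sum(F[i, ] * G[j, ])))
    t_eff <- R[i, j] + Q[i, j]
    loglik <- loglik + W[i, j] * (t_eff * log(p) + (1 - t_eff) * log(1 - p))
  }
  log_prior <- -cfg$lambda_f / 2 * sum(F^2) - cfg$lambda_g / 2 * sum(G^2)
  expect_equal(cosine_loss(model, R, W, Q, diag(2), diag(2)),
               -(loglik + log_prior), tolerance = 1e-10)
})
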