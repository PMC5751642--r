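# Network forward pass, analytic Jacobian, Levenberg-Marquardt stepping and
# the Bayesian-regularization (evidence framework) training loop

test_that("sigmoid is correct, saturating and numerically stable", {
  expect_equal(sigmoid(0), 0.5)
  expect_gte(sigmoid(40), 1 - 1e-17)
  x <- seq(-30, 30, by = 0.7)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_true(all(is.finite(sigmoid(c(-1e3, 1e3)))))
})

test_that("forward pass matches hand evaluation", {
  m <- brnn_model(3, 2, seed = 1)
  m <- set_params(m, rep(0, n_params(m)))
  m$output_bias <- 4.2
  expect_equal(forward(m, matrix(rnorm(15), 5)), rep(4.2, 5))

  # H = 1, zero input weights: y = b0 + w1 * sigmoid(b1)
  m1 <- brnn_model(4, 1)
  m1$input_weights[] <- 0
  m1$hidden_biases <- 0
  m1$output_weights <- 2
  m1$output_bias <- 1
  expect_equal(forward(m1, matrix(rnorm(12), 3)), rep(2, 3))
  expect_error(forward(m1, matrix(1, 1, 3)), "inputs")
  # linear output layer is unbounded
  m1$output_bias <- 50
  expect_gt(abs(forward(m1, matrix(0, 1, 4))), 1)
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(1)
  for (cfg in list(c(24, 10), c(5, 3), c(2, 7))) {
    m <- brnn_model(cfg[1], cfg[2], seed = cfg[1] + cfg[2])
    X <- matrix(stats::rnorm(6 * cfg[1]), 6)
    J <- jacobian(m, X)
    Jfd <- fd_jacobian(m, X)
    expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-5)
  }
  # bias column is all ones (derivative of the prediction w.r.t. b0)
  m <- brnn_model(4, 3, seed = 2)
  J <- jacobian(m, matrix(rnorm(20), 5))
  expect_equal(J[, n_params(m)], rep(1, 5))
  # zero input weights: hidden-bias columns reflect w_j * sigmoid'(b_j)
  m$input_weights[] <- 0
  J0 <- jacobian(m, matrix(rnorm(8), 2))
  z <- sigmoid(m$hidden_biases)
  expect_equal(J0[1, 13:15], m$output_weights * z * (1 - z))
})

test_that("one LM step on a linear harness reaches the OLS optimum", {
  set.seed(2)
  X <- cbind(1, matrix(rnorm(30 * 3), 30))
  y <- drop(X %*% c(1, 2, -1, 0.5)) + rnorm(30, 0, 0.1)
  for (start in list(rep(0, 4), c(5, -5, 3, 3))) {
    st <- training_state(4, alpha = 0, beta = 1, lambda = 1e-10)
    res <- lm_step(linear_harness(start), X, y, st, objective = "sse")
    expect_true(res$accepted)
    ols <- drop(solve(crossprod(X), crossprod(X, y)))
    expect_lt(max(abs(get_params(res$model) - ols)), 1e-8)
  }
})

test_that("large damping turns the LM step into a gradient step", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20)
  start <- c(0.3, -0.2)
  st <- training_state(2, alpha = 0, beta = 1, lambda = 1e12)
  res <- lm_step(linear_harness(start), X, y, st, objective = "sse",
                 lambda_max = 1e13)
  h <- get_params(res$model) - start
  g <- drop(crossprod(X, y - drop(X %*% start)))
  angle <- acos(sum(h * g) / sqrt(sum(h^2) * sum(g^2)))
  expect_lt(angle, 1e-3)
})

test_that("accepted LM steps decrease the objective; rejected ones raise lambda", {
  set.seed(4)
  m <- brnn_model(3, 4, seed = 9)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  st <- training_state(n_params(m))
  r0 <- y - forward(m, X)
  F0 <- st$beta * sum(r0^2) + st$alpha * sum(get_params(m)^2)
  res <- lm_step(m, X, y, st, objective = "regularized")
  expect_true(res$accepted)
  expect_lt(res$state$F, F0)
})

test_that("hyperparameter updates obey the evidence-framework contracts", {
  m <- brnn_model(2, 3, seed = 5)
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20)
  st <- training_state(n_params(m), alpha = 0, beta = 1)
  res <- lm_step(m, X, y, st, objective = "regularized")
  J <- jacobian(res$model, X)
  H <- 2 * res$state$beta * crossprod(J)
  diag(H) <- diag(H) + 2 * res$state$alpha
  st2 <- update_hyperparameters(res$state, res$model, H, 20)
  # alpha = 0 gives gamma = N_par exactly
  expect_equal(st2$gamma, n_params(m))
  expect_gt(st2$beta, 0)

  st3 <- update_hyperparameters(st2, res$model, H + diag(0.5, ncol(H)), 20)
  expect_gte(st3$gamma, 0)
  expect_lte(st3$gamma, n_params(m))
  expect_equal(st3$F, st3$beta * st3$E_D + st3$alpha * st3$E_w)
})

test_that("training recovers a realizable function and is deterministic", {
  set.seed(6)
  true <- brnn_model(2, 2, seed = 77)
  X <- matrix(runif(60 * 2, -1, 1), 60)
  y <- forward(true, X)
  for (alg in c("lm", "brnn")) {
    fit <- brnn_train(X, y, n_hidden = 4, algorithm = alg, seed = 8)
    expect_lt(mean((y - predict(fit, X))^2), 1e-6)
  }
  f1 <- brnn_train(X, y, n_hidden = 4, algorithm = "brnn", seed = 3)
  f2 <- brnn_train(X, y, n_hidden = 4, algorithm = "brnn", seed = 3)
  expect_identical(f1$history, f2$history)
  expect_identical(get_params(f1), get_params(f2))
})

test_that("BRNN approximates a smooth function on held-out points", {
  x <- matrix(seq(-1, 1, length.out = 50), ncol = 1)
  fit <- brnn_train(x, x[, 1]^2, n_hidden = 10, algorithm = "brnn",
                    seed = 4)
  grid <- matrix(seq(-0.97, 0.97, length.out = 41), ncol = 1)
  expect_lt(mean((grid[, 1]^2 - predict(fit, grid))^2), 1e-3)
})

test_that("training history tracks a consistent objective and bounded gamma", {
  set.seed(7)
  X <- matrix(runif(40, -1, 1), ncol = 1)
  y <- sin(2 * X[, 1]) + rnorm(40, 0, 0.1)
  fit <- brnn_train(X, y, n_hidden = 6, algorithm = "brnn", seed = 2,
                    max_iter = 60)
  h <- fit$history
  expect_true(all(h$gamma >= 0 & h$gamma <= n_params(fit)))
  expect_equal(h$F, h$beta * h$E_D + h$alpha * h$E_w)
  expect_true(all(h$alpha >= 0) && all(h$beta > 0) && all(h$lambda > 0))
})

test_that("over-parameterized fits drive gamma well below N_par", {
  set.seed(8)
  X <- matrix(runif(15, -1, 1), ncol = 1)
  y <- 0.5 * X[, 1] + rnorm(15, 0, 0.2)
  fit <- brnn_train(X, y, n_hidden = 15, algorithm = "brnn", seed = 3,
                    max_iter = 150)
  expect_lt(fit$state$gamma, n_params(fit) / 2)
})

test_that("plain-LM equals the regularized path with alpha = 0, beta = 1", {
  set.seed(9)
  m <- brnn_model(2, 3, seed = 4)
  X <- matrix(rnorm(30), 15, 2)
  y <- rnorm(15)
  st_sse <- training_state(n_params(m), alpha = 0, beta = 1)
  st_reg <- training_state(n_params(m), alpha = 0, beta = 1)
  a <- lm_step(m, X, y, st_sse, objective = "sse")
  b <- lm_step(m, X, y, st_reg, objective = "regularized")
  expect_identical(get_params(a$model), get_params(b$model))
  expect_identical(a$state$lambda, b$state$lambda)
})

test_that("hidden-size selection returns the argmin of its own curve", {
  set.seed(10)
  X <- matrix(runif(60, -1, 1), ncol = 1)
  y <- sin(3 * X[, 1]) + rnorm(60, 0, 0.15)
  sel <- select_hidden_size(X, y, candidates = c(3L, 8L, 30L), k_folds = 3,
                            seed = 2, max_iter = 60)
  expect_equal(nrow(sel$curve), 3)
  expect_equal(sel$curve$cv_mse[sel$curve$n_hidden == sel$best_h],
               min(sel$curve$cv_mse))
})

test_that("models serialize to JSON and back without loss", {
  set.seed(11)
  X <- matrix(rnorm(40), 20, 2)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(20, 0, 0.05)
  fit <- brnn_train(X, y, n_hidden = 3, algorithm = "brnn", seed = 6,
                    max_iter = 50)
  path <- withr::local_tempfile(fileext = ".json")
  write_brnn_model(fit, path)
  back <- read_brnn_model(path)
  Xn <- matrix(rnorm(10), 5, 2)
  expect_equal(predict(back, Xn), predict(fit, Xn), tolerance = 1e-12)
  expect_equal(back$state$gamma, fit$state$gamma, tolerance = 1e-12)
})
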