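# Bayesian-regularized neural network regression, implemented from scratch:
# a single-hidden-layer perceptron (sigmoid hidden units, linear output)
# trained by Levenberg-Marquardt on the regularized objective
#   F = beta * E_D + alpha * E_w
# with the evidence-framework (MacKay / Foresee-Hagan) re-estimation of
# alpha, beta and the effective number of parameters gamma at each
# iteration. Plain Levenberg-Marquardt (alpha fixed at 0) and
# Polak-Ribiere conjugate-gradient trainers are provided for comparison.
#
# Parameter packing order used throughout (length N_par = H*N + 2H + 1):
#   [ input weights W (H x N, column-major), hidden biases b (H),
#     output weights w (H), output bias b0 ].

#' Numerically stable logistic sigmoid
#'
#' `1 / (1 + exp(-x))`, evaluated without overflow for large `|x|`.
#'
#' @param x Numeric vector.
#' @return Values in `(0, 1)`.
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  dim(out) <- dim(x)
  out
}

#' Construct a single-hidden-layer network
#'
#' Weights are initialized uniformly in `[-0.5, 0.5]` from the seed.
#' Input/target scaling slots default to the identity; [brnn_train()] fills
#' them in.
#'
#' @param n_inputs Number of input features.
#' @param n_hidden Number of sigmoid hidden units.
#' @param seed Integer seed for weight initialization (optional).
#' @return An object of class `brnn_model`.
#' @export
brnn_model <- function(n_inputs, n_hidden, seed = NULL) {
  n_inputs <- as.integer(n_inputs)
  n_hidden <- as.integer(n_hidden)
  stopifnot(n_inputs >= 1, n_hidden >= 1)
  init <- function() {
    list(
      input_weights = matrix(stats::runif(n_hidden * n_inputs, -0.5, 0.5),
                             n_hidden, n_inputs),
      hidden_biases = stats::runif(n_hidden, -0.5, 0.5),
      output_weights = stats::runif(n_hidden, -0.5, 0.5),
      output_bias = stats::runif(1, -0.5, 0.5)
    )
  }
  w <- if (is.null(seed)) init() else with_seed(seed, init())
  structure(
    c(list(n_inputs = n_inputs, n_hidden = n_hidden), w,
      list(x_center = rep(0, n_inputs), x_scale = rep(1, n_inputs),
           y_min = 0, y_range = 1)),
    class = "brnn_model"
  )
}

#' Total number of free parameters of a network
#' @param model A [brnn_model()].
#' @return `H * N + 2 * H + 1`.
#' @export
n_params <- function(model) {
  model$n_hidden * model$n_inputs + 2L * model$n_hidden + 1L
}

#' Get or set the packed parameter vector
#'
#' Packing order: input weights (column-major), hidden biases, output
#' weights, output bias.
#'
#' @param model A model object.
#' @param theta Numeric vector of length [n_params()].
#' @return `get_params` returns the packed vector; `set_params` the
#'   updated model.
#' @export
get_params <- function(model) UseMethod("get_params")

#' @export
get_params.brnn_model <- function(model) {
  c(as.vector(model$input_weights), model$hidden_biases,
    model$output_weights, model$output_bias)
}

#' @rdname get_params
#' @export
set_params <- function(model, theta) UseMethod("set_params")

#' @export
set_params.brnn_model <- function(model, theta) {
  H <- model$n_hidden
  N <- model$n_inputs
  stopifnot(length(theta) == n_params(model))
  model$input_weights <- matrix(theta[seq_len(H * N)], H, N)
  model$hidden_biases <- theta[H * N + seq_len(H)]
  model$output_weights <- theta[H * N + H + seq_len(H)]
  model$output_bias <- theta[H * N + 2L * H + 1L]
  model
}

#' Forward pass through a network
#'
#' Computes `y = b0 + sum_j w_j * sigmoid(sum_i W_ji x_i + b_j)` directly on
#' the supplied inputs (no scaling applied; see [predict.brnn_model()] for
#' prediction on the original data scale).
#'
#' @param model A model object.
#' @param x Numeric vector (one sample) or matrix with one sample per row.
#' @return Numeric vector of predictions, one per sample.
#' @export
forward <- function(model, x) UseMethod("forward")

#' @export
forward.brnn_model <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != model$n_inputs) {
    stop(sprintf("expected %d inputs, got %d", model$n_inputs, ncol(X)),
         call. = FALSE)
  }
  Z <- sigmoid(sweep(X %*% t(model$input_weights), 2, model$hidden_biases,
                     "+"))
  drop(Z %*% model$output_weights) + model$output_bias
}

#' Analytic Jacobian of predictions with respect to the parameters
#'
#' Row `s`, column `p` holds the partial derivative of the prediction for
#' sample `s` with respect to parameter `p`, in the packing order of
#' [get_params()]. With the residual convention `r = target - prediction`,
#' the residual Jacobian is the negative of this matrix; the
#' Levenberg-Marquardt normal equations are formed so the signs cancel.
#'
#' @param model A model object.
#' @param x Sample matrix (rows = samples).
#' @return Matrix `n_samples x n_params`.
#' @export
jacobian <- function(model, x) UseMethod("jacobian")

#' @export
jacobian.brnn_model <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  n <- nrow(X)
  H <- model$n_hidden
  N <- model$n_inputs
  A <- sweep(X %*% t(model$input_weights), 2, model$hidden_biases, "+")
  Z <- sigmoid(A)                      # n x H hidden activations
  dZ <- Z * (1 - Z)                    # sigmoid derivative
  # d y / d W_ji = w_j * z_j (1 - z_j) * x_i; column-major over (j, i)
  Dhid <- sweep(dZ, 2, model$output_weights, "*")  # n x H
  Jw <- matrix(0, n, H * N)
  for (i in seq_len(N)) {
    Jw[, (i - 1L) * H + seq_len(H)] <- Dhid * X[, i]
  }
  cbind(Jw, Dhid, Z, rep(1, n))
}

#' A linear least-squares harness
#'
#' A trivial model whose forward map is `X %*% coefficients` and whose
#' Jacobian is the design matrix itself. On such a model a single
#' Gauss-Newton step lands exactly on the ordinary-least-squares optimum,
#' which makes it a useful exactness check for the Levenberg-Marquardt
#' machinery.
#'
#' @param coefficients Numeric coefficient vector.
#' @return An object of class `linear_harness`.
#' @export
linear_harness <- function(coefficients) {
  structure(list(coefficients = as.numeric(coefficients)),
            class = "linear_harness")
}

#' @export
get_params.linear_harness <- function(model) model$coefficients

#' @export
set_params.linear_harness <- function(model, theta) {
  model$coefficients <- theta
  model
}

#' @export
forward.linear_harness <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  drop(X %*% model$coefficients)
}

#' @export
jacobian.linear_harness <- function(model, x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

#' Create a training state
#'
#' Holds the Bayesian-regularization hyperparameters: `alpha` (weight
#' decay), `beta` (inverse noise level), `gamma` (effective number of
#' parameters) and the Levenberg-Marquardt damping `lambda`, plus the
#' current objective decomposition `F = beta * E_D + alpha * E_w`.
#'
#' @param n_par Total parameter count of the model being trained.
#' @param alpha Initial weight-decay hyperparameter (>= 0).
#' @param beta Initial noise hyperparameter (> 0).
#' @param lambda Initial damping; `NULL` defers to
#'   `1e-2 * max(diag(J'J))` at the first step, after which the x10
#'   escalation rule takes over.
#' @return An object of class `training_state`.
#' @export
training_state <- function(n_par, alpha = 0.01, beta = 1, lambda = NULL) {
  stopifnot(alpha >= 0, beta > 0, is.null(lambda) || lambda > 0)
  structure(
    list(alpha = alpha, beta = beta, gamma = as.numeric(n_par),
         lambda = lambda, n_par = as.integer(n_par),
         E_D = NA_real_, E_w = NA_real_, F = NA_real_, iteration = 0L),
    class = "training_state"
  )
}

#' One Levenberg-Marquardt step
#'
#' Solves the damped normal equations for the parameter update `h`:
#' for `objective = "sse"`, `(J'J + lambda I) h = J'r`; for
#' `objective = "regularized"`,
#' `(beta J'J + (alpha + lambda) I) h = beta J'r - alpha theta`,
#' where `r = targets - predictions`. The step is accepted if the objective
#' decreases, in which case `lambda` is divided by 10; otherwise `lambda`
#' is multiplied by 10 and the step re-solved, up to a damping cap.
#'
#' @param model A model object supporting [forward()] and [jacobian()].
#' @param x Sample matrix.
#' @param targets Numeric target vector.
#' @param state A [training_state()].
#' @param objective `"regularized"` (minimize `beta E_D + alpha E_w`) or
#'   `"sse"` (minimize `E_D` alone).
#' @param lambda_max Damping cap above which the step is abandoned.
#' @return A list with the updated `model`, `state` (with fresh `E_D`,
#'   `E_w`, `F`, `lambda`) and a logical `accepted`.
#' @export
lm_step <- function(model, x, targets, state,
                    objective = c("regularized", "sse"),
                    lambda_max = 1e12) {
  objective <- match.arg(objective)
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  theta <- get_params(model)
  n_par <- length(theta)

  r <- targets - forward(model, X)
  J <- jacobian(model, X)
  JtJ <- crossprod(J)
  E_D <- sum(r^2)
  E_w <- sum(theta^2)

  a <- if (objective == "regularized") state$alpha else 0
  b <- if (objective == "regularized") state$beta else 1
  F0 <- b * E_D + a * E_w

  if (is.null(state$lambda)) {
    state$lambda <- 1e-2 * max(diag(JtJ))
    if (!is.finite(state$lambda) || state$lambda <= 0) state$lambda <- 1
  }
  lambda <- state$lambda
  g <- b * crossprod(J, r) - a * theta

  accepted <- FALSE
  model_new <- model
  E_D_new <- E_D
  E_w_new <- E_w
  F_new <- F0
  while (lambda <= lambda_max) {
    A <- b * JtJ
    diag(A) <- diag(A) + a + lambda
    h <- tryCatch(solve(A, g), error = function(e) NULL)
    if (is.null(h) || any(!is.finite(h))) {
      lambda <- lambda * 10
      next
    }
    cand <- set_params(model, theta + drop(h))
    r_c <- targets - forward(cand, X)
    E_D_c <- sum(r_c^2)
    E_w_c <- sum((theta + drop(h))^2)
    F_c <- b * E_D_c + a * E_w_c
    if (is.finite(F_c) && F_c < F0) {
      accepted <- TRUE
      model_new <- cand
      E_D_new <- E_D_c
      E_w_new <- E_w_c
      F_new <- F_c
      lambda <- max(lambda / 10, 1e-14)
      break
    }
    lambda <- lambda * 10
  }
  if (!accepted && lambda > lambda_max) {
    lambda <- lambda_max
  }

  state$lambda <- lambda
  state$E_D <- E_D_new
  state$E_w <- E_w_new
  state$F <- state$beta * E_D_new + state$alpha * E_w_new
  state$iteration <- state$iteration + 1L
  list(model = model_new, state = state, accepted = accepted,
       grad_norm = sqrt(sum((2 * g)^2)))
}

#' Evidence-framework hyperparameter update
#'
#' Given the Gauss-Newton Hessian approximation of the regularized
#' objective `F = beta E_D + alpha E_w` at the current weights,
#' `H_MAP = beta grad^2 E_D + alpha grad^2 E_w ~= 2 beta J'J + 2 alpha I`
#' (the sum-of-squares Hessians each carry a factor 2), re-estimates:
#' \deqn{\gamma = N_{par} - 2\alpha\, \mathrm{tr}(H_{MAP}^{-1}),\qquad
#'       \alpha = \gamma / (2 E_w),\qquad \beta = (n - \gamma) / (2 E_D).}
#' With this Hessian, `gamma` equals the usual evidence-framework sum of
#' eigenvalue ratios and lies in `[0, N_par]` by construction; it is
#' clamped there against round-off, and `alpha`, `beta` are clamped to
#' `[1e-12, 1e12]`. Degenerate `E_w = 0` or `E_D = 0` trigger a warning
#' and the clamp.
#'
#' @param state A [training_state()] whose `E_D` reflects the current fit.
#' @param model The current model (supplies `E_w` from its weights).
#' @param h_map Hessian approximation `2 beta J'J + 2 alpha I` at the
#'   current weights.
#' @param n Number of training samples.
#' @return The updated [training_state()].
#' @export
update_hyperparameters <- function(state, model, h_map, n) {
  theta <- get_params(model)
  n_par <- length(theta)
  E_w <- sum(theta^2)
  E_D <- state$E_D

  tr_hinv <- tryCatch(sum(diag(solve(h_map))), error = function(e) NA_real_)
  if (!is.finite(tr_hinv)) {
    # near-singular Hessian: fall back to an eigenvalue-thresholded inverse
    ev <- eigen(h_map, symmetric = TRUE, only.values = TRUE)$values
    tr_hinv <- sum(1 / pmax(ev, 1e-12))
  }
  gamma <- n_par - 2 * state$alpha * tr_hinv
  gamma <- min(max(gamma, 0), n_par)

  if (E_w <= 0) {
    warning("zero weight norm; alpha clamped", call. = FALSE)
  }
  if (E_D <= 0) {
    warning("perfect fit (E_D = 0); beta clamped", call. = FALSE)
  }
  clamp <- function(v) min(max(v, 1e-12), 1e12)
  state$alpha <- clamp(gamma / (2 * max(E_w, 1e-300)))
  state$beta <- clamp((n - gamma) / (2 * max(E_D, 1e-300)))
  state$gamma <- gamma
  state$E_w <- E_w
  state$F <- state$beta * E_D + state$alpha * E_w
  state
}

# column-wise z-score statistics; zero-variance columns get scale 1
scaling_stats <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

#' Train a network by Bayesian-regularized Levenberg-Marquardt
#'
#' Inputs are z-score standardized and targets min-max scaled to `[0, 1]`
#' before training (statistics are stored in the model and inverted by
#' [predict.brnn_model()]). Three algorithms are available:
#' \describe{
#'   \item{`"brnn"`}{Levenberg-Marquardt on `F = beta E_D + alpha E_w`,
#'     with [update_hyperparameters()] applied after every step
#'     (Foresee-Hagan evidence framework).}
#'   \item{`"lm"`}{Plain Levenberg-Marquardt on `E_D` (alpha fixed at 0,
#'     beta at 1, no hyperparameter updates); follows exactly the same
#'     trajectory as `"brnn"` would with updates disabled.}
#'   \item{`"cg"`}{Polak-Ribiere conjugate gradient on `E_D` with line
#'     search (via [stats::optim()]).}
#' }
#' Training stops at `max_iter`, when the objective gradient norm falls
#' below `tol`, when `gamma` has stabilized (|change| < 1e-3) for 5
#' consecutive iterations (`"brnn"` only), or when no step can be accepted.
#'
#' @param x Feature matrix (rows = samples) or data frame of numeric
#'   columns.
#' @param y Numeric target vector.
#' @param n_hidden Hidden-layer size.
#' @param algorithm `"brnn"`, `"lm"` or `"cg"`.
#' @param seed Integer seed controlling weight initialization.
#' @param max_iter Iteration cap (default 300).
#' @param tol Gradient-norm stopping tolerance.
#' @param alpha0,beta0 Initial hyperparameters for `"brnn"`.
#' @return The trained `brnn_model` with components `state`
#'   (final [training_state()]), `history` (one row per iteration:
#'   `iteration`, `E_D`, `E_w`, `F`, `alpha`, `beta`, `gamma`, `lambda`),
#'   `algorithm` and `seed`.
#' @export
brnn_train <- function(x, y, n_hidden = 10L,
                       algorithm = c("brnn", "lm", "cg"),
                       seed = 1L, max_iter = 300L, tol = 1e-7,
                       alpha0 = 0.01, beta0 = 1) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (nrow(X) != length(y)) stop("x / y length mismatch", call. = FALSE)

  sc <- scaling_stats(X)
  Xs <- sweep(sweep(X, 2, sc$center), 2, sc$scale, "/")
  y_min <- min(y)
  y_range <- max(y) - y_min
  if (y_range == 0) y_range <- 1
  ys <- (y - y_min) / y_range

  model <- brnn_model(ncol(X), n_hidden, seed = seed)
  model$x_center <- sc$center
  model$x_scale <- sc$scale
  model$y_min <- y_min
  model$y_range <- y_range
  n_par <- n_params(model)
  n <- nrow(X)

  state <- training_state(n_par,
                          alpha = if (algorithm == "brnn") alpha0 else 0,
                          beta = if (algorithm == "brnn") beta0 else 1)

  if (algorithm == "cg") {
    fn <- function(th) {
      r <- ys - forward(set_params(model, th), Xs)
      sum(r^2)
    }
    gr <- function(th) {
      m <- set_params(model, th)
      r <- ys - forward(m, Xs)
      -2 * drop(crossprod(jacobian(m, Xs), r))
    }
    opt <- stats::optim(get_params(model), fn, gr, method = "CG",
                        control = list(maxit = max_iter, type = 2,
                                       reltol = 1e-12))
    model <- set_params(model, opt$par)
    state$E_D <- opt$value
    state$E_w <- sum(opt$par^2)
    state$F <- state$E_D
    state$iteration <- as.integer(opt$counts[["function"]])
    history <- data.frame(iteration = state$iteration, E_D = state$E_D,
                          E_w = state$E_w, F = state$F, alpha = 0,
                          beta = 1, gamma = NA_real_, lambda = NA_real_)
  } else {
    history <- vector("list", max_iter)
    gamma_stable <- 0L
    for (it in seq_len(max_iter)) {
      step <- lm_step(model, Xs, ys, state, objective = "regularized")
      model <- step$model
      state <- step$state

      if (algorithm == "brnn") {
        gamma_prev <- state$gamma
        J <- jacobian(model, Xs)
        h_map <- 2 * state$beta * crossprod(J)
        diag(h_map) <- diag(h_map) + 2 * state$alpha
        state <- suppressWarnings(
          update_hyperparameters(state, model, h_map, n))
        gamma_stable <- if (abs(state$gamma - gamma_prev) < 1e-3)
          gamma_stable + 1L else 0L
      }

      history[[it]] <- data.frame(
        iteration = it, E_D = state$E_D, E_w = state$E_w, F = state$F,
        alpha = state$alpha, beta = state$beta, gamma = state$gamma,
        lambda = state$lambda)

      if (!is.finite(state$F)) {
        stop("training diverged: non-finite objective", call. = FALSE)
      }
      if (!step$accepted) break
      if (step$grad_norm < tol) break
      if (algorithm == "brnn" && gamma_stable >= 5L) break
    }
    history <- do.call(rbind, history[!vapply(history, is.null, TRUE)])
  }

  model$state <- state
  model$history <- history
  model$algorithm <- algorithm
  model$seed <- as.integer(seed)
  model
}

#' Predict from a trained network on the original data scale
#'
#' Applies the stored input standardization, runs the forward pass, and
#' inverts the target scaling.
#'
#' @param object A trained `brnn_model` from [brnn_train()].
#' @param newdata Feature matrix or data frame (rows = samples).
#' @param ... Unused.
#' @return Numeric predictions in the original target units.
#' @export
predict.brnn_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  forward(object, Xs) * object$y_range + object$y_min
}

#' @export
print.brnn_model <- function(x, ...) {
  cat(sprintf("<brnn_model> %d-%d-1 network (%d parameters)\n",
              x$n_inputs, x$n_hidden, n_params(x)))
  if (!is.null(x$state)) {
    cat(sprintf("  trained (%s): E_D = %.4g, gamma = %.2f / %d\n",
                x$algorithm, x$state$E_D, x$state$gamma, n_params(x)))
  }
  invisible(x)
}

#' Select the hidden-layer size by cross-validation
#'
#' Trains one network per candidate size on each of `k_folds` folds and
#' returns the candidate minimizing mean held-out MSE, with the full curve.
#'
#' @param x Feature matrix.
#' @param y Targets.
#' @param candidates Candidate hidden sizes (default 5 to 60 in steps
#'   of 5).
#' @param k_folds Number of CV folds.
#' @param seed Seed for fold assignment and weight initialization.
#' @param algorithm Training algorithm passed to [brnn_train()].
#' @param max_iter Iteration cap per fit.
#' @return A list with `best_h` and `curve`
#'   (data frame `n_hidden`, `cv_mse`).
#' @export
select_hidden_size <- function(x, y, candidates = seq(5L, 60L, by = 5L),
                               k_folds = 5L, seed = 1L,
                               algorithm = "brnn", max_iter = 100L) {
  X <- as.matrix(x)
  n <- nrow(X)
  stopifnot(n >= k_folds)
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  cv_mse <- vapply(candidates, function(h) {
    errs <- vapply(seq_len(k_folds), function(k) {
      tr <- folds != k
      fit <- brnn_train(X[tr, , drop = FALSE], y[tr], n_hidden = h,
                        algorithm = algorithm, seed = seed + k,
                        max_iter = max_iter)
      mean((y[!tr] - predict(fit, X[!tr, , drop = FALSE]))^2)
    }, 0)
    mean(errs)
  }, 0)
  list(best_h = candidates[which.min(cv_mse)],
       curve = data.frame(n_hidden = candidates, cv_mse = cv_mse))
}

#' Serialize / restore a trained model as JSON
#'
#' Stores layer sizes, parameter arrays, scaling statistics, the final
#' hyperparameter state, seed and training history.
#'
#' @param model A `brnn_model`.
#' @param path JSON file path.
#' @return `write_brnn_model` returns `path` invisibly; `read_brnn_model`
#'   the restored model.
#' @export
write_brnn_model <- function(model, path) {
  stopifnot(inherits(model, "brnn_model"))
  payload <- list(
    n_inputs = model$n_inputs, n_hidden = model$n_hidden,
    input_weights = model$input_weights,
    hidden_biases = model$hidden_biases,
    output_weights = model$output_weights,
    output_bias = model$output_bias,
    x_center = model$x_center, x_scale = model$x_scale,
    y_min = model$y_min, y_range = model$y_range,
    state = model$state[c("alpha", "beta", "gamma", "lambda",
                          "E_D", "E_w", "F", "iteration")],
    algorithm = model$algorithm, seed = model$seed,
    history = model$history
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_brnn_model
#' @export
read_brnn_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- brnn_model(p$n_inputs, p$n_hidden)
  model$input_weights <- matrix(p$input_weights, p$n_hidden, p$n_inputs)
  model$hidden_biases <- as.numeric(p$hidden_biases)
  model$output_weights <- as.numeric(p$output_weights)
  model$output_bias <- as.numeric(p$output_bias)
  model$x_center <- as.numeric(p$x_center)
  model$x_scale <- as.numeric(p$x_scale)
  model$y_min <- p$y_min
  model$y_range <- p$y_range
  if (!is.null(p$state)) {
    st <- training_state(n_params(model))
    st[names(p$state)] <- p$state
    model$state <- st
  }
  model$algorithm <- p$algorithm
  model$seed <- p$seed
  model$history <- p$history
  model
}
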