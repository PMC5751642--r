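# Evaluation pipeline: train/test splitting, the five comparison metrics
# (correlation R, MAE, RMSE/MSE, relative absolute error, root relative
# squared error), the prediction-error histogram, baseline regressors, and
# the end-to-end simulate -> extract -> train -> evaluate orchestration.

#' Split features and labels into train and test sets
#'
#' @param features Data frame or matrix of predictors.
#' @param labels Numeric target vector.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Seed for the random assignment.
#' @param grouping `"by_sample"` splits rows independently (the pooled
#'   70/30 convention); `"by_subject"` keeps all rows of a subject on one
#'   side, avoiding subject-identity leakage.
#' @param subject_ids Character vector (one per row), required for
#'   `"by_subject"`; defaults to a `subject_id` column of `features` when
#'   present.
#' @return A list with `train` and `test`, each holding `x`, `y` and the
#'   row `index` into the input.
#' @export
split_data <- function(features, labels, train_fraction = 0.7, seed = 1L,
                       grouping = c("by_sample", "by_subject"),
                       subject_ids = NULL) {
  grouping <- match.arg(grouping)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("'train_fraction' must lie strictly in (0, 1)", call. = FALSE)
  }
  n <- if (is.matrix(features)) nrow(features) else nrow(as.data.frame(features))
  stopifnot(n >= 2L, length(labels) == n)

  if (grouping == "by_sample") {
    idx_train <- with_seed(seed,
                           sample.int(n, size = round(train_fraction * n)))
  } else {
    if (is.null(subject_ids) && is.data.frame(features) &&
        "subject_id" %in% names(features)) {
      subject_ids <- features$subject_id
    }
    if (is.null(subject_ids)) {
      stop("'by_subject' split needs subject_ids", call. = FALSE)
    }
    subjects <- unique(subject_ids)
    n_train <- max(1L, round(train_fraction * length(subjects)))
    train_subj <- with_seed(seed, sample(subjects, n_train))
    idx_train <- which(subject_ids %in% train_subj)
  }
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(n), idx_train)

  take <- function(idx) {
    x <- if (is.matrix(features)) features[idx, , drop = FALSE]
         else features[idx, , drop = FALSE]
    list(x = x, y = labels[idx], index = idx)
  }
  list(train = take(idx_train), test = take(idx_test))
}

#' Compute the regression comparison metrics
#'
#' Given model outputs and targets, computes mean squared error, Pearson
#' correlation R between outputs and targets, mean absolute error, root
#' mean squared error, relative absolute error
#' (`100 * sum|t - o| / sum|t - mean(t)|`) and root relative squared error
#' (`100 * sqrt(sum (t - o)^2 / sum (t - mean(t))^2)`). The relative errors
#' normalize against the mean predictor, which therefore scores exactly
#' 100% on both. Constant targets make the relative errors (and R)
#' undefined; they are returned as `NA` with the report flagged.
#'
#' @param outputs Model predictions.
#' @param targets True values.
#' @param split Label recorded in the report (`"train"`, `"test"`,
#'   `"all"`).
#' @param n_bins Number of error-histogram bins.
#' @return An object of class `eval_report`: a list with `mse`, `r`,
#'   `mae`, `rmse`, `rae`, `rrse`, `split`, `n`, `histogram` and
#'   `undefined_relative`.
#' @export
compute_metrics <- function(outputs, targets, split = "test",
                            n_bins = 20L) {
  stopifnot(length(outputs) == length(targets), length(targets) > 0)
  e <- targets - outputs
  mse <- mean(e^2)
  mae <- mean(abs(e))
  denom_abs <- sum(abs(targets - mean(targets)))
  denom_sq <- sum((targets - mean(targets))^2)
  undefined <- denom_sq == 0
  rae <- if (undefined) NA_real_ else 100 * sum(abs(e)) / denom_abs
  rrse <- if (undefined) NA_real_ else 100 * sqrt(sum(e^2) / denom_sq)
  r <- if (undefined || stats::sd(outputs) == 0) {
    if (mse == 0 && !undefined) 1 else NA_real_
  } else {
    stats::cor(outputs, targets)
  }
  structure(
    list(mse = mse, r = r, mae = mae, rmse = sqrt(mse),
         rae = rae, rrse = rrse, split = split, n = length(targets),
         histogram = error_histogram(outputs, targets, n_bins),
         undefined_relative = undefined),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s (n = %d)\n", x$split, x$n))
  cat(sprintf("  MSE %.6g  R %.4f  MAE %.6g  RMSE %.6g  RAE %.2f%%  RRSE %.2f%%\n",
              x$mse, x$r, x$mae, x$rmse, x$rae, x$rrse))
  invisible(x)
}

#' Histogram of prediction errors
#'
#' Errors are `target - output`, binned into `n_bins` equal-width bins
#' spanning `[min(error), max(error)]`. When all errors are identical a
#' single bin holds every sample.
#'
#' @param outputs Model predictions.
#' @param targets True values.
#' @param n_bins Number of bins (default 20).
#' @return Data frame with `bin_left`, `bin_right`, `count`; counts sum to
#'   the number of samples.
#' @export
error_histogram <- function(outputs, targets, n_bins = 20L) {
  stopifnot(length(outputs) == length(targets), length(targets) > 0)
  e <- targets - outputs
  lo <- min(e)
  hi <- max(e)
  if (lo == hi) {
    return(data.frame(bin_left = lo, bin_right = hi,
                      count = length(e)))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  width <- (hi - lo) / n_bins
  idx <- pmin(pmax(ceiling((e - lo) / width), 1L), n_bins)
  data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1],
             count = tabulate(idx, nbins = n_bins))
}

# coerce a split element (list(x, y)) into a numeric design matrix + y,
# dropping non-feature key columns if present
design_matrix <- function(x) {
  if (is.data.frame(x)) {
    drop_cols <- intersect(names(x),
                           c("subject_id", "evening_id", "hour_index",
                             "ebac"))
    x <- x[setdiff(names(x), drop_cols)]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  x
}

#' Ordinary-least-squares baseline
#'
#' Fits a linear model with intercept to the training set (rank-deficient
#' designs fall back to a tiny ridge penalty) and evaluates on the test
#' set.
#'
#' @param train,test Lists with `x` (features) and `y` (targets), as
#'   produced by [split_data()].
#' @param n_bins Histogram bins for the report.
#' @return An [compute_metrics()] report on the test set, with the fitted
#'   `coefficients` attached as an attribute.
#' @export
linear_regression_baseline <- function(train, test, n_bins = 20L) {
  Xtr <- cbind(1, design_matrix(train$x))
  Xte <- cbind(1, design_matrix(test$x))
  if (nrow(Xtr) <= ncol(Xtr) - 1L) {
    stop("need more training samples than features", call. = FALSE)
  }
  fit <- stats::lm.fit(Xtr, train$y)
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    # rank deficiency: ridge fallback keeps the solve well posed
    A <- crossprod(Xtr) + diag(1e-8, ncol(Xtr))
    coefs <- drop(solve(A, crossprod(Xtr, train$y)))
  }
  preds <- drop(Xte %*% coefs)
  rep <- compute_metrics(preds, test$y, split = "test", n_bins = n_bins)
  attr(rep, "coefficients") <- coefs
  rep
}

# RBF-kernel support-vector regression baseline (library implementation;
# a comparison row, not this package's contribution)
svm_baseline <- function(train, test, n_bins = 20L) {
  fit <- e1071::svm(design_matrix(train$x), train$y, type = "eps-regression",
                    kernel = "radial")
  preds <- as.numeric(stats::predict(fit, design_matrix(test$x)))
  compute_metrics(preds, test$y, split = "test", n_bins = n_bins)
}

#' Compare the BRNN against baseline regressors
#'
#' Trains the Bayesian-regularized network, an RBF-kernel support-vector
#' regressor (library implementation) and ordinary least squares on the
#' same train/test split, and tabulates the five comparison metrics on the
#' test set.
#'
#' @param split A list with `train` and `test` from [split_data()].
#' @param n_hidden Hidden-layer size for the network.
#' @param seed Seed for network initialization.
#' @param max_iter Training iteration cap.
#' @return A data frame with one row per model (`MLP`, `SVM`,
#'   `Linear Regression`) and columns `r`, `mae`, `rmse`, `rae_pct`,
#'   `rrse_pct`.
#' @export
compare_models <- function(split, n_hidden = 10L, seed = 1L,
                           max_iter = 300L) {
  Xtr <- design_matrix(split$train$x)
  Xte <- design_matrix(split$test$x)

  mlp <- brnn_train(Xtr, split$train$y, n_hidden = n_hidden,
                    algorithm = "brnn", seed = seed, max_iter = max_iter)
  rep_mlp <- compute_metrics(predict(mlp, Xte), split$test$y)
  rep_svm <- svm_baseline(split$train, split$test)
  rep_ols <- linear_regression_baseline(split$train, split$test)

  row <- function(name, rep) {
    data.frame(model = name, r = rep$r, mae = rep$mae, rmse = rep$rmse,
               rae_pct = rep$rae, rrse_pct = rep$rrse,
               stringsAsFactors = FALSE)
  }
  rbind(row("MLP", rep_mlp), row("SVM", rep_svm),
        row("Linear Regression", rep_ols))
}

#' Run the full estimation pipeline
#'
#' Orchestrates the complete analysis: simulate the study
#' ([simulate_dataset()]), extract gait features ([feature_table()]),
#' split 70/30 ([split_data()]), optionally select the hidden-layer size
#' by cross-validation, train the Bayesian-regularized network, and
#' evaluate on train and test splits, plus the baseline comparison. Fully
#' reproducible from `(config, seed)`.
#'
#' @param config A [simulation_config()]; its `seed` drives the data
#'   generation.
#' @param n_hidden Hidden-layer size (ignored if `select_hidden = TRUE`).
#' @param select_hidden If `TRUE`, choose the size by CV over
#'   `hidden_candidates`.
#' @param hidden_candidates Candidate sizes for selection.
#' @param train_fraction Training fraction for the split.
#' @param seed Seed for splitting and training (distinct from the
#'   generator's).
#' @param max_iter Training iteration cap.
#' @param compare If `TRUE`, also run [compare_models()].
#' @param out_dir Optional directory; when given, writes the feature table
#'   and metrics as CSV, the model and a manifest as JSON.
#' @return A list with `features`, `split`, `model`, `metrics_train`,
#'   `metrics_test`, `comparison` (or `NULL`), `hidden_selection`
#'   (or `NULL`) and `config`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         n_hidden = 10L, select_hidden = FALSE,
                         hidden_candidates = seq(5L, 60L, by = 5L),
                         train_fraction = 0.7, seed = 1L,
                         max_iter = 300L, compare = TRUE,
                         out_dir = NULL) {
  dataset <- simulate_dataset(config)
  if (length(dataset$recordings) < 4L) {
    stop("pipeline error [simulate]: too few observed recordings",
         call. = FALSE)
  }
  features <- feature_table(dataset)
  X <- as.matrix(features[gait_feature_names()])
  y <- features$ebac

  split <- split_data(X, y, train_fraction = train_fraction, seed = seed)

  hidden_selection <- NULL
  if (select_hidden) {
    hidden_selection <- select_hidden_size(split$train$x, split$train$y,
                                           candidates = hidden_candidates,
                                           seed = seed)
    n_hidden <- hidden_selection$best_h
  }

  model <- brnn_train(split$train$x, split$train$y, n_hidden = n_hidden,
                      algorithm = "brnn", seed = seed, max_iter = max_iter)
  metrics_train <- compute_metrics(predict(model, split$train$x),
                                   split$train$y, split = "train")
  metrics_test <- compute_metrics(predict(model, split$test$x),
                                  split$test$y, split = "test")

  comparison <- if (compare) {
    compare_models(split, n_hidden = n_hidden, seed = seed,
                   max_iter = max_iter)
  }

  result <- list(features = features, split = split, model = model,
                 metrics_train = metrics_train,
                 metrics_test = metrics_test,
                 comparison = comparison,
                 hidden_selection = hidden_selection,
                 config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(features, file.path(out_dir, "features.csv"))
    write_brnn_model(model, file.path(out_dir, "model.json"))
    metr <- rbind(
      data.frame(split = "train", mse = metrics_train$mse,
                 r = metrics_train$r, mae = metrics_train$mae,
                 rmse = metrics_train$rmse, rae_pct = metrics_train$rae,
                 rrse_pct = metrics_train$rrse, n = metrics_train$n),
      data.frame(split = "test", mse = metrics_test$mse,
                 r = metrics_test$r, mae = metrics_test$mae,
                 rmse = metrics_test$rmse, rae_pct = metrics_test$rae,
                 rrse_pct = metrics_test$rrse, n = metrics_test$n))
    utils::write.csv(metr, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics_test$histogram,
                     file.path(out_dir, "error_histogram.csv"),
                     row.names = FALSE)
    if (!is.null(comparison)) {
      utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                       row.names = FALSE)
    }
    manifest <- list(
      config = unclass(config), seed = seed, n_hidden = n_hidden,
      n_samples = nrow(features),
      n_train = length(split$train$y), n_test = length(split$test$y),
      files = c("features.csv", "model.json", "metrics.csv",
                "error_histogram.csv",
                if (!is.null(comparison)) "comparison.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
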