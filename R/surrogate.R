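# Model registry: each entry is list(id, fit(X, y, seed) -> obj,
# predict(obj, X) -> numeric). All models consume the encoded feature
# matrix and are deterministic given the seed.

fit_linear <- function(X, y, seed) {
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xi, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0   # collinear one-hot blocks: pivoted-out columns
  beta
}

#' Default surrogate model registry
#'
#' A representative pluggable set of supervised regressors spanning the
#' families used for tabular response-surface modeling: a constant
#' baseline, linear least squares, ridge and lasso (glmnet), a CART tree
#' (rpart), a random forest (ranger), gradient-boosted trees (xgboost), an
#' RBF support-vector machine (e1071), a Gaussian-process/kernel-ridge
#' regressor (kernlab) and a shallow MLP (nnet). Any named list with the
#' same `fit`/`predict` contract can be passed instead.
#'
#' @return named list of model definitions.
#' @export
model_registry <- function() {
  list(
    constant_baseline = list(
      id = "constant_baseline",
      fit = function(X, y, seed) mean(y),
      predict = function(obj, X) rep(obj, nrow(X))),
    linear = list(
      id = "linear",
      fit = fit_linear,
      predict = function(obj, X) drop(cbind(1, X) %*% obj)),
    ridge = list(
      id = "ridge",
      fit = function(X, y, seed)
        glmnet::glmnet(X, y, alpha = 0, lambda = 0.05),
      predict = function(obj, X) drop(stats::predict(obj, newx = X))),
    lasso = list(
      id = "lasso",
      fit = function(X, y, seed)
        glmnet::glmnet(X, y, alpha = 1, lambda = 0.01),
      predict = function(obj, X) drop(stats::predict(obj, newx = X))),
    cart = list(
      id = "cart",
      fit = function(X, y, seed) {
        df <- as.data.frame(X)
        df$.y <- y
        rpart::rpart(.y ~ ., data = df, method = "anova",
                     control = rpart::rpart.control(cp = 0.005))
      },
      predict = function(obj, X) stats::predict(obj, as.data.frame(X))),
    random_forest = list(
      id = "random_forest",
      fit = function(X, y, seed)
        ranger::ranger(x = X, y = y, num.trees = 300, seed = seed,
                       num.threads = 1,
                       mtry = max(2L, floor(ncol(X) / 2))),
      predict = function(obj, X)
        stats::predict(obj, data = X, num.threads = 1)$predictions),
    gradient_boosting = list(
      id = "gradient_boosting",
      fit = function(X, y, seed)
        xgboost::xgboost(X, y, nrounds = 120, max_depth = 4,
                         learning_rate = 0.15, nthreads = 1,
                         verbosity = 0, seed = seed,
                         objective = "reg:squarederror"),
      predict = function(obj, X) stats::predict(obj, X)),
    svm_rbf = list(
      id = "svm_rbf",
      fit = function(X, y, seed)
        e1071::svm(x = X, y = y, kernel = "radial", cost = 10,
                   gamma = 1 / ncol(X), epsilon = 0.05, scale = FALSE),
      predict = function(obj, X) as.numeric(stats::predict(obj, X))),
    kernel_ridge = list(
      id = "kernel_ridge",
      fit = function(X, y, seed)
        kernlab::gausspr(x = X, y = y, kernel = "rbfdot",
                         kpar = list(sigma = 1 / ncol(X)), var = 0.01,
                         scaled = FALSE),
      predict = function(obj, X) as.numeric(kernlab::predict(obj, X))),
    mlp = list(
      id = "mlp",
      fit = function(X, y, seed) withr::with_seed(seed,
        nnet::nnet(X, y, size = 6, linout = TRUE, decay = 1e-3,
                   maxit = 200, trace = FALSE, MaxNWts = 5000)),
      predict = function(obj, X) as.numeric(stats::predict(obj, X)))
  )
}

#' Reduced registry: forest primary plus cheap references
#'
#' Random forest plus linear and constant baselines. The forest family is
#' consistently the strongest performer on these formulation surfaces, so
#' multi-campaign experiments use this fast subset.
#'
#' @return named list of model definitions.
#' @export
registry_core <- function() {
  model_registry()[c("random_forest", "linear", "constant_baseline")]
}

#' Train every registered model with k-fold CV and select the winner
#'
#' Each registered model is fit under k-fold cross-validation on the
#' encoded features against measured Ct labels; the winner has the highest
#' mean per-fold R-squared, ties broken by lower CV MSE, then registry
#' order. The winner is refit on all data.
#'
#' @param dataset a `ct_dataset` with at least `cv_folds` records.
#' @param space its `ct_space`.
#' @param registry named list of model definitions
#'   (default [model_registry()]).
#' @param cv_folds number of folds (>= 2).
#' @param seed integer seed controlling fold shuffling and model fits.
#' @return an object of class `ct_surrogate` with fields `model_id`,
#'   `cv_r2` (mean), `cv_r2_folds`, `cv_mse`, `train_mse`, `cv_table` (all
#'   candidates) and the fitted state.
#' @export
train_and_select <- function(dataset, space, registry = model_registry(),
                             cv_folds = 5, seed = 1) {
  if (length(registry) == 0) stop("registry must be non-empty")
  X <- dataset_features(dataset, space)
  y <- dataset$records$ct
  n <- length(y)
  if (n < cv_folds || cv_folds < 2)
    stop("need |dataset| >= cv_folds >= 2")
  if (stats::var(y) == 0)
    stop("degenerate labels: zero variance in ct")
  folds <- withr::with_seed(derive_seed(seed, "folds"),
                            sample(rep_len(seq_len(cv_folds), n)))
  results <- lapply(names(registry), function(mid) {
    mdl <- registry[[mid]]
    r2 <- mse <- numeric(cv_folds)
    for (k in seq_len(cv_folds)) {
      tr <- folds != k
      obj <- mdl$fit(X[tr, , drop = FALSE], y[tr],
                     derive_seed(seed, mid, k))
      p <- mdl$predict(obj, X[!tr, , drop = FALSE])
      yt <- y[!tr]
      ss_tot <- sum((yt - mean(yt))^2)
      ss_res <- sum((yt - p)^2)
      r2[k] <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
      mse[k] <- mean((yt - p)^2)
    }
    list(model_id = mid, cv_r2_folds = r2, cv_r2 = mean(r2, na.rm = TRUE),
         cv_mse = mean(mse))
  })
  cv_table <- data.frame(
    model_id = vapply(results, `[[`, character(1), "model_id"),
    cv_r2 = vapply(results, `[[`, numeric(1), "cv_r2"),
    cv_mse = vapply(results, `[[`, numeric(1), "cv_mse"),
    stringsAsFactors = FALSE)
  pick <- order(-cv_table$cv_r2, cv_table$cv_mse,
                seq_len(nrow(cv_table)))[1]
  winner <- registry[[cv_table$model_id[pick]]]
  fitted <- winner$fit(X, y, derive_seed(seed, "final", winner$id))
  train_pred <- winner$predict(fitted, X)
  structure(list(model_id = winner$id, model = winner, fitted = fitted,
                 cv_r2 = cv_table$cv_r2[pick],
                 cv_r2_folds = results[[pick]]$cv_r2_folds,
                 cv_mse = cv_table$cv_mse[pick],
                 train_mse = mean((y - train_pred)^2),
                 cv_table = cv_table, n_train = n,
                 space_id = space$space_id, dim = ncol(X),
                 training_round = NA_integer_),
            class = "ct_surrogate")
}

#' @export
print.ct_surrogate <- function(x, ...) {
  cat("<ct_surrogate> winner:", x$model_id,
      sprintf("| CV R2 %.3f | CV MSE %.4f | train MSE %.4f | n %d\n",
              x$cv_r2, x$cv_mse, x$train_mse, x$n_train))
  invisible(x)
}

#' Predict Ct for schemes with a trained surrogate
#'
#' @param surrogate a `ct_surrogate`.
#' @param schemes list of valid schemes, or an encoded feature matrix.
#' @param space the `ct_space` (required when `schemes` is a list).
#' @param validate validate schemes before encoding.
#' @return numeric vector of predicted Ct values.
#' @export
predict_ct <- function(surrogate, schemes, space = NULL,
                       validate = TRUE) {
  X <- if (is.matrix(schemes)) schemes
       else {
         if (is.null(space)) stop("space required to encode schemes")
         encode_schemes(space, schemes, validate = validate)
       }
  if (ncol(X) != surrogate$dim)
    stop("feature dimension mismatch: got ", ncol(X), ", surrogate has ",
         surrogate$dim)
  as.numeric(surrogate$model$predict(surrogate$fitted, X))
}

#' Track train/CV error across rounds and flag overfitting
#'
#' A round is flagged when the train-to-CV MSE ratio stays below the
#' threshold (train error much smaller than out-of-fold error) for two
#' consecutive rounds.
#'
#' @param history list of `ct_surrogate` objects (one per round) or a
#'   data.frame with columns `train_mse`, `cv_mse`, `cv_r2`.
#' @param ratio_threshold flag threshold on `train_mse / cv_mse`.
#' @return `list(table = per-round data.frame, flagged_rounds = integer)`.
#' @export
overfitting_monitor <- function(history, ratio_threshold = 0.25) {
  if (length(history) == 0) stop("need >= 1 round of history")
  tab <- if (is.data.frame(history)) history
         else data.frame(
           round = seq_along(history),
           model_id = vapply(history, `[[`, character(1), "model_id"),
           train_mse = vapply(history, `[[`, numeric(1), "train_mse"),
           cv_mse = vapply(history, `[[`, numeric(1), "cv_mse"),
           cv_r2 = vapply(history, `[[`, numeric(1), "cv_r2"),
           stringsAsFactors = FALSE)
  if (is.null(tab$round)) tab$round <- seq_len(nrow(tab))
  tab$mse_ratio <- tab$train_mse / tab$cv_mse
  low <- tab$mse_ratio < ratio_threshold
  tab$overfit_flag <- low & c(FALSE, low[-length(low)])
  list(table = tab, flagged_rounds = tab$round[tab$overfit_flag])
}

#' Per-category weighting factors via permutation importance
#'
#' The trained surrogate is probed on a uniform sample of the space; for
#' each category, its whole feature block (all one-hot columns, or the
#' scaled numeric) is jointly permuted and the mean squared change of the
#' surrogate's predictions is recorded. Importances are averaged over
#' `n_perm` permutations and normalized to sum to 1. On an additive
#' surface this estimator is proportional to twice the category's effect
#' variance under the uniform measure, so normalized weights recover
#' planted variance shares.
#'
#' @param surrogate a `ct_surrogate`.
#' @param space its `ct_space`.
#' @param probe_n uniform probe size (>= 500).
#' @param seed integer seed.
#' @param n_perm permutations averaged per category.
#' @return an object of class `ct_weighting`:
#'   `list(weights, method, probe_n)` with weights summing to 1.
#' @export
weighting_factors <- function(surrogate, space, probe_n = 2000, seed = 1,
                              n_perm = 3) {
  if (probe_n < 500) stop("probe_n must be >= 500")
  probe <- sample_schemes(space, probe_n, seed = derive_seed(seed, "probe"))
  X <- encode_schemes(space, probe)
  base <- predict_ct(surrogate, X)
  blocks <- feature_blocks(space)
  nms <- category_names(space)
  imp <- stats::setNames(numeric(length(nms)), nms)
  withr::with_seed(derive_seed(seed, "perm"), {
    for (nm in nms) {
      cols <- which(blocks == nm)
      acc <- 0
      for (r in seq_len(n_perm)) {
        Xp <- X
        idx <- sample(nrow(X))
        Xp[, cols] <- X[idx, cols, drop = FALSE]
        pp <- predict_ct(surrogate, Xp)
        acc <- acc + mean((pp - base)^2)
      }
      imp[nm] <- acc / n_perm
    }
  })
  if (sum(imp) == 0)
    stop("uninformative surrogate: all permutation importances are zero")
  structure(list(weights = imp / sum(imp), method = "permutation",
                 probe_n = probe_n), class = "ct_weighting")
}

#' @export
print.ct_weighting <- function(x, ...) {
  cat("<ct_weighting> method:", x$method, "| probe:", x$probe_n, "\n")
  w <- sort(x$weights, decreasing = TRUE)
  for (nm in names(w)) cat(sprintf("  %-20s %.3f\n", nm, w[nm]))
  invisible(x)
}

#' Post-campaign weighting-factor experiment
#'
#' Closed-loop data concentrate where the optimizer went, so a surrogate
#' trained on campaign data alone is not identifiable over the whole
#' space and its uniform-probe importance is unreliable (the numeric
#' particle-size profile, for instance, is only observed on a few narrow
#' islands). This experiment therefore appends a small diagnostic design
#' — uniformly sampled schemes measured on the platform, by default two
#' 48-scheme batches — to the accumulated campaign data, retrains the
#' full model registry, selects the CV winner and computes the
#' permutation weighting report from it.
#'
#' @param state a completed `ct_campaign`.
#' @param n_diagnostic uniformly sampled schemes to measure and append.
#' @param registry model registry for the weighting surrogate.
#' @param probe_n uniform probe size for the permutation importance.
#' @param seed integer seed.
#' @return a `ct_weighting` report; the selected surrogate is attached as
#'   attribute `"surrogate"`.
#' @export
weighting_experiment <- function(state, n_diagnostic = 96,
                                 registry = model_registry(),
                                 probe_n = 2000, seed = 1) {
  space <- state$space
  dataset <- state$dataset
  if (n_diagnostic > 0) {
    ss <- sample_schemes(space, n_diagnostic,
                         seed = derive_seed(seed, "diag"))
    ct <- vapply(seq_along(ss), function(i)
      mean(measure_ct(state$oracle, ss[[i]],
                      conc = state$requirement$conc, n_rep = 3,
                      regime = "auto",
                      seed = derive_seed(seed, "diagm", i))), numeric(1))
    dataset <- dataset_append(dataset, space, ss, ct = ct, n_rep = 3,
                              conc = state$requirement$conc,
                              round = length(state$rounds) + 1,
                              source = "loop")
  }
  sur <- train_and_select(dataset, space, registry = registry,
                          seed = derive_seed(seed, "wtrain"))
  rep <- weighting_factors(sur, space, probe_n = probe_n, seed = seed)
  attr(rep, "surrogate") <- sur
  rep
}

#' Export a weighting report as CSV and/or JSON
#' @param report a `ct_weighting`.
#' @param csv_path,json_path optional output paths.
#' @return invisibly, the report data.frame.
#' @export
write_weighting_report <- function(report, csv_path = NULL,
                                   json_path = NULL) {
  df <- data.frame(category = names(report$weights),
                   weight = unname(report$weights),
                   stringsAsFactors = FALSE)
  if (!is.null(csv_path))
    utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    writeLines(as.character(to_json_stable(
      list(method = report$method, probe_n = report$probe_n,
           weights = as.list(report$weights)))), json_path)
  invisible(df)
}
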