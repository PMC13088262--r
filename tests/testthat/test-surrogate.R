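# Deterministic linear dataset on the mixed space: ct is affine in the
# encoded features, so the linear model must reach CV R2 = 1.
linear_dataset <- function(n = 40, seed = 1) {
  sp <- mixed_space()
  ss <- sample_schemes(sp, n, seed = seed)
  X <- encode_schemes(sp, ss)
  ct <- 30 + X %*% c(1.5, 0, -1, 2.0)
  dataset_append(new_dataset(sp), sp, ss, ct = as.numeric(ct),
                 round = -1, source = "industrial")
}

test_that("cross-validated selection finds the exactly-linear signal", {
  sp <- mixed_space()
  ds <- linear_dataset()
  reg <- model_registry()[c("linear", "constant_baseline")]
  sur <- train_and_select(ds, sp, registry = reg, cv_folds = 5, seed = 1)
  expect_identical(sur$model_id, "linear")
  expect_equal(sur$cv_r2, 1.0, tolerance = 1e-8)
  expect_lt(sur$train_mse, 1e-12)
  # a single-model registry selects that model
  one <- train_and_select(ds, sp, registry = model_registry()["cart"],
                          cv_folds = 5, seed = 1)
  expect_identical(one$model_id, "cart")
  # degenerate labels are rejected
  flat <- ds
  flat$records$ct <- 30
  expect_error(train_and_select(flat, sp, registry = reg),
               "degenerate labels")
})

test_that("selection is invariant to registry order apart from exact ties", {
  sp <- mixed_space()
  ds <- linear_dataset(n = 60, seed = 2)
  reg <- model_registry()[c("linear", "ridge", "cart",
                            "constant_baseline")]
  a <- train_and_select(ds, sp, registry = reg, seed = 3)
  b <- train_and_select(ds, sp, registry = rev(reg), seed = 3)
  expect_identical(a$model_id, b$model_id)
  expect_equal(a$cv_r2, b$cv_r2)
})

test_that("every registered model fits, predicts finitely and batches consistently", {
  sp <- default_condition_space()
  o <- default_oracle()
  ds <- gen_literature(sp, o, n = 80, seed = 4, target_best = NULL)
  probe <- sample_schemes(sp, 50, seed = 5)
  for (mid in names(model_registry())) {
    sur <- train_and_select(ds, sp, registry = model_registry()[mid],
                            cv_folds = 4, seed = 6)
    p_batch <- predict_ct(sur, probe, space = sp)
    expect_true(all(is.finite(p_batch)), info = mid)
    p_single <- vapply(probe[1:5], function(s)
      predict_ct(sur, list(s), space = sp), numeric(1))
    expect_equal(p_single, p_batch[1:5], tolerance = 1e-8, info = mid)
  }
  expect_error(predict_ct(
    train_and_select(ds, sp, registry = registry_core(), seed = 1),
    matrix(0, 2, 5)), "dimension mismatch")
})

test_that("an interpolating model reproduces its training labels", {
  sp <- tiny_cat_space()
  o <- tiny_cat_oracle()
  ds <- tiny_exhaustive_dataset(o)
  sur <- train_and_select(ds, sp, registry = model_registry()["linear"],
                          cv_folds = 3, seed = 1)
  # 27 rows, 9 free parameters, additive truth: exact interpolation
  preds <- predict_ct(sur, dataset_schemes(ds, sp), space = sp)
  expect_equal(preds, ds$records$ct, tolerance = 1e-8)
})

test_that("tree ensembles win cross-validation on a rugged interacting surface", {
  # surface dominated by sharp pairwise reagent-matching interactions:
  # smooth global regressors underfit it, tree ensembles do not
  sp <- condition_space(lapply(1:6, function(i)
    condition_category(paste0("c", i), "categorical",
                       levels = paste0("l", i, "_", 1:4))),
    space_id = "rugged6")
  withr::with_seed(99, {
    ss <- sample_schemes(sp, 450, seed = 17)
    X <- encode_schemes(sp, ss)
    f <- function(cat, lv) X[, paste0("c", cat, ".l", cat, "_", lv)]
    ct <- 28 + 3 * f(1, 1) * f(2, 2) + 2.5 * f(2, 2) * f(3, 3) +
      2 * f(1, 1) * f(3, 3) * f(4, 1) + 1.5 * f(4, 1) * f(5, 2) +
      2 * f(5, 2) * f(6, 4) + 2.5 * f(6, 4) * f(1, 2) +
      rnorm(450, 0, 0.3)
  })
  ds <- dataset_append(new_dataset(sp), sp, ss, ct = ct, round = -1,
                       source = "literature")
  winners <- vapply(1:5, function(s)
    train_and_select(ds, sp, registry = model_registry(), cv_folds = 5,
                     seed = s)$model_id, character(1))
  modal <- names(sort(table(winners), decreasing = TRUE))[1]
  expect_true(modal %in% c("random_forest", "gradient_boosting"))
})

test_that("overfitting monitor flags two consecutive low train/CV ratios", {
  hist <- data.frame(train_mse = c(0.5, 0.01, 0.01, 0.4),
                     cv_mse = c(0.5, 1.0, 1.0, 0.5),
                     cv_r2 = c(0.9, 0.5, 0.5, 0.9))
  rep <- overfitting_monitor(hist)
  expect_equal(nrow(rep$table), 4)
  expect_equal(rep$flagged_rounds, 3)   # rounds 2 and 3 low; flag at 3
  none <- overfitting_monitor(data.frame(train_mse = c(1, 1),
                                         cv_mse = c(1, 1),
                                         cv_r2 = c(0.5, 0.5)))
  expect_length(none$flagged_rounds, 0)
  expect_error(overfitting_monitor(list()), ">= 1 round")
})

test_that("permutation weighting recovers planted variance shares", {
  sp <- mixed_space()
  o <- calibrate_variance_shares(mixed_oracle(),
                                 c(cat = 0.8, size = 0.2))
  ss <- sample_schemes(sp, 500, seed = 21)
  ct <- vapply(ss, function(s) true_ct(o, s), numeric(1))
  ds <- dataset_append(new_dataset(sp), sp, ss, ct = ct, round = -1,
                       source = "literature")
  # the CV-selected best model is the weighting surrogate
  sur <- train_and_select(ds, sp, registry = model_registry(), seed = 2)
  w <- weighting_factors(sur, sp, probe_n = 2000, seed = 3)
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)
  expect_equal(unname(w$weights[c("cat", "size")]), c(0.8, 0.2),
               tolerance = 0.05 / 0.8)
  expect_error(weighting_factors(sur, sp, probe_n = 100), ">= 500")
})

test_that("irrelevant categories receive negligible weight", {
  sp <- tiny_cat_space()
  o <- tiny_cat_oracle()
  o$cat_penalties$gamma[] <- 0   # gamma has no effect at all
  ss <- sample_schemes(sp, 400, seed = 31)
  ct <- vapply(ss, function(s) true_ct(o, s), numeric(1))
  ds <- dataset_append(new_dataset(sp), sp, ss, ct = ct, round = -1,
                       source = "literature")
  sur <- train_and_select(ds, sp, registry = registry_core(), seed = 4)
  w <- weighting_factors(sur, sp, probe_n = 1000, seed = 5)
  expect_lte(w$weights[["gamma"]], 0.05)
})

test_that("single-category spaces get weight one and flat surrogates error", {
  sp <- condition_space(list(
    condition_category("only", "categorical", levels = c("u", "v", "w"))))
  o <- oracle_params(sp, scheme(only = "v"),
                     cat_penalties = list(only = c(u = 2, v = 0, w = 1)),
                     noise_sigma_auto = 0)
  ss <- sample_schemes(sp, 100, seed = 1)
  ds <- dataset_append(new_dataset(sp), sp, ss,
                       ct = vapply(ss, function(s) true_ct(o, s),
                                   numeric(1)),
                       round = -1, source = "literature")
  sur <- train_and_select(ds, sp, registry = model_registry()["linear"],
                          seed = 1)
  w <- weighting_factors(sur, sp, probe_n = 500, seed = 1)
  expect_equal(unname(w$weights), 1)
  flat <- train_and_select(ds, sp,
                           registry = model_registry()["constant_baseline"],
                           seed = 1)
  expect_error(weighting_factors(flat, sp, probe_n = 500, seed = 1),
               "uninformative")
})
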