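# Shared fixtures: tiny spaces and oracles built in code.

# 3 x 3 x 3 fully categorical space (27 schemes), enumerable.
tiny_cat_space <- function() {
  condition_space(list(
    condition_category("alpha", "categorical", levels = c("a1", "a2", "a3")),
    condition_category("beta", "categorical", levels = c("b1", "b2", "b3")),
    condition_category("gamma", "categorical", levels = c("c1", "c2", "c3"))
  ), space_id = "tiny3x3x3")
}

# Additive oracle on the tiny categorical space, optimum (a2, b1, c3).
tiny_cat_oracle <- function(noise_auto = 0, noise_hitl = 0) {
  sp <- tiny_cat_space()
  oracle_params(
    sp, scheme(alpha = "a2", beta = "b1", gamma = "c3"), ct_opt = 26,
    cat_penalties = list(
      alpha = c(a1 = 2.5, a2 = 0, a3 = 1.0),
      beta = c(b1 = 0, b2 = 0.7, b3 = 1.4),
      gamma = c(c1 = 0.9, c2 = 0.4, c3 = 0)),
    noise_sigma_auto = noise_auto, noise_sigma_hitl = noise_hitl)
}

# Mixed space: one 3-level categorical + one numeric on [200, 1000].
mixed_space <- function() {
  condition_space(list(
    condition_category("cat", "categorical",
                       levels = c("level1", "level2", "level3")),
    condition_category("size", "numeric", range = c(200, 1000),
                       unit = "nm")
  ), space_id = "mixed2d")
}

mixed_oracle <- function(noise_auto = 0) {
  oracle_params(
    mixed_space(), scheme(cat = "level2", size = 600), ct_opt = 26,
    cat_penalties = list(cat = c(level1 = 2, level2 = 0, level3 = 1)),
    num_penalties = list(size = list(opt = 600, coef = 4)),
    noise_sigma_auto = noise_auto, noise_sigma_hitl = 0.4)
}

# Small GA budget for fast tests.
fast_ga <- function(batch_k = 5, ...) {
  ga_config(batch_k = batch_k, population = 60, generations = 15, ...)
}

# Deterministic dataset on the tiny space: all 27 schemes, exact labels.
tiny_exhaustive_dataset <- function(oracle = tiny_cat_oracle()) {
  sp <- oracle$space
  schemes <- enumerate_space(sp)
  ct <- vapply(schemes, function(s) true_ct(oracle, s), numeric(1))
  dataset_append(new_dataset(sp), sp, schemes, ct, conc = 1e5,
                 round = -1, source = "industrial")
}

# Surrogate that predicts the true surface exactly (for GA tests).
exact_surrogate <- function(oracle) {
  sp <- oracle$space
  structure(list(
    model_id = "exact_oracle",
    model = list(id = "exact_oracle",
                 predict = function(obj, X) {
                   vapply(seq_len(nrow(X)), function(i)
                     true_ct(obj, decode_scheme(sp, X[i, ])), numeric(1))
                 }),
    fitted = oracle, cv_r2 = 1, cv_mse = 0, train_mse = 0,
    n_train = 0L, space_id = sp$space_id, dim = space_dim(sp),
    training_round = NA_integer_), class = "ct_surrogate")
}
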