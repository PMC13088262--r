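test_that("fitness scores match their mode definitions", {
  o <- tiny_cat_oracle()
  sur <- exact_surrogate(o)
  s_opt <- o$optimum                       # true Ct 26.0
  s_27 <- scheme(alpha = "a2", beta = "b2", gamma = "c2")  # 26 + 0.7 + 0.4
  expect_equal(fitness(sur, list(s_27), target_ct = 26.6,
                       mode = "closest", space = o$space), 0.5)
  expect_equal(fitness(sur, list(s_opt), target_ct = 26.0,
                       mode = "closest", space = o$space), 0.0)
  mins <- fitness(sur, list(s_opt, s_27), mode = "minimize",
                  space = o$space)
  expect_equal(order(mins),
               order(c(true_ct(o, s_opt), true_ct(o, s_27))))
  expect_error(fitness(sur, list(s_opt), mode = "closest",
                       space = o$space), "target_ct required")
})

brute_top_k <- function(oracle, k, target_ct, mode) {
  ss <- enumerate_space(oracle$space)
  ct <- vapply(ss, function(s) true_ct(oracle, s), numeric(1))
  f <- if (mode == "closest") abs(ct - target_ct) else ct
  enc <- encode_schemes(oracle$space, ss)
  ord <- do.call(order, c(list(f), lapply(seq_len(ncol(enc)),
                                          function(j) enc[, j])))
  ss[ord][seq_len(k)]
}

test_that("proposals equal the exhaustive top-k when diversity and dedup are off", {
  o <- tiny_cat_oracle()
  sur <- exact_surrogate(o)
  cfg <- ga_config(batch_k = 5, min_diversity = 0, dedup = FALSE)
  for (mode in c("minimize", "closest")) {
    got <- propose_batch(sur, o$space, cfg, target_ct = 27.0,
                         mode = mode, seed = 1)
    want <- brute_top_k(o, 5, 27.0, mode)
    expect_identical(lapply(got, scheme_assignments),
                     lapply(want, scheme_assignments))
  }
})

test_that("the pure GA path also recovers the exhaustive top-k on a tiny space", {
  o <- tiny_cat_oracle()
  sur <- exact_surrogate(o)
  # exhaustive shortcut disabled: generous GA budget must find the same set
  cfg <- ga_config(batch_k = 5, population = 120, generations = 25,
                   min_diversity = 0, dedup = FALSE,
                   exhaustive_limit = 0)
  got <- propose_batch(sur, o$space, cfg, target_ct = NULL,
                       mode = "minimize", seed = 11)
  want <- brute_top_k(o, 5, NULL, "minimize")
  expect_identical(lapply(got, scheme_assignments),
                   lapply(want, scheme_assignments))
})

test_that("dedup excludes evaluated schemes and small spaces return all unseen", {
  o <- tiny_cat_oracle()
  sur <- exact_surrogate(o)
  all27 <- enumerate_space(o$space)
  evaluated <- all27[1:24]
  cfg <- ga_config(batch_k = 48, min_diversity = 0, dedup = TRUE)
  got <- propose_batch(sur, o$space, cfg, evaluated = evaluated,
                       mode = "minimize", seed = 2)
  expect_length(got, 3)   # only 3 unseen schemes remain
  got_keys <- vapply(got, ctloop:::scheme_key, character(1))
  seen_keys <- vapply(evaluated, ctloop:::scheme_key, character(1))
  expect_length(intersect(got_keys, seen_keys), 0)
  expect_error(propose_batch(sur, o$space, cfg, evaluated = all27,
                             mode = "minimize", seed = 2),
               "space exhausted")
})

test_that("batches respect the pairwise categorical diversity floor", {
  o <- tiny_cat_oracle()
  sur <- exact_surrogate(o)
  cfg <- ga_config(batch_k = 6, min_diversity = 2, dedup = FALSE)
  got <- propose_batch(sur, o$space, cfg, mode = "minimize", seed = 3)
  for (i in seq_along(got)) for (j in seq_len(i - 1)) {
    expect_gte(ctloop:::hamming_cat(o$space, got[[i]], got[[j]]), 2)
  }
})

test_that("default configuration proposes a full batch of 48 on an ample space", {
  sp <- default_condition_space()
  o <- default_oracle()
  ds <- gen_literature(sp, o, n = 100, seed = 8, target_best = NULL)
  sur <- train_and_select(ds, sp, registry = registry_core(), seed = 8)
  got <- propose_batch(sur, sp, ga_config(generations = 15),
                       target_ct = 26.5, mode = "minimize", seed = 8)
  expect_length(got, 48)
  keys <- vapply(got, ctloop:::scheme_key, character(1))
  expect_false(any(duplicated(keys)))
  for (s in got) expect_true(validate_scheme(sp, s)$ok)
  # reproducible per seed
  again <- propose_batch(sur, sp, ga_config(generations = 15),
                         target_ct = 26.5, mode = "minimize", seed = 8)
  expect_identical(lapply(got, scheme_assignments),
                   lapply(again, scheme_assignments))
})

test_that("rule advisor recombines best marginals and beats the best record on additive surfaces", {
  o <- tiny_cat_oracle()
  sp <- o$space
  ds <- tiny_exhaustive_dataset(o)   # exact labels over the whole space
  sug <- rule_advisor(sp, ds, top_fraction = 1.0, n_suggestions = 3,
                      seed = 1)
  # on a separable additive surface the marginal recombination is optimal
  expect_identical(scheme_assignments(sug[[1]]),
                   scheme_assignments(o$optimum))
  expect_lte(true_ct(o, sug[[1]]), min(ds$records$ct))
  expect_identical(rule_advisor(sp, ds, n_suggestions = 0, seed = 1),
                   list())
  # a dominant unique top record is reproduced among suggestions
  sug2 <- rule_advisor(sp, ds, top_fraction = 1 / 27, n_suggestions = 2,
                       seed = 2)
  keys <- vapply(sug2, ctloop:::scheme_key, character(1))
  expect_true(ctloop:::scheme_key(o$optimum) %in% keys)
  expect_error(rule_advisor(sp, new_dataset(sp)), "non-empty")
  expect_error(rule_advisor(sp, ds, top_fraction = 0), "top_fraction")
})
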