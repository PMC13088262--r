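# Fast campaign setup on the tiny categorical space.
tiny_campaign <- function(target_ct = 26.5, max_rounds = 3, batch_k = 4,
                          noise = 0.02, seed = 1, initial_n = 10,
                          advisor = TRUE) {
  o <- tiny_cat_oracle(noise_auto = noise, noise_hitl = 0.4)
  sp <- o$space
  ss <- sample_schemes(sp, initial_n, seed = derive_seed(seed, "init"))
  ct <- vapply(seq_along(ss), function(i)
    measure_ct(o, ss[[i]], n_rep = 1, regime = "auto",
               seed = derive_seed(seed, "lab", i)) + 2, numeric(1))
  init <- dataset_append(new_dataset(sp), sp, ss, ct = pmax(ct, 27),
                         round = -1, source = "industrial")
  list(req = requirement(target_ct, conc = 1e5, max_rounds = max_rounds,
                         batch_k = batch_k),
       space = sp, oracle = o, init = init, seed = seed,
       scfg = list(registry = "linear", cv_folds = 3),
       ga = fast_ga(batch_k = batch_k))
}

run_tiny <- function(tc, ...) {
  run_campaign(tc$req, tc$space, tc$init, tc$oracle,
               surrogate_cfg = tc$scfg, ga_cfg = tc$ga, seed = tc$seed,
               ...)
}

test_that("a requirement already satisfied by the store ends with zero rounds", {
  tc <- tiny_campaign()
  tc$init$records$ct[3] <- 26.2
  st <- run_tiny(tc)
  expect_identical(st$status, "met")
  expect_length(st$rounds, 0)
  expect_error(best_trajectory(st), "no executed rounds")
})

test_that("a hostile flat oracle exhausts its round budget", {
  sp <- tiny_cat_space()
  # plateau far above target: every scheme measures ~40
  o <- oracle_params(sp, scheme(alpha = "a2", beta = "b1", gamma = "c3"),
                     ct_opt = 40,
                     cat_penalties = list(
                       alpha = c(a1 = 0.1, a2 = 0, a3 = 0.1),
                       beta = c(b1 = 0, b2 = 0.1, b3 = 0.1),
                       gamma = c(c1 = 0.1, c2 = 0.1, c3 = 0)),
                     noise_sigma_auto = 0.02)
  ss <- sample_schemes(sp, 10, seed = 1)
  init <- dataset_append(new_dataset(sp), sp, ss,
                         ct = vapply(ss, function(s) true_ct(o, s),
                                     numeric(1)),
                         round = -1, source = "industrial")
  st <- run_campaign(requirement(26.5, max_rounds = 1, batch_k = 4),
                     sp, init, o,
                     surrogate_cfg = list(registry =
                                            model_registry()["linear"],
                                          cv_folds = 3),
                     ga_cfg = fast_ga(batch_k = 4), seed = 1)
  expect_identical(st$status, "exhausted")
  expect_length(st$rounds, 1)
})

test_that("campaigns are deterministic and their trajectory is monotone", {
  tc <- tiny_campaign(target_ct = 26.05, max_rounds = 3)
  st1 <- run_tiny(tc)
  st2 <- run_tiny(tc)
  expect_identical(st1$status, st2$status)
  expect_identical(st1$dataset$records, st2$dataset$records)
  expect_identical(best_trajectory(st1), best_trajectory(st2))
  expect_true(all(diff(best_trajectory(st1)) <= 0))
  # success implies a stored record at or below target
  if (st1$status == "met")
    expect_true(min(st1$dataset$records$ct) <= 26.05)
  # the store only grows and initial records are untouched
  expect_identical(st1$dataset$records[1:10, ], tc$init$records)
})

test_that("round logs carry surrogate metrics and measured batches", {
  tc <- tiny_campaign(target_ct = 20, max_rounds = 2)  # unreachable
  st <- run_tiny(tc)
  expect_identical(st$status, "exhausted")
  expect_length(st$rounds, 2)
  for (rl in st$rounds) {
    expect_true(rl$model_id %in% names(model_registry()))
    expect_true(is.finite(rl$cv_r2) && rl$cv_mse >= 0)
    expect_equal(length(rl$measured_ct), length(rl$proposals))
    expect_equal(rl$best_ct, min(rl$measured_ct))
  }
  tab <- round_log_table(st)
  expect_equal(tab$round, 1:2)
  mon <- overfitting_monitor(data.frame(
    train_mse = tab$train_mse, cv_mse = tab$cv_mse, cv_r2 = tab$cv_r2))
  expect_equal(nrow(mon$table), 2)
})

test_that("save/load round-trips a campaign losslessly", {
  tc <- tiny_campaign(target_ct = 26.05, max_rounds = 2)
  st <- run_tiny(tc)
  path <- withr::local_tempfile(fileext = ".json")
  save_campaign(st, path)
  back <- load_campaign(path)
  expect_identical(back$status, st$status)
  expect_equal(back$requirement$target_ct, st$requirement$target_ct)
  expect_identical(back$dataset$records[names(back$dataset$records)],
                   st$dataset$records[names(back$dataset$records)])
  expect_equal(best_trajectory(back), best_trajectory(st))
  expect_equal(vapply(back$rounds, `[[`, character(1), "model_id"),
               vapply(st$rounds, `[[`, character(1), "model_id"))
  # corrupt and truncated files fail loudly
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 80), bad)
  expect_error(load_campaign(bad), "corrupt")
  writeLines('{"something": 1}', bad)
  expect_error(load_campaign(bad), "format_version")
})

test_that("a resumed campaign reaches the same final state as an uninterrupted run", {
  tc <- tiny_campaign(target_ct = 26.0, max_rounds = 4)
  full <- run_tiny(tc)
  # replay only the first round, persist, reload, resume
  tc1 <- tc
  tc1$req$max_rounds <- 1
  part <- run_tiny(tc1)
  path <- withr::local_tempfile(fileext = ".json")
  save_campaign(part, path)
  resumed <- resume_campaign(load_campaign(path), max_rounds = 4)
  expect_identical(resumed$status, full$status)
  expect_equal(best_trajectory(resumed), best_trajectory(full))
  expect_equal(resumed$dataset$records$ct, full$dataset$records$ct)
})

test_that("campaign scope pinning keeps out-of-scope categories fixed", {
  tc <- tiny_campaign(target_ct = 20, max_rounds = 1)
  tc$req$categories_in_scope <- c("alpha", "beta")
  st <- run_tiny(tc)
  pin <- st$dataset$records$gamma[which.min(tc$init$records$ct)]
  prop_gamma <- unique(st$dataset$records$gamma[
    st$dataset$records$round == 1])
  expect_identical(prop_gamma, pin)
})

test_that("requirement constructor validates its bounds", {
  expect_error(requirement(-1), "target_ct")
  expect_error(requirement(26.5, max_rounds = 0), "max_rounds")
})
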