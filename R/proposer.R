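#' Genetic-algorithm configuration for batch proposal
#'
#' @param batch_k proposals per round (default 48, the platform batch).
#' @param population GA population size (>= batch_k).
#' @param generations number of GA generations.
#' @param crossover_rate probability a child is produced by uniform
#'   per-category crossover rather than cloning.
#' @param mutation_rate per-category mutation probability (level resample
#'   for categoricals, Gaussian jitter for numerics).
#' @param elitism number of elites copied unchanged each generation.
#' @param min_diversity minimum pairwise Hamming distance on categorical
#'   assignments within a batch (0 disables).
#' @param dedup never propose an already-evaluated scheme.
#' @param exhaustive_limit fully categorical spaces at most this large are
#'   scored exhaustively instead of by GA (0 disables the exact path).
#' @param numeric_jitter mutation sd for numerics, as a fraction of range.
#' @param tournament tournament size for parent selection.
#' @return a `ct_ga_config` list.
#' @export
ga_config <- function(batch_k = 48, population = 192, generations = 40,
                      crossover_rate = 0.9, mutation_rate = 0.15,
                      elitism = 8, min_diversity = 1, dedup = TRUE,
                      exhaustive_limit = 1000, numeric_jitter = 0.1,
                      tournament = 3) {
  stopifnot(batch_k >= 1, population >= batch_k,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(batch_k = batch_k, population = population,
                 generations = generations,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, elitism = elitism,
                 min_diversity = min_diversity, dedup = dedup,
                 exhaustive_limit = exhaustive_limit,
                 numeric_jitter = numeric_jitter, tournament = tournament),
            class = "ct_ga_config")
}

#' Fitness of schemes under a campaign requirement
#'
#' `"closest"` scores the absolute gap between predicted Ct and the target
#' (the platform proposes schemes whose calculated Ct is closest to the
#' requirement); `"minimize"` scores the raw prediction. Lower is better
#' in both modes.
#'
#' @param surrogate a `ct_surrogate`.
#' @param schemes list of valid schemes or encoded matrix.
#' @param target_ct required Ct (ignored for `"minimize"`).
#' @param mode `"closest"` or `"minimize"`.
#' @param space the `ct_space` (needed when schemes is a list).
#' @param validate validate schemes before encoding.
#' @return numeric scores, lower = better.
#' @export
fitness <- function(surrogate, schemes, target_ct = NULL,
                    mode = c("closest", "minimize"), space = NULL,
                    validate = TRUE) {
  mode <- match.arg(mode)
  preds <- predict_ct(surrogate, schemes, space = space,
                      validate = validate)
  if (mode == "minimize") return(preds)
  if (is.null(target_ct)) stop("target_ct required for mode 'closest'")
  abs(preds - target_ct)
}

hamming_cat <- function(space, a, b) {
  aa <- scheme_assignments(a); bb <- scheme_assignments(b)
  sum(vapply(category_names(space), function(nm) {
    if (is_categorical(space$categories[[nm]]))
      !identical(aa[[nm]], bb[[nm]]) else FALSE
  }, logical(1)))
}

# Greedy selection over a fitness-sorted candidate list: drop
# already-evaluated schemes (keys computed lazily) and enforce the
# pairwise categorical diversity floor.
select_batch <- function(space, cands, config, seen = character(0)) {
  kept <- list()
  any_seen <- length(seen) > 0
  for (s in cands) {
    if (length(kept) == config$batch_k) break
    if (any_seen && scheme_key(s) %in% seen) next
    if (config$min_diversity > 0 && length(kept) > 0) {
      d <- vapply(kept, function(k2) hamming_cat(space, s, k2), numeric(1))
      if (any(d < config$min_diversity)) next
    }
    kept[[length(kept) + 1]] <- s
  }
  kept
}

mutate_scheme <- function(space, s, config) {
  a <- scheme_assignments(s)
  for (nm in category_names(space)) {
    if (stats::runif(1) >= config$mutation_rate) next
    cc <- space$categories[[nm]]
    if (is_categorical(cc)) {
      a[[nm]] <- sample(setdiff(cc$levels, a[[nm]]), 1)
    } else {
      w <- diff(cc$range)
      x <- a[[nm]] + stats::rnorm(1, 0, config$numeric_jitter * w)
      a[[nm]] <- min(max(x, cc$range[1]), cc$range[2])
    }
  }
  scheme(assignments = a)
}

crossover_schemes <- function(space, p1, p2) {
  a1 <- scheme_assignments(p1); a2 <- scheme_assignments(p2)
  pickmask <- stats::runif(length(a1)) < 0.5
  a <- a1
  for (i in which(pickmask)) a[[i]] <- a2[[names(a1)[i]]]
  scheme(assignments = a)
}

#' Propose a batch of candidate schemes for the next round
#'
#' Up to `batch_k` unique valid schemes, none already evaluated (when
#' dedup is on), pairwise categorical Hamming distance at least
#' `min_diversity`, sorted by fitness. On fully categorical spaces no
#' larger than `exhaustive_limit` the batch is computed by exact
#' exhaustive scoring; otherwise a genetic algorithm (tournament
#' selection, uniform per-category crossover, per-category mutation,
#' elitism) searches the space, with advisor suggestions injected into the
#' initial population. The whole candidate archive accumulated across
#' generations is ranked, so the returned batch is the best unseen
#' material the search encountered. Ties in fitness are broken
#' lexicographically on the encoded vector for determinism.
#'
#' @param surrogate a fitted `ct_surrogate`.
#' @param space the `ct_space`.
#' @param config a [ga_config()].
#' @param evaluated list of already-evaluated schemes (deduped against).
#' @param advisor_suggestions schemes injected into generation 0.
#' @param target_ct requirement target.
#' @param mode fitness mode, see [fitness()].
#' @param seed integer seed.
#' @return list of schemes sorted by fitness (best first).
#' @export
propose_batch <- function(surrogate, space, config = ga_config(),
                          evaluated = list(), advisor_suggestions = list(),
                          target_ct = NULL, mode = "closest", seed = 1) {
  seen <- if (config$dedup)
    vapply(evaluated, scheme_key, character(1)) else character(0)
  all_cat <- all(vapply(space$categories, is_categorical, logical(1)))
  sizes <- vapply(space$categories, function(c)
    if (is_categorical(c)) length(c$levels) else Inf, numeric(1))
  if (all_cat && config$exhaustive_limit > 0 &&
      prod(sizes) <= config$exhaustive_limit) {
    cands <- enumerate_space(space, limit = config$exhaustive_limit)
  } else {
    cands <- ga_search(surrogate, space, config, advisor_suggestions,
                       target_ct, mode, seed)
  }
  fit <- fitness(surrogate, cands, target_ct = target_ct, mode = mode,
                 space = space, validate = FALSE)
  enc <- encode_schemes(space, cands, validate = FALSE)
  # exact lexicographic tie-break on the encoded vector, column by column
  ord <- do.call(order, c(list(fit), lapply(seq_len(ncol(enc)),
                                            function(j) enc[, j])))
  batch <- select_batch(space, cands[ord], config, seen = seen)
  if (length(batch) == 0)
    stop("space exhausted: no unseen candidate schemes remain")
  batch
}

# GA engine; returns the deduplicated archive of every individual
# encountered (generation-0 population, advisor suggestions, all offspring).
ga_search <- function(surrogate, space, config, advisor_suggestions,
                      target_ct, mode, seed) {
  withr::with_seed(derive_seed(seed, "ga"), {
    pop <- advisor_suggestions
    for (s in pop) assert_valid_scheme(space, s)
    if (length(pop) > config$population)
      pop <- pop[seq_len(config$population)]
    need <- config$population - length(pop)
    if (need > 0) {
      pop <- c(pop, sample_schemes(space, need,
                                   seed = derive_seed(seed, "ga0")))
    }
    archive <- new.env(parent = emptyenv())
    stash <- function(ss) for (s in ss)
      assign(scheme_key(s), s, envir = archive)
    stash(pop)
    popfit <- fitness(surrogate, pop, target_ct = target_ct, mode = mode,
                      space = space, validate = FALSE)
    for (g in seq_len(config$generations)) {
      elite_idx <- order(popfit)[seq_len(min(config$elitism, length(pop)))]
      offspring <- vector("list", config$population - length(elite_idx))
      for (i in seq_along(offspring)) {
        pick <- function() {
          cand <- sample(length(pop), min(config$tournament, length(pop)))
          pop[[cand[which.min(popfit[cand])]]]
        }
        p1 <- pick()
        child <- if (stats::runif(1) < config$crossover_rate)
          crossover_schemes(space, p1, pick()) else p1
        offspring[[i]] <- mutate_scheme(space, child, config)
      }
      pop <- c(pop[elite_idx], offspring)
      stash(offspring)
      popfit <- fitness(surrogate, pop, target_ct = target_ct, mode = mode,
                        space = space, validate = FALSE)
    }
    mget(ls(archive), envir = archive)
  })
}

#' Rule-based advisor: recombine the best marginal sub-conditions
#'
#' A deterministic, non-network stand-in for external parameter
#' suggestions: from the `top_fraction` lowest-Ct records of the dataset,
#' it computes for each category the level with the lowest marginal mean
#' Ct (the median value for numerics) and suggests their recombination,
#' plus seeded recombinations of the top-2 marginal levels. On a
#' separable additive surface the pure marginal recombination is at least
#' as good as the best observed record.
#'
#' @param space the `ct_space`.
#' @param dataset a non-empty `ct_dataset`.
#' @param top_fraction fraction (0, 1] of lowest-Ct records used.
#' @param n_suggestions number of suggestions (0 allowed).
#' @param seed integer seed.
#' @return list of schemes (possibly fewer after dedup).
#' @export
rule_advisor <- function(space, dataset, top_fraction = 0.25,
                         n_suggestions = 4, seed = 1) {
  rec <- dataset$records
  if (nrow(rec) == 0) stop("dataset must be non-empty")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  if (n_suggestions == 0) return(list())
  ntop <- max(1, ceiling(top_fraction * nrow(rec)))
  top <- rec[order(rec$ct)[seq_len(ntop)], , drop = FALSE]
  ranked <- lapply(category_names(space), function(nm) {
    cc <- space$categories[[nm]]
    if (is_categorical(cc)) {
      means <- tapply(top$ct, factor(top[[nm]], levels = cc$levels), mean)
      ord <- order(means, seq_along(means), na.last = TRUE)
      lv <- cc$levels[ord]
      lv[!is.na(means[ord])]
    } else {
      stats::median(top[[nm]])
    }
  })
  names(ranked) <- category_names(space)
  best <- lapply(ranked, function(r) if (is.character(r)) r[1] else r)
  out <- list(scheme(assignments = best))
  extra <- withr::with_seed(derive_seed(seed, "advisor"), {
    lapply(seq_len(max(0, n_suggestions - 1)), function(i) {
      a <- lapply(names(ranked), function(nm) {
        r <- ranked[[nm]]
        if (is.character(r)) sample(r[seq_len(min(2, length(r)))], 1)
        else {
          cc <- space$categories[[nm]]
          x <- r + stats::rnorm(1, 0, 0.05 * diff(cc$range))
          min(max(x, cc$range[1]), cc$range[2])
        }
      })
      names(a) <- names(ranked)
      scheme(assignments = a)
    })
  })
  out <- c(out, extra)
  out[!duplicated(vapply(out, scheme_key, character(1)))]
}
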