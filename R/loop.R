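#' Campaign requirement
#'
#' What the project manager asks for: a Ct target at a fixed template
#' concentration, plus the round/batch budget.
#'
#' @param target_ct required Ct (> 0), e.g. 26.5.
#' @param conc template concentration in copies/mL (default 1e5).
#' @param max_rounds iteration budget (>= 1).
#' @param batch_k schemes proposed and measured per round (default 48).
#' @param categories_in_scope optional character subset of category names
#'   to optimize; out-of-scope categories are pinned to the best initial
#'   record's assignment.
#' @return a `ct_requirement`.
#' @export
requirement <- function(target_ct, conc = 1e5, max_rounds = 9,
                        batch_k = 48, categories_in_scope = NULL) {
  if (target_ct <= 0) stop("target_ct must be > 0")
  if (max_rounds < 1) stop("max_rounds must be >= 1")
  structure(list(target_ct = target_ct, conc = conc,
                 max_rounds = max_rounds, batch_k = batch_k,
                 categories_in_scope = categories_in_scope),
            class = "ct_requirement")
}

new_campaign_state <- function(requirement, space, initial, oracle,
                               surrogate_cfg, ga_cfg, advisor, seed,
                               mode) {
  structure(list(version = "1.0",
                 requirement = requirement, space = space,
                 oracle = oracle, dataset = initial,
                 rounds = list(), status = "running",
                 seed = seed, mode = mode,
                 surrogate_cfg = surrogate_cfg, ga_cfg = ga_cfg,
                 advisor = advisor),
            class = "ct_campaign")
}

#' @export
print.ct_campaign <- function(x, ...) {
  cat("<ct_campaign> status:", x$status, "| rounds:", length(x$rounds),
      "| records:", nrow(x$dataset$records))
  if (length(x$rounds))
    cat(" | best Ct:",
        round(x$rounds[[length(x$rounds)]]$best_so_far, 3))
  cat("\n")
  invisible(x)
}

# The registry field may be "default", "core", a character vector of
# model ids from model_registry(), or a full registry list (the latter is
# not persistable in campaign JSON).
resolve_surrogate_cfg <- function(cfg) {
  cfg <- cfg %||% list()
  reg <- cfg$registry %||% "default"
  if (is.character(reg)) {
    if (length(reg) == 1 && reg == "default") reg <- model_registry()
    else if (length(reg) == 1 && reg == "core") reg <- registry_core()
    else {
      unknown <- setdiff(reg, names(model_registry()))
      if (length(unknown))
        stop("unknown registry model id(s): ",
             paste(unknown, collapse = ", "))
      reg <- model_registry()[reg]
    }
  }
  list(registry = reg, cv_folds = cfg$cv_folds %||% 5)
}

# Pin out-of-scope categories of a proposal to reference assignments.
apply_scope <- function(space, s, scope, pin) {
  if (is.null(scope)) return(s)
  a <- scheme_assignments(s)
  for (nm in setdiff(category_names(space), scope)) a[[nm]] <- pin[[nm]]
  scheme(assignments = a)
}

# Execute one closed-loop round, mutating and returning the state.
campaign_step <- function(state, r) {
  req <- state$requirement
  space <- state$space
  scfg <- resolve_surrogate_cfg(state$surrogate_cfg)
  sur <- train_and_select(state$dataset, space,
                          registry = scfg$registry,
                          cv_folds = scfg$cv_folds,
                          seed = derive_seed(state$seed, "train", r))
  sur$training_round <- r
  suggestions <- list()
  if (isTRUE(state$advisor)) {
    suggestions <- rule_advisor(space, state$dataset,
                                seed = derive_seed(state$seed, "adv", r))
  }
  gcfg <- state$ga_cfg
  gcfg$batch_k <- req$batch_k
  evaluated <- dataset_schemes(state$dataset, space)
  proposals <- propose_batch(sur, space, config = gcfg,
                             evaluated = evaluated,
                             advisor_suggestions = suggestions,
                             target_ct = req$target_ct, mode = state$mode,
                             seed = derive_seed(state$seed, "ga", r))
  if (!is.null(req$categories_in_scope)) {
    pin_row <- state$dataset$records[which.min(state$dataset$records$ct), ]
    pin <- as.list(pin_row[category_names(space)])
    proposals <- lapply(proposals, function(s)
      apply_scope(space, s, req$categories_in_scope, pin))
    proposals <- proposals[!duplicated(vapply(proposals, scheme_key,
                                              character(1)))]
  }
  meas <- lapply(seq_along(proposals), function(i)
    measure_ct(state$oracle, proposals[[i]], conc = req$conc, n_rep = 3,
               regime = "auto",
               seed = derive_seed(state$seed, "measure", r, i)))
  ct_mean <- vapply(meas, mean, numeric(1))
  ct_sd <- vapply(meas, stats::sd, numeric(1))
  state$dataset <- dataset_append(state$dataset, space, proposals,
                                  ct = ct_mean, ct_sd = ct_sd, n_rep = 3,
                                  conc = req$conc, round = r,
                                  source = "loop")
  prev_best <- if (length(state$rounds))
    state$rounds[[length(state$rounds)]]$best_so_far
    else min(state$dataset$records$ct[state$dataset$records$round == -1],
             Inf)
  best_round <- min(ct_mean)
  state$rounds[[r]] <- list(
    round = r, model_id = sur$model_id, cv_r2 = sur$cv_r2,
    cv_mse = sur$cv_mse, train_mse = sur$train_mse,
    proposals = proposals, measured_ct = ct_mean, measured_sd = ct_sd,
    best_ct = best_round, best_so_far = min(prev_best, best_round))
  if (state$rounds[[r]]$best_so_far <= req$target_ct) {
    state$status <- "met"
  } else if (r >= req$max_rounds) {
    state$status <- "exhausted"
  }
  state
}

#' Run a closed-loop optimization campaign
#'
#' Implements the full loop: the initial dataset is first searched for a
#' record already meeting the requirement (0 rounds if found); otherwise
#' each round trains and selects a surrogate on all accumulated data,
#' proposes a batch via the GA (with advisor suggestions injected),
#' measures every proposal as the mean of 3 replicates at the
#' requirement's concentration under the automated noise regime, appends
#' the results, and stops when the best measured mean Ct reaches the
#' target or the round budget is exhausted. Fully reproducible per seed;
#' per-round sub-seeds are derived with [derive_seed()] so an interrupted
#' campaign can be resumed to an identical result.
#'
#' @param requirement a [requirement()].
#' @param space the `ct_space`.
#' @param initial a `ct_dataset` of pre-campaign data.
#' @param oracle the `ct_oracle` standing in for the synthesis/PCR system.
#' @param surrogate_cfg list with `registry` (`"default"`, `"core"` or a
#'   registry list) and `cv_folds`.
#' @param ga_cfg a [ga_config()].
#' @param advisor logical: inject [rule_advisor()] suggestions.
#' @param seed global campaign seed.
#' @param mode fitness mode (`"minimize"` or `"closest"`). A
#'   below-threshold requirement is one-sided, so the default minimizes
#'   predicted Ct; `"closest"` targets the requirement value itself.
#' @param verbose emit per-round progress via `message()`.
#' @return a `ct_campaign` state.
#' @export
run_campaign <- function(requirement, space, initial, oracle,
                         surrogate_cfg = list(registry = "default",
                                              cv_folds = 5),
                         ga_cfg = ga_config(), advisor = TRUE, seed = 1,
                         mode = "minimize", verbose = FALSE) {
  if (initial$space_id != space$space_id)
    stop("initial dataset was built on space '", initial$space_id,
         "', not '", space$space_id, "'")
  state <- new_campaign_state(requirement, space, initial, oracle,
                              surrogate_cfg, ga_cfg, advisor, seed, mode)
  hit <- lookup_meeting_requirement(initial, requirement$target_ct)
  if (!is.null(hit)) {
    state$status <- "met"
    return(state)
  }
  for (r in seq_len(requirement$max_rounds)) {
    state <- campaign_step(state, r)
    if (verbose)
      message(sprintf("round %d: model %s, CV R2 %.3f, best Ct %.3f", r,
                      state$rounds[[r]]$model_id, state$rounds[[r]]$cv_r2,
                      state$rounds[[r]]$best_so_far))
    if (state$status == "met") break
  }
  state
}

#' Resume an interrupted campaign
#'
#' Continues a `"running"` campaign from its last completed round using
#' the same seed-derivation rule, so the final state equals an
#' uninterrupted run.
#'
#' @param state a `ct_campaign`.
#' @param max_rounds optional extended round budget; a campaign that
#'   exhausted a smaller budget becomes `"running"` again.
#' @param verbose emit per-round progress.
#' @return the completed `ct_campaign`.
#' @export
resume_campaign <- function(state, max_rounds = NULL, verbose = FALSE) {
  if (!is.null(max_rounds)) {
    state$requirement$max_rounds <- max_rounds
    if (state$status == "exhausted" && length(state$rounds) < max_rounds)
      state$status <- "running"
  }
  while (state$status == "running" &&
         length(state$rounds) < state$requirement$max_rounds) {
    r <- length(state$rounds) + 1
    state <- campaign_step(state, r)
    if (verbose)
      message(sprintf("round %d: best Ct %.3f", r,
                      state$rounds[[r]]$best_so_far))
  }
  state
}

#' Best-so-far Ct trajectory of a campaign
#'
#' @param state a `ct_campaign` with at least one executed round.
#' @return numeric vector, one value per round, non-increasing.
#' @export
best_trajectory <- function(state) {
  if (length(state$rounds) == 0) stop("campaign has no executed rounds")
  vapply(state$rounds, `[[`, numeric(1), "best_so_far")
}

# ---- persistence -----------------------------------------------------------

serialize_space <- function(space) {
  list(space_id = space$space_id,
       categories = lapply(unname(space$categories), function(c) {
         out <- list(name = c$name, kind = c$kind)
         if (is_categorical(c)) out$levels <- as.list(c$levels)
         else { out$range <- c$range; out$unit <- c$unit }
         out
       }))
}

serialize_oracle <- function(oracle) {
  list(optimum = scheme_assignments(oracle$optimum),
       ct_opt = oracle$ct_opt,
       cat_penalties = lapply(oracle$cat_penalties, as.list),
       num_penalties = oracle$num_penalties,
       interactions = oracle$interactions,
       noise_sigma_auto = oracle$noise_sigma_auto,
       noise_sigma_hitl = oracle$noise_sigma_hitl,
       conc_model = oracle$conc_model)
}

deserialize_oracle <- function(obj, space) {
  oracle_params(space, scheme(assignments = obj$optimum),
                ct_opt = obj$ct_opt,
                cat_penalties = lapply(obj$cat_penalties, unlist),
                num_penalties = obj$num_penalties,
                interactions = lapply(obj$interactions, function(it)
                  list(categories = unlist(it$categories),
                       levels = unlist(it$levels), penalty = it$penalty)),
                noise_sigma_auto = obj$noise_sigma_auto,
                noise_sigma_hitl = obj$noise_sigma_hitl,
                conc_model = obj$conc_model)
}

#' Save / load a campaign state as versioned JSON
#'
#' The file holds everything needed to resume or replay the campaign:
#' requirement, space, oracle parameters, the full experiment store,
#' per-round logs (selected model, CV metrics, proposals, measurements),
#' status, mode and seed. The round trip is lossless.
#'
#' @param state a `ct_campaign`.
#' @param path file path.
#' @export
save_campaign <- function(state, path) {
  rec <- state$dataset$records
  rec <- rec[setdiff(names(rec), "timestamp")]
  # numerics as %.17g strings: bit-exact round trip, so a resumed campaign
  # trains on literally the same labels
  for (cl in names(rec))
    if (is.numeric(rec[[cl]])) rec[[cl]] <- sprintf("%.17g", rec[[cl]])
  payload <- list(
    format_version = "1.0",
    requirement = unclass(state$requirement),
    space = serialize_space(state$space),
    oracle = serialize_oracle(state$oracle),
    dataset = list(space_id = state$dataset$space_id,
                   records = rec),
    rounds = lapply(state$rounds, function(rl) {
      rl$proposals <- lapply(rl$proposals, scheme_assignments)
      rl
    }),
    status = state$status, seed = state$seed, mode = state$mode,
    surrogate_cfg = {
      sc <- state$surrogate_cfg %||% list()
      if (!is.character(sc$registry %||% "default"))
        stop("cannot persist a campaign with a non-named custom registry; ",
             "pass registry as model ids instead")
      list(registry = sc$registry %||% "default",
           cv_folds = sc$cv_folds %||% 5)
    },
    ga_cfg = unclass(state$ga_cfg),
    advisor = state$advisor)
  writeLines(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                           digits = NA, null = "null",
                                           dataframe = "columns")), path)
  invisible(path)
}

#' @rdname save_campaign
#' @return [load_campaign()] returns a `ct_campaign`.
#' @export
load_campaign <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE),
                                     simplifyVector = FALSE),
                  error = function(e)
                    stop("corrupt campaign file '", path, "': ",
                         conditionMessage(e)))
  if (is.null(obj$format_version))
    stop("corrupt campaign file '", path, "': no format_version")
  if (obj$format_version != "1.0")
    stop("campaign file version mismatch: ", obj$format_version)
  space <- space_from_config(obj$space)
  oracle <- deserialize_oracle(obj$oracle, space)
  req <- do.call(requirement, obj$requirement[
    c("target_ct", "conc", "max_rounds", "batch_k")])
  req$categories_in_scope <-
    if (!is.null(obj$requirement$categories_in_scope))
      unlist(obj$requirement$categories_in_scope)
  ds <- new_dataset(space)
  reccols <- obj$dataset$records
  if (length(reccols$ct %||% list())) {
    rec <- as.data.frame(lapply(reccols, unlist),
                         stringsAsFactors = FALSE)
    num_cols <- c("ct", "ct_sd", "n_rep", "conc_copies_per_ml", "round",
                  vapply(space$categories, function(c)
                    if (!is_categorical(c)) c$name else NA_character_,
                    character(1)))
    for (cl in num_cols[!is.na(num_cols)])
      rec[[cl]] <- as.numeric(rec[[cl]])
    rec$timestamp <- NA_character_
    ds$records <- rec[names(ds$records)]
  }
  ga <- do.call(ga_config, obj$ga_cfg[names(formals(ga_config))])
  state <- new_campaign_state(req, space, ds, oracle,
                              obj$surrogate_cfg, ga,
                              isTRUE(obj$advisor), obj$seed, obj$mode)
  state$status <- obj$status
  state$rounds <- lapply(obj$rounds, function(rl) {
    rl$proposals <- lapply(rl$proposals, function(a)
      scheme(assignments = a))
    rl$measured_ct <- unlist(rl$measured_ct)
    rl$measured_sd <- unlist(rl$measured_sd)
    rl
  })
  state
}

#' Export per-round logs as a CSV table
#' @param state a `ct_campaign`.
#' @param path optional file; when given the table is written there.
#' @return data.frame with columns `round`, `model_id`, `cv_r2`,
#'   `cv_mse`, `train_mse`, `best_ct`, `best_so_far`.
#' @export
round_log_table <- function(state, path = NULL) {
  tab <- do.call(rbind, lapply(state$rounds, function(rl)
    data.frame(round = rl$round, model_id = rl$model_id,
               cv_r2 = rl$cv_r2, cv_mse = rl$cv_mse,
               train_mse = rl$train_mse, best_ct = rl$best_ct,
               best_so_far = rl$best_so_far, stringsAsFactors = FALSE)))
  if (is.null(tab))
    tab <- data.frame(round = integer(0), model_id = character(0),
                      cv_r2 = numeric(0), cv_mse = numeric(0),
                      train_mse = numeric(0), best_ct = numeric(0),
                      best_so_far = numeric(0))
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}
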