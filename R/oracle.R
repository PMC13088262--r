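#' Ground-truth Ct response surface parameters
#'
#' The oracle is the synthetic benchmark the closed loop optimizes: a
#' deterministic penalty surface over the condition space plus replicate
#' noise regimes and a template-concentration model. The true Ct of a
#' scheme is `ct_opt` plus additive per-category penalties (zero at the
#' optimal sub-condition) plus a small set of pairwise interaction
#' penalties. It is a benchmark surface, not a mechanistic model of
#' binding or lysis chemistry.
#'
#' @param space the `ct_space` the oracle lives on.
#' @param optimum the scheme at which the surface attains `ct_opt`.
#' @param ct_opt global-minimum Ct (default 26.0).
#' @param cat_penalties named list: per categorical category, a named
#'   numeric vector of penalties (Ct) per level, all `>= 0` and exactly 0
#'   at the optimal level.
#' @param num_penalties named list: per numeric category,
#'   `list(opt =, coef =)` giving the convex quadratic penalty
#'   `coef * ((x - opt) / (max - min))^2`.
#' @param interactions list of
#'   `list(categories = c(a, b), levels = c(la, lb), penalty =)` terms,
#'   each `>= 0`, applied when both assignments match; they never involve
#'   both optimal levels, so the optimum is preserved.
#' @param noise_sigma_auto replicate noise sd (Ct) of the automated
#'   platform regime.
#' @param noise_sigma_hitl replicate noise sd (Ct) of the manual (HITL)
#'   regime.
#' @param conc_model `list(ref_conc =, slope =)`: measured Ct gains
#'   `slope * log10(ref_conc / conc)` away from the reference template
#'   concentration (copies/mL); the default slope `log2(10)` is the
#'   perfect-doubling standard-curve slope.
#' @return an object of class `ct_oracle`.
#' @export
oracle_params <- function(space, optimum, ct_opt = 26.0,
                          cat_penalties, num_penalties = list(),
                          interactions = list(),
                          noise_sigma_auto = 0.065,
                          noise_sigma_hitl = 0.40,
                          conc_model = list(ref_conc = 1e5,
                                            slope = log2(10))) {
  assert_valid_scheme(space, optimum)
  opt <- scheme_assignments(optimum)
  for (nm in names(cat_penalties)) {
    cc <- space$categories[[nm]]
    if (is.null(cc) || !is_categorical(cc))
      stop("cat_penalties for unknown/non-categorical category '", nm, "'")
    p <- cat_penalties[[nm]]
    if (!setequal(names(p), cc$levels))
      stop("penalty table for '", nm, "' must name every level")
    if (any(p < 0)) stop("penalties must be >= 0 ('", nm, "')")
    if (p[[opt[[nm]]]] != 0)
      stop("penalty at the optimal level of '", nm, "' must be 0")
  }
  for (nm in names(num_penalties)) {
    cc <- space$categories[[nm]]
    if (is.null(cc) || is_categorical(cc))
      stop("num_penalties for unknown/non-numeric category '", nm, "'")
    np <- num_penalties[[nm]]
    if (np$coef < 0) stop("numeric penalty coef must be >= 0 ('", nm, "')")
  }
  for (it in interactions) {
    if (it$penalty < 0) stop("interaction penalties must be >= 0")
  }
  if (noise_sigma_auto < 0 || noise_sigma_hitl < 0)
    stop("noise sigmas must be >= 0")
  if (conc_model$slope <= 0) stop("conc_model slope must be > 0")
  structure(list(space = space, optimum = optimum, ct_opt = ct_opt,
                 cat_penalties = cat_penalties,
                 num_penalties = num_penalties,
                 interactions = interactions,
                 noise_sigma_auto = noise_sigma_auto,
                 noise_sigma_hitl = noise_sigma_hitl,
                 conc_model = conc_model),
            class = "ct_oracle")
}

#' @export
print.ct_oracle <- function(x, ...) {
  cat("<ct_oracle> ct_opt =", x$ct_opt,
      "| sigma auto/hitl =", x$noise_sigma_auto, "/", x$noise_sigma_hitl,
      "| slope =", round(x$conc_model$slope, 4),
      "| interactions:", length(x$interactions), "\n")
  invisible(x)
}

oracle_id <- function(oracle) {
  fnv1a(paste(oracle$space$space_id, scheme_key(oracle$optimum),
              oracle$ct_opt,
              paste(unlist(oracle$cat_penalties), collapse = ","),
              paste(unlist(oracle$num_penalties), collapse = ","),
              paste(unlist(oracle$interactions), collapse = ","),
              sep = "|"))
}

#' Default calibrated oracle on the ten-category space
#'
#' Optimum Ct 26.0 at a 390 nm poly-carboxyl particle with a
#' Triton X-100 / GITC / isopropanol / PEG2000 reagent system. Per-category
#' maximum penalties sum to about 16.5 Ct, so poor formulations sit in the
#' high 30s to low 40s. A set of reagent-matching interaction pairs makes
#' the surface non-additive in the way formulation chemistry is: the
#' optimal surfactant, binding alcohol and elution chemistry each perform
#' poorly when paired with the wrong chaotrope, wash or buffer, so
#' one-at-a-time marginals over dispersed data are misleading while the
#' jointly matched combination still attains the global minimum.
#'
#' @param space the space to build on (default [default_condition_space()]).
#' @return a `ct_oracle`.
#' @export
default_oracle <- function(space = default_condition_space()) {
  optimum <- scheme(
    particle_size = 390,
    functional_group = "poly_carboxyl",
    surfactant = "triton_x100",
    salting_out = "ammonium_sulfate",
    buffer = "tris_hcl",
    molecular_crowding = "peg2000",
    chaotrope = "gitc",
    binding_alcohol = "isopropanol",
    wash_composition = "ethanol_80",
    elution_condition = "te_buffer")
  cat_pen <- list(
    functional_group = c(mono_carboxyl = 3.4, di_carboxyl = 1.6,
                         poly_carboxyl = 0),
    surfactant = c(none = 0.8, tween20 = 0.3, triton_x100 = 0, sds = 0.5),
    salting_out = c(nacl = 0.7, ammonium_sulfate = 0, sodium_citrate = 1.3,
                    potassium_acetate = 2.2),
    buffer = c(tris_hcl = 0, hepes = 0.25, phosphate = 0.7, mops = 0.45),
    molecular_crowding = c(none = 2.6, peg2000 = 0, peg4000 = 0.8,
                           peg8000 = 1.2, dextran = 1.9),
    chaotrope = c(gitc = 0, guanidine_hcl = 0.3, urea = 0.6),
    binding_alcohol = c(ethanol = 0.35, isopropanol = 0, butanol = 0.6),
    wash_composition = c(ethanol_70 = 0.25, ethanol_80 = 0,
                         isopropanol_wash = 0.5),
    elution_condition = c(nuclease_free_water = 0.2, te_buffer = 0,
                          low_salt_tris = 0.45))
  num_pen <- list(particle_size = list(opt = 390, coef = 8.0))
  # Reagent-matching interactions: the optimal reagent of one category is
  # penalized when paired with the wrong partner in another, so marginal
  # (one-category-at-a-time) statistics over dispersed data point at the
  # wrong sub-conditions; only jointly matched combinations reach the
  # optimum. All penalties are >= 0 and never fire at the matched optimal
  # pair, so the global minimum stays at the optimum.
  interactions <- list(
    list(categories = c("surfactant", "chaotrope"),
         levels = c("triton_x100", "guanidine_hcl"), penalty = 1.8),
    list(categories = c("surfactant", "chaotrope"),
         levels = c("triton_x100", "urea"), penalty = 1.8),
    list(categories = c("binding_alcohol", "wash_composition"),
         levels = c("isopropanol", "ethanol_70"), penalty = 1.5),
    list(categories = c("binding_alcohol", "wash_composition"),
         levels = c("isopropanol", "isopropanol_wash"), penalty = 1.5),
    list(categories = c("elution_condition", "buffer"),
         levels = c("te_buffer", "hepes"), penalty = 1.2),
    list(categories = c("elution_condition", "buffer"),
         levels = c("te_buffer", "phosphate"), penalty = 1.2),
    list(categories = c("elution_condition", "buffer"),
         levels = c("te_buffer", "mops"), penalty = 1.2),
    list(categories = c("surfactant", "chaotrope"),
         levels = c("sds", "urea"), penalty = 0.8),
    list(categories = c("molecular_crowding", "salting_out"),
         levels = c("none", "nacl"), penalty = 0.6))
  oracle_params(space, optimum, ct_opt = 26.0,
                cat_penalties = cat_pen, num_penalties = num_pen,
                interactions = interactions)
}

# Per-category penalty contributions of one scheme (named numeric vector;
# interactions excluded).
category_contributions <- function(oracle, scheme) {
  a <- scheme_assignments(scheme)
  space <- oracle$space
  vapply(category_names(space), function(nm) {
    cc <- space$categories[[nm]]
    if (is_categorical(cc)) {
      p <- oracle$cat_penalties[[nm]]
      if (is.null(p)) 0 else unname(p[[a[[nm]]]])
    } else {
      np <- oracle$num_penalties[[nm]]
      if (is.null(np)) 0
      else np$coef * ((a[[nm]] - np$opt) / diff(cc$range))^2
    }
  }, numeric(1))
}

interaction_penalty <- function(oracle, scheme) {
  a <- scheme_assignments(scheme)
  tot <- 0
  for (it in oracle$interactions) {
    if (identical(a[[it$categories[1]]], it$levels[1]) &&
        identical(a[[it$categories[2]]], it$levels[2]))
      tot <- tot + it$penalty
  }
  tot
}

#' True (noise-free) Ct of a scheme at reference concentration
#'
#' @param oracle a `ct_oracle`.
#' @param scheme a valid scheme.
#' @return Ct value; the global minimum is `ct_opt`, attained at the
#'   oracle's optimum.
#' @export
true_ct <- function(oracle, scheme) {
  assert_valid_scheme(oracle$space, scheme)
  oracle$ct_opt + sum(category_contributions(oracle, scheme)) +
    interaction_penalty(oracle, scheme)
}

#' Simulate replicate Ct measurements of a scheme
#'
#' Each replicate is
#' `true_ct + slope * log10(ref_conc / conc) + N(0, sigma_regime)`:
#' diluting the template below the reference concentration raises Ct along
#' the standard curve, and the noise regime reflects who ran the
#' experiment (automated platform vs manual HITL).
#'
#' @param oracle a `ct_oracle`.
#' @param scheme a valid scheme.
#' @param conc template concentration in copies/mL (> 0).
#' @param n_rep number of replicates (>= 1).
#' @param regime `"auto"` or `"hitl"`.
#' @param seed integer seed.
#' @return numeric vector of `n_rep` Ct values.
#' @export
measure_ct <- function(oracle, scheme, conc = oracle$conc_model$ref_conc,
                       n_rep = 1, regime = c("auto", "hitl"), seed = 1) {
  regime <- match.arg(regime)
  if (conc <= 0) stop("conc must be > 0")
  if (n_rep < 1) stop("n_rep must be >= 1")
  base <- true_ct(oracle, scheme) +
    oracle$conc_model$slope * log10(oracle$conc_model$ref_conc / conc)
  sigma <- if (regime == "auto") oracle$noise_sigma_auto
           else oracle$noise_sigma_hitl
  withr::with_seed(seed, base + stats::rnorm(n_rep, 0, sigma))
}

# Closed-form per-category variance of the penalty contribution under
# uniform scheme sampling. Categorical: variance of the penalty table under
# the uniform level distribution. Numeric: variance of coef * z^2 with
# z = (x - opt)/width, x ~ U(min, max), via raw moments of z.
category_variances <- function(oracle) {
  space <- oracle$space
  vapply(category_names(space), function(nm) {
    cc <- space$categories[[nm]]
    if (is_categorical(cc)) {
      p <- oracle$cat_penalties[[nm]]
      if (is.null(p)) 0 else mean(p^2) - mean(p)^2
    } else {
      np <- oracle$num_penalties[[nm]]
      if (is.null(np) || np$coef == 0) return(0)
      w <- diff(cc$range)
      a <- (cc$range[1] - np$opt) / w
      b <- (cc$range[2] - np$opt) / w
      m2 <- (b^3 - a^3) / (3 * (b - a))
      m4 <- (b^5 - a^5) / (5 * (b - a))
      np$coef^2 * (m4 - m2^2)
    }
  }, numeric(1))
}

#' Monte-Carlo estimate of per-category effect-variance shares
#'
#' Shares of the total main-effect variance under uniform scheme sampling;
#' this is the planted ground truth that permutation-based weighting
#' factors are expected to recover.
#'
#' @param oracle a `ct_oracle`.
#' @param mc_n Monte-Carlo sample size.
#' @param seed integer seed.
#' @return named numeric vector summing to 1.
#' @export
variance_shares <- function(oracle, mc_n = 20000, seed = 1) {
  schemes <- sample_schemes(oracle$space, mc_n, seed = seed)
  contr <- t(vapply(schemes, function(s) category_contributions(oracle, s),
                    numeric(length(oracle$space$categories))))
  v <- apply(contr, 2, stats::var)
  v / sum(v)
}

#' Rescale penalties so category variance shares match a target profile
#'
#' Per-category penalty magnitudes are rescaled (categorical tables and
#' numeric coefficients scale linearly, so variances scale quadratically)
#' so that each category's share of the total main-effect variance under
#' uniform sampling equals the target. Total main-effect variance is
#' preserved; the optimum location is unchanged (zeros stay zeros).
#' Interactions are zeroed by default so the planted shares are exact; set
#' `zero_interactions = FALSE` to keep them.
#'
#' @param oracle a `ct_oracle`.
#' @param target_shares named numeric vector over all categories, summing
#'   to 1.
#' @param mc_n Monte-Carlo size for the verification step (>= 1000).
#' @param seed seed for the verification sample.
#' @param zero_interactions drop interaction terms (default TRUE).
#' @param tol maximum allowed deviation of MC-verified shares (default
#'   0.02).
#' @return the recalibrated `ct_oracle`, with the MC-verified shares in
#'   attribute `"mc_shares"`.
#' @export
calibrate_variance_shares <- function(oracle, target_shares, mc_n = 20000,
                                      seed = 1, zero_interactions = TRUE,
                                      tol = 0.02) {
  if (mc_n < 1000) stop("mc_n must be >= 1000")
  nms <- category_names(oracle$space)
  if (!setequal(names(target_shares), nms))
    stop("target_shares must name every category of the space")
  target_shares <- target_shares[nms]
  if (abs(sum(target_shares) - 1) > 1e-9)
    stop("target_shares must sum to 1")
  cur <- category_variances(oracle)
  zero_pen <- cur == 0
  if (any(target_shares > 0 & zero_pen))
    stop("target share > 0 for category with all-zero penalties: ",
         paste(nms[target_shares > 0 & zero_pen], collapse = ", "))
  v_tot <- sum(cur)
  scl <- ifelse(cur > 0, sqrt(target_shares * v_tot / cur), 0)
  out <- oracle
  for (nm in names(out$cat_penalties))
    out$cat_penalties[[nm]] <- out$cat_penalties[[nm]] * scl[[nm]]
  for (nm in names(out$num_penalties))
    out$num_penalties[[nm]]$coef <- out$num_penalties[[nm]]$coef * scl[[nm]]
  if (zero_interactions) out$interactions <- list()
  mc <- variance_shares(out, mc_n = mc_n, seed = seed)
  if (max(abs(mc - target_shares)) > tol)
    stop("calibration verification failed: max share deviation ",
         signif(max(abs(mc - target_shares)), 3), " exceeds ", tol)
  attr(out, "mc_shares") <- mc
  out
}

#' Reference data-driven weighting profile
#'
#' The sharp, data-driven importance profile used as the planted truth in
#' weighting-factor recovery experiments: particle size and functional
#' group dominate, molecular crowding and salting out follow, and the
#' remaining six reagent categories share about 10% of the effect
#' variance.
#'
#' @return named numeric vector over the default space's categories,
#'   summing to 1.
#' @export
reference_weight_profile <- function() {
  c(particle_size = 0.357, functional_group = 0.264,
    molecular_crowding = 0.151, salting_out = 0.125,
    surfactant = 0.025, buffer = 0.020, chaotrope = 0.018,
    binding_alcohol = 0.015, wash_composition = 0.013,
    elution_condition = 0.012)
}

#' Convert a Ct value to an extraction-efficiency fraction
#'
#' One PCR cycle corresponds to a factor `base` of template, so a scheme
#' measuring `ct` against a no-loss reference `ct_ref` recovered a
#' fraction `base^-(ct - ct_ref)` of the template, capped at 1.
#'
#' @param ct measured Ct.
#' @param ct_ref reference Ct of lossless extraction.
#' @param base amplification base (> 1, default 2 = perfect doubling).
#' @return efficiency fraction in `(0, 1]`.
#' @export
efficiency_from_ct <- function(ct, ct_ref, base = 2) {
  if (base <= 1) stop("base must be > 1")
  pmin(1.0, base^(-(ct - ct_ref)))
}

#' Simulate a dilution panel for one scheme
#'
#' Measures `n_rep` replicates at each template concentration and reports
#' mean and sd per concentration, ordered by descending concentration. On
#' a noise-free oracle the fitted slope of mean Ct against log10
#' concentration is exactly minus the standard-curve slope.
#'
#' @param oracle a `ct_oracle`.
#' @param scheme a valid scheme.
#' @param concs template concentrations in copies/mL (all > 0).
#' @param n_rep replicates per concentration.
#' @param regime noise regime, `"auto"` or `"hitl"`.
#' @param seed integer seed.
#' @return data.frame with columns `conc_copies_per_ml`, `mean_ct`,
#'   `sd_ct`, `n_rep`.
#' @export
dilution_panel <- function(oracle, scheme,
                           concs = c(1e5, 1e4, 1e3, 5e2),
                           n_rep = 3, regime = "auto", seed = 1) {
  if (length(concs) == 0) stop("concs must be non-empty")
  if (any(concs <= 0)) stop("all concs must be > 0")
  concs <- sort(concs, decreasing = TRUE)
  rows <- lapply(seq_along(concs), function(i) {
    reps <- measure_ct(oracle, scheme, conc = concs[i], n_rep = n_rep,
                       regime = regime,
                       seed = derive_seed(seed, "dilution", i))
    data.frame(conc_copies_per_ml = concs[i], mean_ct = mean(reps),
               sd_ct = if (n_rep > 1) stats::sd(reps) else 0,
               n_rep = n_rep)
  })
  do.call(rbind, rows)
}
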