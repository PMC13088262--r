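#' Replicate consistency score
#'
#' `1 - sigma`, where `sigma` is the sample (n-1 denominator) standard
#' deviation of replicate Ct values across batches. Identical replicates
#' score 1; the score is not clamped, so very noisy panels can score
#' below 0.
#'
#' @param ct_values numeric vector of at least 2 replicate Ct values.
#' @return the consistency score.
#' @export
consistency_score <- function(ct_values) {
  if (length(ct_values) < 2)
    stop("consistency_score needs >= 2 replicate values")
  1 - stats::sd(ct_values)
}

#' PCA projection and compactness of labeled datasets
#'
#' Encodes every record of every dataset, fits a 2-component PCA on the
#' union (centered, unscaled; sign convention: the largest-magnitude
#' loading of each component is positive), and reports per-dataset
#' compactness as the mean Euclidean distance to the dataset's own
#' centroid in the full encoded space (the projection is for
#' visualization only; compactness in 2D would depend on the projection).
#' Constant columns are dropped before the PCA; an error is raised only
#' if every column is constant across the union.
#'
#' @param datasets named list of `ct_dataset` objects (>= 3 records each).
#' @param space their shared `ct_space`.
#' @return `list(projection = data.frame(dataset_label, pc1, pc2),
#'   compactness = named numeric)`.
#' @export
pca_compactness <- function(datasets, space) {
  if (length(datasets) < 1) stop("need >= 1 dataset")
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  feats <- lapply(datasets, function(d) {
    if (nrow(d$records) < 3) stop("each dataset needs >= 3 records")
    if (d$space_id != space$space_id)
      stop("dataset space '", d$space_id, "' does not match '",
           space$space_id, "'")
    dataset_features(d, space)
  })
  union <- do.call(rbind, feats)
  label <- rep(names(datasets), vapply(feats, nrow, integer(1)))
  keep <- apply(union, 2, function(col) stats::var(col) > 0)
  if (!any(keep))
    stop("constant features across the union: PCA is undefined")
  pc <- stats::prcomp(union[, keep, drop = FALSE], center = TRUE,
                      scale. = FALSE, rank. = 2)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(pc$rotation))) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- pc$x
  if (ncol(scores) < 2) scores <- cbind(scores, 0)
  compact <- vapply(feats, function(f) {
    ctr <- colMeans(f)
    mean(sqrt(rowSums((f - matrix(ctr, nrow(f), ncol(f),
                                  byrow = TRUE))^2)))
  }, numeric(1))
  list(projection = data.frame(dataset_label = label,
                               pc1 = scores[, 1], pc2 = scores[, 2],
                               stringsAsFactors = FALSE),
       compactness = compact)
}

#' Align and compare campaign trajectories
#'
#' All states must share the same requirement target and oracle.
#' Trajectories are padded to the longest round count by carrying the
#' last best-so-far value forward; the final gap of each campaign is
#' reported relative to the first.
#'
#' @param states named list of `ct_campaign` states.
#' @return `list(table = data.frame(round, one column per state),
#'   final_best = named numeric, final_gap = named numeric)`.
#' @export
compare_campaigns <- function(states) {
  if (length(states) < 1) stop("need >= 1 campaign state")
  if (is.null(names(states)) || any(!nzchar(names(states))))
    names(states) <- paste0("campaign", seq_along(states))
  targets <- vapply(states, function(s) s$requirement$target_ct,
                    numeric(1))
  if (length(unique(targets)) != 1)
    stop("campaigns have mismatched requirements (target_ct)")
  oids <- vapply(states, function(s) oracle_id(s$oracle), character(1))
  if (length(unique(oids)) != 1)
    stop("campaigns were run on different oracles")
  trajs <- lapply(states, best_trajectory)
  rmax <- max(vapply(trajs, length, integer(1)))
  padded <- lapply(trajs, function(tr)
    c(tr, rep(tr[length(tr)], rmax - length(tr))))
  tab <- data.frame(round = seq_len(rmax))
  for (nm in names(padded)) tab[[nm]] <- padded[[nm]]
  final_best <- vapply(padded, function(tr) tr[rmax], numeric(1))
  list(table = tab, final_best = final_best,
       final_gap = final_best - final_best[[1]])
}

#' Gini coefficient of a nonnegative weight vector
#'
#' Sharpness statistic for weighting profiles: 0 for uniform weights,
#' approaching 1 as a single category dominates.
#'
#' @param w nonnegative numeric vector with positive sum.
#' @return the Gini coefficient.
#' @export
gini_coefficient <- function(w) {
  if (any(w < 0) || sum(w) <= 0)
    stop("weights must be nonnegative with positive sum")
  n <- length(w)
  mean(abs(outer(w, w, "-"))) / (2 * mean(w))
}

#' Compare a weighting report against reference profiles
#'
#' Produces a side-by-side table of the report's weights against each
#' reference profile (absolute differences included) plus a Gini
#' sharpness statistic per profile; a sharper (more discriminating)
#' profile has the larger Gini.
#'
#' @param report a `ct_weighting` from [weighting_factors()].
#' @param references named list of named numeric profiles, each summing
#'   to 1 over the same categories.
#' @return `list(table = data.frame, gini = named numeric)`.
#' @export
weighting_profile_report <- function(report, references = list()) {
  w <- report$weights
  tab <- data.frame(category = names(w), weight = unname(w),
                    stringsAsFactors = FALSE)
  gin <- c(report = gini_coefficient(w))
  for (nm in names(references)) {
    ref <- references[[nm]]
    if (!setequal(names(ref), names(w)))
      stop("reference profile '", nm, "' must cover the same categories")
    ref <- ref[names(w)]
    if (abs(sum(ref) - 1) > 1e-6)
      stop("reference profile '", nm, "' is not normalized")
    tab[[nm]] <- unname(ref)
    tab[[paste0("diff_", nm)]] <- abs(unname(w - ref))
    gin[nm] <- gini_coefficient(ref)
  }
  list(table = tab, gini = gin)
}
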