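#' Define one optimization condition (parameter category)
#'
#' A condition category is one axis of the formulation space: either a
#' categorical factor with named sub-condition levels (e.g. the salting-out
#' reagent) or a bounded numeric parameter (e.g. particle size in nm).
#'
#' @param name identifier, unique within a space.
#' @param kind `"categorical"` or `"numeric"`.
#' @param levels for categorical categories: ordered character vector of at
#'   least two uniquely named levels.
#' @param range for numeric categories: `c(min, max)` with `min < max`.
#' @param unit optional unit string for numeric categories (e.g. `"nm"`).
#' @return an object of class `ct_category`.
#' @export
condition_category <- function(name, kind = c("categorical", "numeric"),
                               levels = NULL, range = NULL, unit = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) < 2)
      stop("categorical category '", name, "' needs >= 2 levels")
    if (anyDuplicated(levels))
      stop("duplicate level names in category '", name, "'")
    if (!is.null(range))
      stop("category '", name, "': exactly one of levels/range may be given")
    out <- list(name = name, kind = kind, levels = as.character(levels))
  } else {
    if (is.null(range) || length(range) != 2 || !is.numeric(range))
      stop("numeric category '", name, "' needs range = c(min, max)")
    if (!(range[1] < range[2]))
      stop("numeric category '", name, "': min must be < max")
    if (!is.null(levels))
      stop("category '", name, "': exactly one of levels/range may be given")
    out <- list(name = name, kind = kind, range = as.numeric(range),
                unit = unit)
  }
  structure(out, class = "ct_category")
}

#' Assemble a condition space from categories
#'
#' @param categories list of [condition_category()] objects with unique names.
#' @param space_id short identifier stored in scheme JSON and datasets.
#' @return an object of class `ct_space`.
#' @export
condition_space <- function(categories, space_id = "custom") {
  stopifnot(length(categories) >= 1)
  nms <- vapply(categories, function(c) c$name, character(1))
  if (anyDuplicated(nms)) stop("category names must be unique")
  names(categories) <- nms
  structure(list(space_id = space_id, categories = categories),
            class = "ct_space")
}

#' @export
print.ct_space <- function(x, ...) {
  cat("<ct_space '", x$space_id, "'> ", length(x$categories),
      " categories, feature dimension ", space_dim(x), "\n", sep = "")
  for (cc in x$categories) {
    if (cc$kind == "categorical") {
      cat("  ", cc$name, ": ", paste(cc$levels, collapse = ", "), "\n",
          sep = "")
    } else {
      cat("  ", cc$name, ": [", cc$range[1], ", ", cc$range[2], "] ",
          cc$unit %||% "", "\n", sep = "")
    }
  }
  invisible(x)
}

#' The default ten-category extraction formulation space
#'
#' Ten axes routinely tuned when a magnetic-nanoparticle nucleic-acid
#' extraction product is formulated: the particle diameter plus nine
#' reagent-choice factors (surface chemistry, lysis, binding, wash and
#' elution chemistry). Feature dimension is 33 (one scaled numeric + 32
#' one-hot columns). Fully overridable: build any space with
#' [condition_space()] or load one with [read_space()].
#'
#' @return a `ct_space` with 10 categories.
#' @export
default_condition_space <- function() {
  condition_space(list(
    condition_category("particle_size", "numeric", range = c(200, 1000),
                       unit = "nm"),
    condition_category("functional_group", "categorical",
                       levels = c("mono_carboxyl", "di_carboxyl",
                                  "poly_carboxyl")),
    condition_category("surfactant", "categorical",
                       levels = c("none", "tween20", "triton_x100", "sds")),
    condition_category("salting_out", "categorical",
                       levels = c("nacl", "ammonium_sulfate",
                                  "sodium_citrate", "potassium_acetate")),
    condition_category("buffer", "categorical",
                       levels = c("tris_hcl", "hepes", "phosphate", "mops")),
    condition_category("molecular_crowding", "categorical",
                       levels = c("none", "peg2000", "peg4000", "peg8000",
                                  "dextran")),
    condition_category("chaotrope", "categorical",
                       levels = c("gitc", "guanidine_hcl", "urea")),
    condition_category("binding_alcohol", "categorical",
                       levels = c("ethanol", "isopropanol", "butanol")),
    condition_category("wash_composition", "categorical",
                       levels = c("ethanol_70", "ethanol_80",
                                  "isopropanol_wash")),
    condition_category("elution_condition", "categorical",
                       levels = c("nuclease_free_water", "te_buffer",
                                  "low_salt_tris"))
  ), space_id = "mnp_extraction_10d")
}

category_names <- function(space) names(space$categories)

is_categorical <- function(cat) cat$kind == "categorical"

#' Feature-vector dimension of a space
#'
#' One column per categorical level (one-hot) plus one per numeric category.
#'
#' @param space a `ct_space`.
#' @return integer dimension.
#' @export
space_dim <- function(space) {
  sum(vapply(space$categories, function(c)
    if (is_categorical(c)) length(c$levels) else 1L, integer(1)))
}

#' Feature column names of the encoding
#' @param space a `ct_space`.
#' @return character vector of length [space_dim()].
#' @export
feature_names <- function(space) {
  unlist(lapply(space$categories, function(c) {
    if (is_categorical(c)) paste0(c$name, ".", c$levels) else c$name
  }), use.names = FALSE)
}

# Map feature column index -> owning category, for block operations.
feature_blocks <- function(space) {
  rep(category_names(space), vapply(space$categories, function(c)
    if (is_categorical(c)) length(c$levels) else 1L, integer(1)))
}

#' Construct a scheme (one complete formulation)
#'
#' A scheme assigns exactly one sub-condition (level or numeric value) to
#' every category of its space. Schemes are plain named lists; an optional
#' label is kept as an attribute.
#'
#' @param ... or `assignments`: named values, one per category.
#' @param assignments named list alternative to `...`.
#' @param label optional identifier.
#' @return a named list of class `ct_scheme`.
#' @export
scheme <- function(..., assignments = NULL, label = NULL) {
  a <- if (is.null(assignments)) list(...) else assignments
  structure(a, class = "ct_scheme", label = label)
}

scheme_assignments <- function(scheme) {
  a <- unclass(scheme)
  attributes(a) <- list(names = names(a))
  a
}

#' Validate a scheme against a space
#'
#' Violations are returned, not raised: missing or unknown categories,
#' undeclared categorical levels, numeric values outside the range.
#'
#' @param space a `ct_space`.
#' @param scheme a scheme (named list).
#' @return `list(ok = logical, violations = character vector)`.
#' @export
validate_scheme <- function(space, scheme) {
  a <- scheme_assignments(scheme)
  v <- character(0)
  missing <- setdiff(category_names(space), names(a))
  if (length(missing))
    v <- c(v, paste0("missing category: ", missing))
  unknown <- setdiff(names(a), category_names(space))
  if (length(unknown))
    v <- c(v, paste0("unknown category: ", unknown))
  if (anyDuplicated(names(a)))
    v <- c(v, "duplicated category assignment")
  for (nm in intersect(names(a), category_names(space))) {
    cc <- space$categories[[nm]]
    val <- a[[nm]]
    if (is_categorical(cc)) {
      if (!is.character(val) || length(val) != 1 || !(val %in% cc$levels))
        v <- c(v, paste0("undeclared level for ", nm, ": ",
                         paste(val, collapse = ",")))
    } else {
      if (!is.numeric(val) || length(val) != 1 || is.na(val)) {
        v <- c(v, paste0("non-numeric value for ", nm))
      } else if (val < cc$range[1] || val > cc$range[2]) {
        v <- c(v, paste0("out of range for ", nm, ": ", val))
      }
    }
  }
  list(ok = length(v) == 0, violations = v)
}

assert_valid_scheme <- function(space, scheme) {
  res <- validate_scheme(space, scheme)
  if (!res$ok)
    stop("invalid scheme: ", paste(res$violations, collapse = "; "))
  invisible(TRUE)
}

#' Encode a scheme as a fixed-length feature vector
#'
#' Categorical categories become one-hot blocks (in declared level order);
#' numeric categories are min-max scaled to `[0, 1]`. The encoding is the
#' representation used for all surrogate training, distance computations
#' and PCA.
#'
#' @param space a `ct_space`.
#' @param scheme a valid scheme.
#' @return named numeric vector of length [space_dim()].
#' @export
encode_scheme <- function(space, scheme) {
  assert_valid_scheme(space, scheme)
  a <- scheme_assignments(scheme)
  out <- numeric(0)
  for (cc in space$categories) {
    if (is_categorical(cc)) {
      hot <- as.numeric(cc$levels == a[[cc$name]])
      out <- c(out, hot)
    } else {
      out <- c(out, (a[[cc$name]] - cc$range[1]) / diff(cc$range))
    }
  }
  names(out) <- feature_names(space)
  out
}

#' Encode a list of schemes as a feature matrix
#'
#' Vectorized across schemes; set `validate = FALSE` for schemes known to
#' be valid by construction (e.g. inside the GA inner loop).
#'
#' @param space a `ct_space`.
#' @param schemes list of valid schemes.
#' @param validate check every scheme first.
#' @return numeric matrix, one row per scheme.
#' @export
encode_schemes <- function(space, schemes, validate = TRUE) {
  n <- length(schemes)
  m <- matrix(0, n, space_dim(space),
              dimnames = list(NULL, feature_names(space)))
  j <- 1
  for (cc in space$categories) {
    vals <- lapply(schemes, `[[`, cc$name)
    if (is_categorical(cc)) {
      v <- unlist(vals, use.names = FALSE)
      idx <- match(v, cc$levels)
      if (validate && anyNA(idx))
        stop("invalid scheme: undeclared level for ", cc$name, ": ",
             v[which(is.na(idx))[1]])
      L <- length(cc$levels)
      m[cbind(seq_len(n), j - 1 + idx)] <- 1
      j <- j + L
    } else {
      x <- as.numeric(unlist(vals, use.names = FALSE))
      if (validate && (anyNA(x) || any(x < cc$range[1]) ||
                       any(x > cc$range[2])))
        stop("invalid scheme: out of range for ", cc$name)
      m[, j] <- (x - cc$range[1]) / diff(cc$range)
      j <- j + 1
    }
  }
  if (validate) {
    lens <- lengths(schemes)
    if (any(lens != length(space$categories)))
      stop("invalid scheme: wrong number of assignments")
  }
  m
}

#' Decode a feature vector back to a scheme
#'
#' Inverse of [encode_scheme()]: the arg-max entry of each one-hot block
#' picks the level, numerics are rescaled back to their range.
#'
#' @param space a `ct_space`.
#' @param features numeric vector of length [space_dim()].
#' @return a `ct_scheme`.
#' @export
decode_scheme <- function(space, features) {
  if (length(features) != space_dim(space))
    stop("feature vector has length ", length(features),
         ", expected ", space_dim(space))
  a <- list()
  i <- 1
  for (cc in space$categories) {
    if (is_categorical(cc)) {
      L <- length(cc$levels)
      block <- features[i:(i + L - 1)]
      a[[cc$name]] <- cc$levels[which.max(block)]
      i <- i + L
    } else {
      a[[cc$name]] <- unname(cc$range[1] + features[i] * diff(cc$range))
      i <- i + 1
    }
  }
  scheme(assignments = a)
}

#' Serialize a scheme to its JSON scheme code
#'
#' The on-disk dialect is this package's own, versioned format: an object
#' with `format_version`, `space_id`, `assignments` and `meta`, serialized
#' with sorted keys and full numeric precision so the same scheme always
#' produces the same bytes.
#'
#' @param scheme a valid scheme.
#' @param space the `ct_space` it belongs to.
#' @param meta optional named list of metadata.
#' @return a JSON string.
#' @export
scheme_to_json <- function(scheme, space, meta = list()) {
  assert_valid_scheme(space, scheme)
  payload <- list(format_version = "1.0",
                  space_id = space$space_id,
                  assignments = scheme_assignments(scheme),
                  meta = meta)
  as.character(to_json_stable(payload))
}

#' Parse a JSON scheme code
#'
#' @param text JSON produced by [scheme_to_json()] (or compatible).
#' @param space the `ct_space` to validate against.
#' @return a `ct_scheme`.
#' @export
scheme_from_json <- function(text, space) {
  obj <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e)
                    stop("scheme JSON parse error: ", conditionMessage(e)))
  if (is.null(obj$assignments))
    stop("scheme JSON parse error: missing 'assignments' field")
  if (!is.null(obj$space_id) && obj$space_id != space$space_id)
    stop("scheme JSON parse error: space_id '", obj$space_id,
         "' does not match space '", space$space_id, "'")
  a <- obj$assignments
  unknown <- setdiff(names(a), category_names(space))
  if (length(unknown))
    stop("scheme JSON parse error: unknown category '", unknown[1],
         "' in assignments")
  s <- scheme(assignments = a)
  assert_valid_scheme(space, s)
  s
}

#' Serialize a batch of schemes as a JSON array of scheme codes
#' @param schemes list of valid schemes.
#' @param space their `ct_space`.
#' @return a JSON array string.
#' @export
schemes_to_json <- function(schemes, space) {
  items <- lapply(schemes, function(s)
    sort_named(list(format_version = "1.0", space_id = space$space_id,
                    assignments = scheme_assignments(s), meta = list())))
  as.character(jsonlite::toJSON(items, auto_unbox = TRUE, digits = NA))
}

#' Sample schemes uniformly over a space
#'
#' Categorical levels uniform over declared levels, numerics uniform over
#' their range; reproducible per seed.
#'
#' @param space a `ct_space`.
#' @param n number of schemes (>= 1).
#' @param seed integer seed.
#' @return list of `ct_scheme`.
#' @export
sample_schemes <- function(space, n, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- lapply(space$categories, function(cc) {
        if (is_categorical(cc)) sample(cc$levels, 1)
        else stats::runif(1, cc$range[1], cc$range[2])
      })
      names(a) <- category_names(space)
      scheme(assignments = a)
    })
  })
}

#' Enumerate every scheme of a fully categorical space
#'
#' Returns the full Cartesian product in lexicographic order: the first
#' category is the most significant digit, levels iterate in declared
#' order.
#'
#' @param space a fully categorical `ct_space`.
#' @param limit refuse to enumerate more than this many schemes.
#' @return list of `ct_scheme`.
#' @export
enumerate_space <- function(space, limit = 10000) {
  if (any(!vapply(space$categories, is_categorical, logical(1))))
    stop("enumerate_space requires a fully categorical space")
  sizes <- vapply(space$categories, function(c) length(c$levels), integer(1))
  total <- prod(sizes)
  if (total > limit)
    stop("space has ", total, " schemes, exceeding limit ", limit)
  # expand.grid varies the first factor fastest; feed reversed levels so the
  # first category is the slowest-varying (lexicographic order).
  grid <- expand.grid(rev(lapply(space$categories, function(c) c$levels)),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]
  names(grid) <- category_names(space)
  lapply(seq_len(nrow(grid)), function(i)
    scheme(assignments = as.list(grid[i, , drop = FALSE])))
}

#' Read / write a space definition file
#'
#' YAML with fields `space_id` and `categories`, each category carrying
#' `name`, `kind`, and `levels` (categorical) or `range` + optional `unit`
#' (numeric).
#'
#' @param path file path.
#' @return [read_space()] returns a `ct_space`.
#' @export
read_space <- function(path) {
  cfg <- yaml::read_yaml(path)
  space_from_config(cfg)
}

space_from_config <- function(cfg) {
  if (is.null(cfg$categories)) stop("space config: missing 'categories'")
  cats <- lapply(cfg$categories, function(c) {
    condition_category(c$name, c$kind,
                       levels = c$levels,
                       range = if (!is.null(c$range)) unlist(c$range),
                       unit = c$unit)
  })
  condition_space(cats, space_id = cfg$space_id %||% "custom")
}

#' @rdname read_space
#' @param space a `ct_space` to write.
#' @export
write_space <- function(space, path) {
  cfg <- list(space_id = space$space_id,
              categories = lapply(unname(space$categories), function(c) {
                out <- list(name = c$name, kind = c$kind)
                if (is_categorical(c)) out$levels <- c$levels
                else {
                  out$range <- c$range
                  if (!is.null(c$unit)) out$unit <- c$unit
                }
                out
              }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
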