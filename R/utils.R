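# Internal helpers: deterministic seed derivation, canonical keys, JSON.

#' Derive a reproducible sub-seed from a base seed and context labels
#'
#' All stochastic components of a campaign draw their seeds through this
#' splitting rule, so a resumed campaign replays exactly the draws of the
#' uninterrupted run. The rule is a polynomial accumulation over the base
#' seed and the context parts (strings hashed by character codes), reduced
#' modulo 2^31 - 1; every intermediate product stays below 2^53 so the
#' arithmetic is exact in doubles.
#'
#' @param seed integer base seed.
#' @param ... integers or strings identifying the consumer (e.g. round
#'   number, "measure", proposal index).
#' @return a single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(list(seed), list(...))
  acc <- 0
  for (p in parts) {
    vals <- if (is.character(p)) utf8ToInt(p) else as.numeric(p)
    for (v in vals) {
      acc <- (acc * 69069 + abs(v) + 1) %% 2147483647
    }
  }
  as.integer(acc)
}

# Canonical string key for a scheme (sorted category names, full-precision
# numerics). Used for dedup sets and archive hashing.
scheme_key <- function(scheme) {
  a <- scheme_assignments(scheme)
  nm <- sort(names(a))
  vals <- vapply(nm, function(n) {
    v <- a[[n]]
    if (is.numeric(v)) sprintf("%.15g", v) else as.character(v)
  }, character(1))
  paste(paste0(nm, "=", vals), collapse = ";")
}

# Recursively sort list names so JSON serialization is byte-stable.
sort_named <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x) > 0) {
    x <- x[order(names(x))]
    lapply(x, sort_named)
  } else if (is.list(x)) {
    lapply(x, sort_named)
  } else {
    x
  }
}

to_json_stable <- function(x) {
  jsonlite::toJSON(sort_named(x), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

# FNV-1a hash of a string, hex-encoded; used for config/oracle identity in
# manifests and campaign comparison. Not cryptographic.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
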