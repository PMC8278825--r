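#' Wrap angles to the half-open interval (-pi, pi]
#'
#' All phase quantities in the package are stored in radians wrapped to
#' `(-pi, pi]`, matching the branch of `atan2()`.
#'
#' @param x numeric vector, matrix or array of angles (radians).
#' @return object of the same shape with every value in `(-pi, pi]`.
#' @export
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
# All randomness in the package flows through this helper so that no
# function mutates the global .Random.seed as a side effect.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a per-item seed from a master seed
#'
#' Deterministic integer mixing used to give every generated map, split or
#' training run its own reproducible stream. The rule is stable across
#' sessions and platforms and the result always fits a 32-bit signed
#' integer.
#'
#' @param master integer master seed.
#' @param ... further nonnegative integer indices (class index, map index,
#'   stage index ...), combined in order.
#' @return a single integer seed in `[1, 2147483629]`.
#' @export
#' @examples
#' derive_seed(11, 2, 5)
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483629
  for (k in idx) {
    s <- (s * 10007 + as.double(k) + 1) %% 2147483629
  }
  as.integer(s + 1)
}

stop_if_not_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

same_shape <- function(...) {
  dims <- lapply(list(...), dim)
  all(vapply(dims[-1], identical, logical(1), dims[[1]]))
}

# Cheap deterministic 32-bit digest of an R object's serialized bytes;
# used only for provenance logging, not for security.
object_hash <- function(x) {
  b <- as.double(as.integer(serialize(x, NULL, version = 2)))
  lane <- (seq_along(b) - 1) %% 8
  sums <- vapply(0:7, function(k) sum(b[lane == k]) %% 2147483629, numeric(1))
  s <- (sum(sums * 31^(0:7)) + length(b)) %% 2147483629
  sprintf("%08x", as.integer(s))
}
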