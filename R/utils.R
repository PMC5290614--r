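# Internal helpers shared across modules.

# Evaluate `expr` under a deterministic RNG state without disturbing the
# caller's stream.  All exported generators/optimizers route their
# randomness through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(base_seed, k) {
  as.integer((as.numeric(base_seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647L)
}

# Strict scalar checks used at module boundaries.
stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Validate a square symmetric nonnegative dissimilarity matrix and return
# it as a plain numeric matrix.
as_delta_matrix <- function(delta) {
  if (inherits(delta, "dist")) delta <- as.matrix(delta)
  if (inherits(delta, "rf_dist")) delta <- delta$delta
  delta <- as.matrix(delta)
  storage.mode(delta) <- "double"
  dimnames(delta) <- NULL
  n <- nrow(delta)
  if (n != ncol(delta)) stop("distance matrix must be square", call. = FALSE)
  if (any(!is.finite(delta))) stop("distance matrix has non-finite entries", call. = FALSE)
  if (any(delta < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (any(abs(delta - t(delta)) > 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(delta) != 0)) stop("distance matrix must have a zero diagonal", call. = FALSE)
  delta
}

# Upper-triangle (i < j) logical mask for an n x n matrix.
upper_mask <- function(n) upper.tri(matrix(0, n, n))
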