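# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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
  force(code)
}

# Deterministic per-stage seed derived from one master seed and a stage name.
# Kept strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Distance-matrix plumbing: all modules exchange stats::dist objects.
as_dist_checked <- function(d, arg = "d") {
  if (inherits(d, "dist")) return(d)
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
      abort(sprintf("`%s` must be a symmetric square matrix or a dist object", arg))
    }
    return(stats::as.dist(d))
  }
  abort(sprintf("`%s` must be a dist object or symmetric matrix", arg))
}

dist_labels <- function(d) {
  lab <- attr(d, "Labels")
  if (is.null(lab)) as.character(seq_len(attr(d, "Size"))) else as.character(lab)
}

check_same_labels <- function(d1, d2, a1 = "d1", a2 = "d2") {
  l1 <- dist_labels(d1)
  l2 <- dist_labels(d2)
  if (length(l1) != length(l2) || !all(l1 == l2)) {
    abort(sprintf("`%s` and `%s` must carry identical labels in identical order", a1, a2))
  }
  invisible(TRUE)
}

# Upper-triangle vector of a dist, in the canonical dist ordering.
utri <- function(d) as.vector(as_dist_checked(d))

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
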