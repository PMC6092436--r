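#' Bray-Curtis dissimilarity between samples
#'
#' Computes pairwise Bray-Curtis dissimilarities between samples from a
#' relative-abundance matrix, after an optional per-entry transform. The
#' default square-root transform damps the influence of dominant OTUs; since
#' the input is already relative, `"hellinger"` coincides with `"sqrt"` and is
#' kept as an explicit synonym for code that thinks in those terms.
#'
#' @param ra relative-abundance (or transformed community) matrix,
#'   OTUs x samples.
#' @param transform `"sqrt"` (default), `"none"`, or `"hellinger"`.
#' @return a `dist` over samples.
#' @export
bray_curtis <- function(ra, transform = c("sqrt", "none", "hellinger")) {
  transform <- match.arg(transform)
  if (ncol(ra) < 2L) abort("need at least 2 samples")
  zero <- colnames(ra)[colSums(ra) == 0]
  if (length(zero)) {
    abort(sprintf("dissimilarity undefined for all-zero sample(s): %s",
                  paste(zero, collapse = ", ")))
  }
  comm <- t(ra)
  if (transform %in% c("sqrt", "hellinger")) comm <- sqrt(comm)
  vegan::vegdist(comm, method = "bray")
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS via vegan's `metaMDS`/`monoMDS`, keeping the best of
#' `n_starts` random starts. Configurations are centred; with a fixed seed the
#' result is reproducible.
#'
#' @param dm a `dist` (or symmetric matrix) of community dissimilarities.
#' @param k number of ordination dimensions.
#' @param n_starts random starts.
#' @param max_iter maximum iterations per start.
#' @param tol stress convergence tolerance.
#' @param seed integer seed.
#' @return an `rs_nmds` object: `coordinates` tibble, `stress`, `converged`,
#'   `n_starts`.
#' @export
nmds <- function(dm, k = 2L, n_starts = 20L, max_iter = 300L, tol = 1e-7,
                 seed = 1L) {
  dm <- as_dist_checked(dm, "dm")
  n <- attr(dm, "Size")
  if (k >= n) abort("k must be smaller than the number of sites")
  fit <- with_seed(seed, suppressWarnings(suppressMessages(
    vegan::metaMDS(dm, k = k, try = n_starts, trymax = n_starts,
                   maxit = max_iter, sfgrmin = 1e-7, smin = 1e-4,
                   sratmax = 1 - tol, trace = 0, autotransform = FALSE,
                   wascores = FALSE)
  )))
  pts <- sweep(fit$points, 2L, colMeans(fit$points))
  coords <- as_tibble(pts, .name_repair = "minimal")
  names(coords) <- paste0("NMDS", seq_len(k))
  coords <- dplyr::bind_cols(tibble(sample_id = dist_labels(dm)), coords)
  structure(
    list(coordinates = coords, stress = fit$stress, n_starts = n_starts,
         converged = isTRUE(fit$converged) || (is.numeric(fit$converged) && fit$converged > 0)),
    class = "rs_nmds"
  )
}

#' @export
print.rs_nmds <- function(x, ...) {
  cat(sprintf("NMDS: %d sites, stress = %.4f, %d starts, converged: %s\n",
              nrow(x$coordinates), x$stress, x$n_starts, x$converged))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of between-group vs within-group distances:
#' `R = (mean rank between - mean rank within) / (M/2)` with `M = n(n-1)/2`,
#' p-value from free permutation of group labels,
#' `(count of permuted R >= observed + 1) / (n_perm + 1)` (vegan's `anosim`).
#'
#' @param dm distance matrix (`dist`).
#' @param groups group label per site, in the order of `dm`'s labels.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return an `rs_anosim` object with `R`, `p_value`, `n_perm`.
#' @export
anosim_test <- function(dm, groups, n_perm = 999L, seed = 1L) {
  dm <- as_dist_checked(dm, "dm")
  groups <- as.factor(groups)
  if (length(groups) != attr(dm, "Size")) abort("groups length must match dm")
  sizes <- table(groups)
  if (length(sizes) < 2L) abort("need at least 2 groups")
  if (any(sizes < 2L)) {
    abort(sprintf("group(s) of size 1: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  fit <- with_seed(seed, vegan::anosim(dm, groups, permutations = n_perm))
  structure(list(R = unname(fit$statistic), p_value = fit$signif,
                 n_perm = n_perm, n_groups = length(sizes)),
            class = "rs_anosim")
}

#' @export
print.rs_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4g (%d permutations, %d groups)\n",
              x$R, x$p_value, x$n_perm, x$n_groups))
  invisible(x)
}

#' Mantel and partial Mantel tests between distance matrices
#'
#' Correlation (Pearson or Spearman) over the upper-triangle pairs of two
#' distance matrices, with significance from simultaneous row/column
#' permutation of one matrix; one-sided (`r >=` observed) by default,
#' matching the distance-decay direction, with a two-sided option. The
#' partial form correlates the residuals of `d1 ~ d3` and `d2 ~ d3`
#' (vegan's `mantel` and `mantel.partial`).
#'
#' @param d1,d2,d3 `dist` objects with identical labels in identical order.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param two_sided use a two-sided p-value on |r|?
#' @return an `rs_mantel` object: `r`, `p_value`, `n_perm`, `method`,
#'   `partial`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 999L, seed = 1L, two_sided = FALSE) {
  method <- match.arg(method)
  d1 <- as_dist_checked(d1, "d1"); d2 <- as_dist_checked(d2, "d2")
  check_same_labels(d1, d2)
  if (var(utri(d1)) == 0 || var(utri(d2)) == 0) {
    warn("a distance matrix has zero variance: Mantel r is undefined")
    return(structure(list(r = NA_real_, p_value = NA_real_, n_perm = n_perm,
                          method = method, partial = FALSE),
                     class = "rs_mantel"))
  }
  fit <- with_seed(seed, vegan::mantel(d1, d2, method = method,
                                       permutations = n_perm))
  p <- fit$signif
  if (two_sided) p <- (sum(abs(fit$perm) >= abs(fit$statistic)) + 1) / (n_perm + 1)
  structure(list(r = unname(fit$statistic), p_value = p, n_perm = n_perm,
                 method = method, partial = FALSE),
            class = "rs_mantel")
}

#' @rdname mantel_test
#' @export
partial_mantel_test <- function(d1, d2, d3, method = c("pearson", "spearman"),
                                n_perm = 999L, seed = 1L) {
  method <- match.arg(method)
  d1 <- as_dist_checked(d1, "d1"); d2 <- as_dist_checked(d2, "d2")
  d3 <- as_dist_checked(d3, "d3")
  check_same_labels(d1, d2)
  check_same_labels(d1, d3, "d1", "d3")
  if (var(utri(d1)) == 0 || var(utri(d2)) == 0 || var(utri(d3)) == 0) {
    warn("a distance matrix has zero variance: partial Mantel r is undefined")
    return(structure(list(r = NA_real_, p_value = NA_real_, n_perm = n_perm,
                          method = method, partial = TRUE),
                     class = "rs_mantel"))
  }
  fit <- with_seed(seed, vegan::mantel.partial(d1, d2, d3, method = method,
                                               permutations = n_perm))
  structure(list(r = unname(fit$statistic), p_value = fit$signif,
                 n_perm = n_perm, method = method, partial = TRUE),
            class = "rs_mantel")
}

#' @export
print.rs_mantel <- function(x, ...) {
  cat(sprintf("%sMantel (%s): r = %.3f, p = %.4g (%d permutations)\n",
              if (x$partial) "Partial " else "", x$method, x$r, x$p_value,
              x$n_perm))
  invisible(x)
}
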