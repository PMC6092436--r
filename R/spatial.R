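EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance matrix between sampling stations
#'
#' Haversine distances in km (mean Earth radius 6371.0088 km) between the
#' coordinates in a metadata table. Sites span several degrees of latitude,
#' where the length of a degree of longitude varies, so great-circle rather
#' than raw-degree Euclidean distance is used throughout.
#'
#' @param meta metadata tibble with `sample_id`, `latitude`, `longitude`.
#' @return a `dist` in km, labelled by sample id.
#' @export
haversine_matrix <- function(meta) {
  meta <- validate_sample_metadata(meta)
  if (!all(c("latitude", "longitude") %in% names(meta))) {
    abort("metadata must carry latitude and longitude")
  }
  bad <- meta$sample_id[is.na(meta$latitude) | is.na(meta$longitude)]
  if (length(bad)) {
    abort(sprintf("missing coordinate for sample(s): %s", paste(bad, collapse = ", ")))
  }
  xy <- cbind(meta$longitude, meta$latitude)
  m <- geosphere::distm(xy, fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM)
  })
  dimnames(m) <- list(meta$sample_id, meta$sample_id)
  stats::as.dist(m)
}

#' Euclidean distance in standardized environmental space
#'
#' Every physico-chemical variable except pH is log(x+1) transformed (to tame
#' right-skewed concentrations), then each variable is z-scored across samples
#' (mixed units make standardization necessary), and Euclidean distance is
#' taken.
#'
#' @param meta metadata tibble.
#' @param vars environmental variable names; default all via [env_vars()].
#' @return a `dist` labelled by sample id.
#' @export
env_distance <- function(meta, vars = NULL) {
  meta <- validate_sample_metadata(meta)
  vars <- vars %||% env_vars(meta)
  miss <- setdiff(vars, names(meta))
  if (length(miss)) abort(sprintf("unknown variable(s): %s", paste(miss, collapse = ", ")))
  x <- as.matrix(meta[, vars, drop = FALSE])
  if (anyNA(x)) abort("missing environmental values among selected samples")
  x <- transform_env(x)
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0  # constant variables carry no signal
  d <- dist(x)
  attr(d, "Labels") <- meta$sample_id
  d
}

# log(x+1) every column except pH (pH is already a log-scale quantity).
transform_env <- function(x) {
  for (j in seq_len(ncol(x))) {
    if (tolower(colnames(x)[j]) == "ph") next
    if (any(x[, j] < 0)) {
      abort(sprintf("negative value in '%s' under log(x+1) transform", colnames(x)[j]))
    }
    x[, j] <- log1p(x[, j])
  }
  x
}

#' Distance-decay of community similarity with geographic distance
#'
#' Mantel correlation (Spearman by default) between community dissimilarity
#' and geographic distance, plus the least-squares slope of dissimilarity on
#' distance for the decay direction.
#'
#' @param comm community dissimilarity (`dist`).
#' @param geo geographic distance (`dist`, km), same labels.
#' @param method correlation type for the Mantel test.
#' @param n_perm,seed permutation settings.
#' @return an `rs_decay` object: the `rs_mantel` fit, `slope` (per km),
#'   `intercept`, and a `pairs` tibble for plotting.
#' @export
distance_decay <- function(comm, geo, method = c("spearman", "pearson"),
                           n_perm = 999L, seed = 1L) {
  method <- match.arg(method)
  comm <- as_dist_checked(comm, "comm"); geo <- as_dist_checked(geo, "geo")
  check_same_labels(comm, geo, "comm", "geo")
  mt <- mantel_test(comm, geo, method = method, n_perm = n_perm, seed = seed)
  x <- utri(geo); y <- utri(comm)
  fit <- lm(y ~ x)
  structure(list(mantel = mt, slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pairs = tibble(geo_km = x, dissimilarity = y)),
            class = "rs_decay")
}

#' @export
print.rs_decay <- function(x, ...) {
  cat(sprintf("Distance-decay: Mantel r = %.3f (p = %.4g), slope = %.3g per km\n",
              x$mantel$r, x$mantel$p_value, x$slope))
  invisible(x)
}

#' PCNM spatial eigenfunctions from a geographic distance matrix
#'
#' Principal coordinates of neighbour matrices: the distance matrix is
#' truncated at `t` (by default the longest edge of its minimum spanning
#' tree), distances beyond the threshold replaced by `4t`, the truncated
#' matrix Gower double-centred (`-0.5 d^2`), and eigen-decomposed.
#' Eigenvectors with positive eigenvalues are retained, scaled by the square
#' root of their eigenvalue, and sign-fixed so the largest-magnitude loading
#' is positive. Axes are numbered in descending eigenvalue order; along a
#' linear transect they look like sinusoids of increasing frequency, which is
#' what makes them useful as broad-to-fine spatial predictors.
#'
#' @param geo geographic `dist` (km).
#' @param truncation `"auto"` (longest MST edge) or a distance in km.
#' @return an `rs_pcnm` object: `vectors` (sites x axes matrix, columns
#'   `PCNM1..`), `eigenvalues`, `truncation`, `n_positive`, `labels`.
#' @export
pcnm_basis <- function(geo, truncation = "auto") {
  geo <- as_dist_checked(geo, "geo")
  n <- attr(geo, "Size")
  if (n < 3L) abort("need at least 3 sites")
  if (max(geo) <= 0) abort("all sites coincident")
  t_km <- if (identical(truncation, "auto")) {
    max(vegan::spantree(geo)$dist)
  } else {
    as.numeric(truncation)
  }
  dm <- as.matrix(geo)
  dstar <- ifelse(dm > t_km, 4 * t_km, dm)
  diag(dstar) <- 0
  a <- -0.5 * dstar^2
  g <- a - outer(rowMeans(a), colMeans(a), "+") + mean(a)  # Gower centring
  eg <- eigen(g, symmetric = TRUE)
  keep <- which(eg$values > 1e-8)
  if (!length(keep)) abort("no positive eigenvalues")
  vec <- eg$vectors[, keep, drop = FALSE]
  vec <- sweep(vec, 2L, sqrt(eg$values[keep]), "*")
  # sign convention: largest-|loading| entry positive, for reproducibility
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  dimnames(vec) <- list(dist_labels(geo), paste0("PCNM", seq_along(keep)))
  structure(list(vectors = vec, eigenvalues = eg$values[keep],
                 truncation = t_km, n_positive = length(keep),
                 labels = dist_labels(geo)),
            class = "rs_pcnm")
}

#' @export
print.rs_pcnm <- function(x, ...) {
  cat(sprintf("PCNM basis: %d sites, %d positive axes, truncation %.2f km\n",
              length(x$labels), x$n_positive, x$truncation))
  invisible(x)
}
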