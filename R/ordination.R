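# Constrained ordination: DCA gating, RDA/CCA, VIF filtering, permutation
# forward selection, permutation ANOVA, and two-component variation
# partitioning on adjusted R2.
#
# Heavy ordination objects (eigenvalues, scores) come from vegan::rda/cca.
# R2 and pseudo-F for the permutation machinery are computed by a direct
# projection engine, which makes forward selection and null calibration cheap;
# the engine is cross-checked against vegan in the test suite.

#' Prepare a community matrix for ordination
#'
#' Converts the package's OTU x sample tables to the samples-in-rows
#' orientation used by ordination, with an optional transform:
#' `"hellinger"` (square root of relative abundance, the standard transform
#' for species RDA), `"sqrt_ra"` (same values; named for code that starts
#' from counts and mirrors the Bray-Curtis transform), or `"none"`.
#'
#' @param cm OTU x sample count (or relative-abundance) matrix.
#' @param transform one of `"hellinger"`, `"sqrt_ra"`, `"none"`.
#' @return samples x OTUs numeric matrix.
#' @export
transform_community <- function(cm, transform = c("hellinger", "sqrt_ra", "none")) {
  transform <- match.arg(transform)
  comm <- t(cm)
  if (transform %in% c("hellinger", "sqrt_ra")) {
    comm <- sqrt(comm / rowSums(comm))
  }
  comm
}

# ---- projection engine ------------------------------------------------------

# Response preparation. For RDA: column-centred community, total SS. For CCA:
# the chi-square standardized contingency residuals Q = (P - rc')/sqrt(rc')
# whose squared norm is the total inertia; regression happens against
# sqrt(rowweight)-scaled centred predictors, the classical CCA algebra.
ord_response <- function(comm, method = c("rda", "cca")) {
  method <- match.arg(method)
  comm <- as.matrix(comm)
  if (method == "rda") {
    y <- scale(comm, center = TRUE, scale = FALSE)
    sstot <- sum(y^2)
    if (sstot <= 1e-12) abort("total variance is zero (identical samples)")
    list(method = "rda", Y = y, sstot = sstot, w = NULL)
  } else {
    if (any(comm < 0)) abort("CCA requires a non-negative community matrix")
    p <- comm / sum(comm)
    r <- rowSums(p); cc <- colSums(p)
    if (any(r == 0)) abort("CCA: sample with zero total")
    keep <- cc > 0
    p <- p[, keep, drop = FALSE]; cc <- cc[keep]
    e <- outer(r, cc)
    q <- (p - e) / sqrt(e)
    sstot <- sum(q^2)
    if (sstot <= 1e-12) abort("total inertia is zero (identical samples)")
    list(method = "cca", Y = q, sstot = sstot, w = r)
  }
}

# Design preparation: centred (weighted for CCA) predictor QR factorization.
ord_design <- function(x, w = NULL) {
  x <- as.matrix(x)
  if (is.null(w)) {
    xc <- scale(x, center = TRUE, scale = FALSE)
  } else {
    xm <- colSums(x * w) / sum(w)
    xc <- sweep(x, 2L, xm) * sqrt(w)
  }
  qr(xc)
}

ord_r2 <- function(resp, qx) {
  sum(qr.fitted(qx, resp$Y)^2) / resp$sstot
}

#' Ezekiel's adjusted R-squared
#'
#' `1 - (1 - R2) (n - 1) / (n - m - 1)`, the adjustment used for linear
#' (RDA-based) explained-variance fractions.
#'
#' @param r2 raw R-squared.
#' @param n number of samples.
#' @param m number of explanatory variables.
#' @export
adjusted_r2 <- function(r2, n, m) {
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

# Permutation-based adjusted R2 for CCA fractions (Peres-Neto et al. 2006):
# the expected inertia captured by random predictors replaces the analytic
# (n-1)/(n-m-1) correction, which does not hold for weighted chi-square space.
adjusted_r2_perm <- function(resp, x, n_perm = 199L, seed = 1L) {
  n <- nrow(resp$Y)
  qx <- ord_design(x, resp$w)
  r2 <- ord_r2(resp, qx)
  perm_r2 <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ord_r2(resp, ord_design(as.matrix(x)[sample(n), , drop = FALSE], resp$w))
  }, numeric(1)))
  1 - (1 - r2) / (1 - mean(perm_r2))
}

# ---- DCA gate ---------------------------------------------------------------

#' DCA gradient lengths and the RDA-vs-CCA recommendation
#'
#' Detrended correspondence analysis (vegan's `decorana`, 26 detrending
#' segments, Hill's nonlinear rescaling); axis lengths are the ranges of the
#' rescaled site scores, in standard deviations of species turnover. A
#' longest gradient under 3 SD means compositional responses are close to
#' linear (use RDA); over 4 SD means full species turnover (use CCA);
#' in between either defensible.
#'
#' @param comm samples x species matrix (see [transform_community()]).
#' @return an `rs_dca` object: `axis_lengths` (4 axes), `longest`,
#'   `recommendation` (`"rda"`, `"cca"`, or `"either"`).
#' @export
dca_gradient_length <- function(comm) {
  comm <- as.matrix(comm)
  if (nrow(comm) < 3L) abort("need at least 3 samples")
  if (sum(colSums(comm) > 0) < 2L) abort("degenerate table: fewer than 2 nonzero OTUs")
  # if every species is confined to a single sample, turnover is complete and
  # the gradient length is effectively unbounded (CA is fully degenerate)
  if (all(colSums(comm > 0) <= 1L)) {
    warn("every OTU occurs in a single sample: gradient length unbounded")
    return(structure(list(axis_lengths = rep(Inf, 4), longest = Inf,
                          recommendation = "cca"), class = "rs_dca"))
  }
  fit <- tryCatch(vegan::decorana(comm), error = function(e) {
    abort(sprintf("detrended correspondence analysis failed: %s",
                  conditionMessage(e)))
  })
  sc <- vegan::scores(fit, display = "sites", choices = 1:4, origin = TRUE)
  len <- apply(sc, 2L, function(z) diff(range(z)))
  if (!all(is.finite(len))) {
    warn("non-finite DCA axis length (near-complete turnover); treating as long gradient")
    len[!is.finite(len)] <- Inf
  }
  longest <- max(len)
  rec <- if (longest < 3) "rda" else if (longest > 4) "cca" else "either"
  structure(list(axis_lengths = unname(len), longest = longest,
                 recommendation = rec),
            class = "rs_dca")
}

#' @export
print.rs_dca <- function(x, ...) {
  cat(sprintf("DCA axis lengths: %s SD; longest %.2f -> %s\n",
              paste(sprintf("%.2f", x$axis_lengths), collapse = ", "),
              x$longest, x$recommendation))
  invisible(x)
}

# ---- RDA / CCA --------------------------------------------------------------

ordination_result <- function(fit, method, comm, x, n_perm, seed) {
  cf <- fit$CCA$tot.chi / fit$tot.chi
  adj <- if (method == "rda") {
    vegan::RsquareAdj(fit)$adj.r.squared
  } else {
    resp <- ord_response(comm, "cca")
    adjusted_r2_perm(resp, x, n_perm = n_perm, seed = seed)
  }
  structure(list(
    method = method,
    eigenvalues = list(constrained = fit$CCA$eig, unconstrained = fit$CA$eig),
    site_scores = vegan::scores(fit, display = "sites", choices = 1:2),
    constrained_fraction = cf,
    adj_r2 = adj,
    selected_vars = colnames(as.matrix(x)),
    vegan_fit = fit
  ), class = "rs_ordination")
}

#' Redundancy analysis (RDA)
#'
#' Linear constrained ordination of a (transformed) community matrix on
#' explanatory variables, via vegan's `rda`. Reports the constrained fraction
#' of variance (raw R2) and Ezekiel's adjusted R2.
#'
#' @param comm samples x species matrix, typically Hellinger-transformed.
#' @param x samples x variables matrix or data frame (VIF-filtered).
#' @return an `rs_ordination` object.
#' @export
rda_fit <- function(comm, x) {
  x <- as.matrix(x)
  if (ncol(x) >= nrow(comm) - 1L) abort("overdetermined: m >= n - 1")
  fit <- vegan::rda(as.matrix(comm) ~ ., data = as.data.frame(x))
  ordination_result(fit, "rda", comm, x, n_perm = 0L, seed = 1L)
}

#' Canonical correspondence analysis (CCA)
#'
#' Unimodal constrained ordination (vegan's `cca`); the community must be
#' non-negative (counts or relative abundances). The adjusted R2 is
#' permutation-based (Peres-Neto), since Ezekiel's correction does not apply
#' to the chi-square metric.
#'
#' @inheritParams rda_fit
#' @param n_perm permutations for the adjusted R2.
#' @param seed integer seed.
#' @export
cca_fit <- function(comm, x, n_perm = 199L, seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) >= nrow(comm) - 1L) abort("overdetermined: m >= n - 1")
  ord_response(comm, "cca")  # validates non-negativity / non-degeneracy
  fit <- vegan::cca(as.matrix(comm) ~ ., data = as.data.frame(x))
  ordination_result(fit, "cca", comm, x, n_perm = n_perm, seed = seed)
}

#' @export
print.rs_ordination <- function(x, ...) {
  cat(sprintf("%s: constrained %.1f%% (adj R2 = %.3f) with %d variable(s)\n",
              toupper(x$method), 100 * x$constrained_fraction, x$adj_r2,
              length(x$selected_vars)))
  invisible(x)
}

# ---- VIF filtering ----------------------------------------------------------

#' Iterative variance-inflation-factor filtering
#'
#' Repeatedly drops the predictor with the highest VIF
#' (`1 / (1 - R2_j)` from regressing it on the remaining predictors, with
#' intercept) while any VIF exceeds `threshold`. Perfectly collinear columns
#' have infinite VIF and go first; ties are broken by dropping the later
#' column.
#'
#' @param x samples x variables matrix or data frame.
#' @param threshold VIF ceiling (default 20).
#' @return list: `x` (reduced matrix), `dropped` (tibble variable/vif),
#'   `vif` (named vector of survivors' VIFs).
#' @export
vif_filter <- function(x, threshold = 20) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) < 2L) abort("need at least 2 columns")
  dropped <- tibble(variable = character(), vif = numeric())
  repeat {
    v <- vif_values(x)
    if (all(v <= threshold)) break
    j <- max(which(v == max(v)))  # later column loses on ties
    dropped <- dplyr::bind_rows(dropped,
                                tibble(variable = colnames(x)[j], vif = v[j]))
    x <- x[, -j, drop = FALSE]
    if (ncol(x) == 1L) break
  }
  list(x = x, dropped = dropped,
       vif = if (ncol(x) >= 2L) vif_values(x) else setNames(1, colnames(x)))
}

vif_values <- function(x) {
  n <- ncol(x)
  vapply(seq_len(n), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(x))
}

# ---- permutation ANOVA ------------------------------------------------------

# Pseudo-F of adding X_test given X_cond (possibly NULL), in the projection
# engine's space; used by both permutation_anova and forward_select.
pseudo_f <- function(resp, q_full, q_red, m_test, m_cond, ymat = NULL) {
  y <- ymat %||% resp$Y
  n <- nrow(y)
  sstot <- sum(y^2)
  r2f <- sum(qr.fitted(q_full, y)^2) / sstot
  r2r <- if (is.null(q_red)) 0 else sum(qr.fitted(q_red, y)^2) / sstot
  ((r2f - r2r) / m_test) / ((1 - r2f) / (n - 1 - m_test - m_cond))
}

#' Permutation ANOVA for a (partial) constrained ordination
#'
#' Tests the pseudo-F of the constraint `x` — optionally after partialling
#' out `condition` — by permutation. Partial tests permute the residuals of
#' the reduced (condition-only) model (Freedman-Lane); the marginal test
#' permutes response rows. `p = (count of permuted F >= observed + 1) /
#' (n_perm + 1)`.
#'
#' @param comm samples x species matrix.
#' @param x explanatory matrix under test.
#' @param condition conditioning matrix or `NULL`.
#' @param method `"rda"` or `"cca"`.
#' @param n_perm,seed permutation settings.
#' @return list: `f`, `p_value`, `n_perm`.
#' @export
permutation_anova <- function(comm, x, condition = NULL,
                              method = c("rda", "cca"), n_perm = 999L,
                              seed = 1L) {
  method <- match.arg(method)
  resp <- ord_response(comm, method)
  x <- as.matrix(x)
  n <- nrow(resp$Y)
  m_cond <- if (is.null(condition)) 0L else ncol(as.matrix(condition))
  x_full <- if (is.null(condition)) x else cbind(as.matrix(condition), x)
  q_full <- ord_design(x_full, resp$w)
  q_red <- if (is.null(condition)) NULL else ord_design(as.matrix(condition), resp$w)
  f_obs <- pseudo_f(resp, q_full, q_red, ncol(x), m_cond)
  if (is.null(condition)) {
    fitted_red <- matrix(0, n, ncol(resp$Y))
    resid_red <- resp$Y
  } else {
    fitted_red <- qr.fitted(q_red, resp$Y)
    resid_red <- resp$Y - fitted_red
  }
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ystar <- fitted_red + resid_red[sample(n), , drop = FALSE]
    pseudo_f(resp, q_full, q_red, ncol(x), m_cond, ymat = ystar)
  }, numeric(1)))
  list(f = f_obs, p_value = (sum(f_perm >= f_obs) + 1) / (n_perm + 1),
       n_perm = n_perm)
}

# ---- forward selection ------------------------------------------------------

#' Permutation forward selection of explanatory variables
#'
#' At each step the unselected variable with the largest partial pseudo-F
#' (given the already-selected set) is tested by permutation of the
#' reduced-model residuals; it enters if its p-value is below `alpha`, and
#' selection stops when the best candidate fails. Expects a VIF-filtered
#' predictor matrix (perfect collinearity is an error). An empty selection is
#' a legitimate outcome, not an error.
#'
#' @param comm samples x species matrix.
#' @param x candidate predictors (samples x variables, VIF-filtered).
#' @param method `"rda"` or `"cca"`.
#' @param alpha entry threshold on the permutation p-value.
#' @param n_perm,seed permutation settings.
#' @return an `rs_forward` object: `selected` (names in entry order),
#'   `trace` (tibble step/variable/pseudo_f/p_value/cum_adj_r2).
#' @export
forward_select <- function(comm, x, method = c("rda", "cca"), alpha = 0.05,
                           n_perm = 199L, seed = 1L) {
  method <- match.arg(method)
  resp <- ord_response(comm, method)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  n <- nrow(resp$Y)
  if (qr(cbind(1, x))$rank < ncol(x) + 1L) {
    abort("collinear predictors: VIF contract violated (run vif_filter first)")
  }
  selected <- character()
  trace <- tibble(step = integer(), variable = character(),
                  pseudo_f = numeric(), p_value = numeric(),
                  cum_adj_r2 = numeric())
  seed_i <- seed
  repeat {
    candidates <- setdiff(colnames(x), selected)
    if (!length(candidates) || length(selected) >= n - 3L) break
    x_sel <- if (length(selected)) x[, selected, drop = FALSE] else NULL
    q_red <- if (is.null(x_sel)) NULL else ord_design(x_sel, resp$w)
    f_cand <- vapply(candidates, function(v) {
      q_full <- ord_design(cbind(x_sel, x[, v, drop = FALSE]), resp$w)
      pseudo_f(resp, q_full, q_red, 1L, length(selected))
    }, numeric(1))
    best <- candidates[which.max(f_cand)]
    q_full <- ord_design(cbind(x_sel, x[, best, drop = FALSE]), resp$w)
    if (is.null(x_sel)) {
      fitted_red <- matrix(0, n, ncol(resp$Y)); resid_red <- resp$Y
    } else {
      fitted_red <- qr.fitted(q_red, resp$Y); resid_red <- resp$Y - fitted_red
    }
    f_obs <- f_cand[best]
    seed_i <- derive_seed(seed_i, best)
    f_perm <- with_seed(seed_i, vapply(seq_len(n_perm), function(i) {
      ystar <- fitted_red + resid_red[sample(n), , drop = FALSE]
      pseudo_f(resp, q_full, q_red, 1L, length(selected), ymat = ystar)
    }, numeric(1)))
    p <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)
    if (p >= alpha) break
    selected <- c(selected, best)
    r2_cum <- ord_r2(resp, ord_design(x[, selected, drop = FALSE], resp$w))
    trace <- dplyr::bind_rows(trace, tibble(
      step = length(selected), variable = best, pseudo_f = unname(f_obs),
      p_value = p, cum_adj_r2 = adjusted_r2(r2_cum, n, length(selected))
    ))
  }
  if (!length(selected)) message("forward selection: no variable significant at step 1")
  structure(list(selected = selected, trace = trace, method = method,
                 alpha = alpha, n_perm = n_perm),
            class = "rs_forward")
}

#' @export
print.rs_forward <- function(x, ...) {
  cat(sprintf("Forward selection (%s, alpha = %.2f): %d variable(s) selected\n",
              x$method, x$alpha, length(x$selected)))
  if (nrow(x$trace)) print(x$trace)
  invisible(x)
}

# ---- variation partitioning -------------------------------------------------

#' Two-component variation partitioning between environment and space
#'
#' Fits three constrained models — environment alone (E), space alone (S),
#' and both (E union S) — converts each raw R2 to an adjusted R2 (Ezekiel for
#' RDA; permutation-based for CCA), and decomposes:
#' pure environment `E|S = adj(ES) - adj(S)`, pure space
#' `S|E = adj(ES) - adj(E)`, shared `adj(E) + adj(S) - adj(ES)`, residual
#' `1 - adj(ES)`. Negative fractions are reported as-is. The pure fractions
#' get permutation ANOVA p-values from partial models.
#'
#' @param comm samples x species matrix.
#' @param x_env,x_spa explanatory matrices (typically forward-selected).
#' @param method `"rda"` (default; the adjusted-R2 partition is defined for
#'   the linear engine) or `"cca"`.
#' @param n_perm,seed permutation settings; `n_perm = 0` skips the pure-
#'   fraction significance tests (their p-values come back `NA`).
#' @return an `rs_varpart` object.
#' @export
variation_partition <- function(comm, x_env, x_spa, method = c("rda", "cca"),
                                n_perm = 999L, seed = 1L) {
  method <- match.arg(method)
  x_env <- as.matrix(x_env); x_spa <- as.matrix(x_spa)
  if (!ncol(x_env) || !ncol(x_spa)) abort("both explanatory sets must be non-empty")
  resp <- ord_response(comm, method)
  n <- nrow(resp$Y)
  r2 <- function(x) ord_r2(resp, ord_design(x, resp$w))
  r2_e <- r2(x_env); r2_s <- r2(x_spa); r2_es <- r2(cbind(x_env, x_spa))
  adj <- if (method == "rda") {
    c(E = adjusted_r2(r2_e, n, ncol(x_env)),
      S = adjusted_r2(r2_s, n, ncol(x_spa)),
      ES = adjusted_r2(r2_es, n, ncol(x_env) + ncol(x_spa)))
  } else {
    c(E = adjusted_r2_perm(resp, x_env, n_perm = min(n_perm, 199L), seed = derive_seed(seed, "adjE")),
      S = adjusted_r2_perm(resp, x_spa, n_perm = min(n_perm, 199L), seed = derive_seed(seed, "adjS")),
      ES = adjusted_r2_perm(resp, cbind(x_env, x_spa), n_perm = min(n_perm, 199L),
                            seed = derive_seed(seed, "adjES")))
  }
  res <- varpart_fractions(adj[["E"]], adj[["S"]], adj[["ES"]])
  if (n_perm > 0) {
    pe <- permutation_anova(comm, x_env, condition = x_spa, method = method,
                            n_perm = n_perm, seed = derive_seed(seed, "pureE"))
    ps <- permutation_anova(comm, x_spa, condition = x_env, method = method,
                            n_perm = n_perm, seed = derive_seed(seed, "pureS"))
  } else {
    pe <- ps <- list(p_value = NA_real_)
  }
  structure(c(res, list(p_pure_env = pe$p_value, p_pure_spatial = ps$p_value,
                        method = method, raw_r2 = c(E = r2_e, S = r2_s, ES = r2_es))),
            class = "rs_varpart")
}

#' @rdname variation_partition
#' @param adj_e,adj_s,adj_es adjusted R2 of the environment-only, space-only
#'   and joint models; exposed so the arithmetic identities can be used on
#'   externally obtained fractions.
#' @export
varpart_fractions <- function(adj_e, adj_s, adj_es) {
  list(E = adj_e, S = adj_s, ES = adj_es,
       pure_env = adj_es - adj_s,
       pure_spatial = adj_es - adj_e,
       shared = adj_e + adj_s - adj_es,
       residual = 1 - adj_es)
}

#' @export
print.rs_varpart <- function(x, ...) {
  cat(sprintf(paste0(
    "Variation partitioning (%s, adjusted R2):\n",
    "  pure env (E|S)     %6.1f%%  (p = %.4g)\n",
    "  pure spatial (S|E) %6.1f%%  (p = %.4g)\n",
    "  shared (S n E)     %6.1f%%\n",
    "  residual           %6.1f%%\n"),
    x$method, 100 * x$pure_env, x$p_pure_env, 100 * x$pure_spatial,
    x$p_pure_spatial, 100 * x$shared, 100 * x$residual))
  invisible(x)
}
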