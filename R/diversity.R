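#' Alpha diversity and coverage per sample
#'
#' Observed richness, Chao1 (bias-corrected by default, with the classical
#' form selectable) with its standard error, ACE (rare-OTU cutoff 10),
#' Shannon-Wiener H' (natural log), Simpson's index of diversity (1 - D),
#' Pielou's evenness H'/ln(S) and Good's coverage 1 - F1/N. Richness
#' estimators and Shannon/Simpson are delegated to vegan
#' (`estimateR`, `diversity`).
#'
#' @param cm a count matrix, or a single per-sample count vector.
#' @param chao1 `"bias_corrected"` (default) or `"classical"` (F1^2 / 2 F2).
#' @return a tibble with one row per sample.
#' @export
alpha_diversity <- function(cm, chao1 = c("bias_corrected", "classical")) {
  chao1 <- match.arg(chao1)
  if (is.null(dim(cm))) {
    cm <- matrix(as.integer(cm), ncol = 1,
                 dimnames = list(paste0("OTU", seq_along(cm)), "sample1"))
  }
  validate_count_matrix(cm)
  if (any(colSums(cm) == 0)) abort("all-zero sample")
  comm <- t(cm)  # vegan wants samples in rows
  est <- vegan::estimateR(comm)
  h <- vegan::diversity(comm, index = "shannon")
  simp <- vegan::diversity(comm, index = "simpson")
  s_obs <- rowSums(comm > 0)
  f1 <- rowSums(comm == 1)
  f2 <- rowSums(comm == 2)
  n <- rowSums(comm)
  chao1_val <- if (chao1 == "bias_corrected") {
    unname(est["S.chao1", ])
  } else {
    s_obs + ifelse(f2 > 0, f1^2 / (2 * f2), f1 * (f1 - 1) / 2)
  }
  tibble(
    sample_id = colnames(cm),
    observed_richness = as.integer(s_obs),
    chao1 = unname(chao1_val),
    chao1_se = unname(est["se.chao1", ]),
    ace = unname(est["S.ACE", ]),
    shannon = unname(h),
    simpson_diversity = unname(simp),
    pielou = unname(ifelse(s_obs > 1, h / log(s_obs), 0)),
    goods_coverage = unname(1 - f1 / n)
  )
}

#' Analytic rarefaction curve for one sample
#'
#' Expected OTU richness at each subsampling depth under the hypergeometric
#' law, `E[S_d] = sum_i (1 - C(N - n_i, d) / C(N, d))` (vegan's `rarefy`).
#'
#' @param counts per-sample count vector.
#' @param depths integer depths, each at most `sum(counts)`.
#' @return tibble with `depth` and `expected_richness`.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- as.integer(counts)
  n <- sum(counts)
  if (n <= 0) abort("all-zero sample")
  if (any(depths > n)) abort(sprintf("depth exceeds total count %d", n))
  er <- vapply(depths, function(d) {
    unname(suppressWarnings(vegan::rarefy(counts, sample = d)))
  }, numeric(1))
  tibble(depth = as.integer(depths), expected_richness = er)
}

#' Species accumulation curve over random sample orderings
#'
#' Mean cumulative number of distinct OTUs as samples are added in random
#' order (vegan's `specaccum(method = "random")`).
#'
#' @param cm count matrix.
#' @param n_perm number of random orderings.
#' @param seed integer seed.
#' @return tibble with `n_samples`, `richness` (mean), `sd`.
#' @export
species_accumulation <- function(cm, n_perm = 100L, seed = 1L) {
  validate_count_matrix(cm)
  if (n_perm < 1L) abort("n_perm must be >= 1")
  sac <- with_seed(seed, vegan::specaccum(t(cm), method = "random",
                                          permutations = n_perm))
  tibble(n_samples = sac$sites, richness = sac$richness,
         sd = if (is.null(sac$sd)) NA_real_ else sac$sd)
}

# Exact two-sided Mann-Whitney p by enumeration of all C(m+n, m) group
# assignments, with average ranks on ties; two-sidedness measured as the
# distance of U from its null mean mn/2.
mann_whitney_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  dev_obs <- abs(u_obs - m * n / 2)
  idxs <- combn(m + n, m)
  devs <- abs(apply(idxs, 2L, u_of) - m * n / 2)
  mean(devs >= dev_obs - 1e-12)
}

#' Mann-Whitney rank-sum comparison of two groups
#'
#' Returns the U statistic (min-U convention) and the two-sided p-value:
#' exact enumeration over all group assignments when the pooled size is at
#' most 10 (ties handled by average ranks), otherwise the normal
#' approximation with tie correction (`wilcox.test`).
#'
#' @param x,y numeric vectors.
#' @return one-row tibble: `u`, `p_value`, `exact`.
#' @export
rank_sum_compare <- function(x, y) {
  if (!length(x) || !length(y)) abort("empty input")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  u <- min(u1, m * n - u1)
  exact <- (m + n) <= 10L
  p <- if (exact) {
    mann_whitney_exact(x, y)
  } else {
    suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  tibble(u = u, p_value = p, exact = exact)
}
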