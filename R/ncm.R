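#' Predicted detection frequency under Sloan's neutral community model
#'
#' Under the neutral model for large microbial populations, the local relative
#' abundance of a taxon with regional mean relative abundance `p` follows a
#' Beta(`Nm p`, `Nm (1 - p)`) distribution, where `N` is the local community
#' (metacommunity) size and `m` the immigration rate. The probability of
#' detecting the taxon in a local community — its expected occurrence
#' frequency — is the probability that its local abundance exceeds the
#' detection limit `d`:
#' `freq(p) = 1 - BetaCDF(d; Nm p, Nm (1 - p))`.
#'
#' @param p regional mean relative abundance(s), in (0, 1).
#' @param Nm product of metacommunity size and immigration rate, > 0.
#' @param d detection limit (fraction), in (0, 1).
#' @return predicted frequency in `[0, 1]`, non-decreasing in `p`.
#' @export
ncm_predict <- function(p, Nm, d) {
  if (any(p <= 0 | p >= 1)) abort("p must lie strictly in (0, 1)")
  if (Nm <= 0) abort("Nm must be positive")
  if (d <= 0 || d >= 1) abort("d must lie strictly in (0, 1)")
  1 - pbeta(d, Nm * p, Nm * (1 - p))
}

# Wilson 95% score interval around a predicted proportion at n trials.
wilson_interval <- function(p, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  list(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Fit Sloan's neutral community model to an OTU table
#'
#' For every OTU detected in at least one sample, computes its regional mean
#' relative abundance (zeros included) and its observed occurrence frequency
#' (fraction of samples where it has at least one read), then estimates `Nm`
#' by least squares between observed and predicted frequencies. The search
#' runs over a log-spaced grid of `Nm` values and is polished by bounded
#' scalar minimisation, avoiding local minima from a cold start. `N` is the
#' mean sequencing depth; the default detection limit is `ln(2)/N`, the local
#' abundance at which the probability of drawing at least one read among `N`
#' crosses one half — the step threshold that makes the Beta-CDF detection
#' model agree with read-level detection (a threshold of `1/N` understates
#' detection and inflates `Nm`); `m = Nm / N`; fit quality is
#' `R2 = 1 - SSres/SStot` (may be
#' negative for a community far from neutrality). 95% bands are Wilson score
#' intervals around the predicted frequency at the sample count.
#'
#' @param cm OTU x sample count matrix (at least 5 samples and 20 detected
#'   OTUs).
#' @param detection_limit `"auto"` (`ln(2)` / mean depth) or a fraction.
#' @return an `rs_ncm` object: `Nm`, `m`, `N`, `detection_limit`,
#'   `r_squared`, `n_samples`, and per-OTU tibble `otus`
#'   (`otu_id`, `p`, `freq_obs`, `freq_pred`, `ci_low`, `ci_high`).
#' @export
fit_ncm <- function(cm, detection_limit = "auto") {
  validate_count_matrix(cm)
  if (ncol(cm) < 5L) abort("need at least 5 samples")
  detected <- rowSums(cm > 0) > 0
  cm <- cm[detected, , drop = FALSE]
  if (nrow(cm) < 20L) abort("need at least 20 detected OTUs")
  n_samp <- ncol(cm)
  ra <- relative_abundance(cm)
  p <- rowMeans(ra)
  freq_obs <- rowMeans(cm > 0)
  n_reads <- mean(colSums(cm))
  d <- if (identical(detection_limit, "auto")) log(2) / n_reads else as.numeric(detection_limit)
  sstot <- sum((freq_obs - mean(freq_obs))^2)
  if (sstot <= 0) abort("degenerate frequency spectrum: every OTU has the same occurrence frequency")
  ss <- function(log_nm) {
    pred <- ncm_predict(p, exp(log_nm), d)
    sum((freq_obs - pred)^2)
  }
  fit_in <- function(lo, hi) {
    grid <- seq(log(lo), log(hi), length.out = 80L)
    best <- grid[which.min(vapply(grid, ss, numeric(1)))]
    step <- diff(grid[1:2])
    optimize(ss, lower = best - step, upper = best + step)
  }
  bounds <- c(1e-1, 1e7)
  opt <- fit_in(bounds[1], bounds[2])
  if (opt$minimum <= log(bounds[1]) + 1e-6 || opt$minimum >= log(bounds[2]) - 1e-6) {
    warn("Nm estimate at search bound; widening once")
    opt <- fit_in(1e-3, 1e9)
    if (opt$minimum <= log(1e-3) + 1e-6 || opt$minimum >= log(1e9) - 1e-6) {
      abort("Nm optimizer stuck at the widened search bound")
    }
  }
  nm <- exp(opt$minimum)
  pred <- ncm_predict(p, nm, d)
  ci <- wilson_interval(pred, n_samp)
  r2 <- 1 - sum((freq_obs - pred)^2) / sstot
  structure(list(
    Nm = nm, m = nm / n_reads, N = n_reads, detection_limit = d,
    r_squared = r2, n_samples = n_samp,
    otus = tibble(otu_id = rownames(cm), p = unname(p),
                  freq_obs = unname(freq_obs), freq_pred = unname(pred),
                  ci_low = unname(ci$low), ci_high = unname(ci$high))
  ), class = "rs_ncm")
}

#' @export
print.rs_ncm <- function(x, ...) {
  cat(sprintf(
    "Sloan neutral community model fit:\n  Nm = %.1f  (m = %.4g, N = %.1f)\n  R2 = %.3f on %d OTUs x %d samples (detection limit %.3g)\n",
    x$Nm, x$m, x$N, x$r_squared, nrow(x$otus), x$n_samples, x$detection_limit))
  invisible(x)
}
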