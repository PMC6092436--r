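# broom-style tidiers for the fitted objects.

#' @export
tidy.rs_ncm <- function(x, ...) x$otus

#' @export
glance.rs_ncm <- function(x, ...) {
  tibble(Nm = x$Nm, m = x$m, N = x$N, detection_limit = x$detection_limit,
         r_squared = x$r_squared, n_otus = nrow(x$otus),
         n_samples = x$n_samples)
}

#' @export
tidy.rs_varpart <- function(x, ...) {
  tibble(
    fraction = c("pure_env", "pure_spatial", "shared", "residual"),
    adj_r2 = c(x$pure_env, x$pure_spatial, x$shared, x$residual),
    p_value = c(x$p_pure_env, x$p_pure_spatial, NA_real_, NA_real_)
  )
}

#' @export
glance.rs_varpart <- function(x, ...) {
  tibble(E = x$E, S = x$S, ES = x$ES, pure_env = x$pure_env,
         pure_spatial = x$pure_spatial, shared = x$shared,
         residual = x$residual, method = x$method)
}

#' @export
tidy.rs_mantel <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value, n_perm = x$n_perm,
         method = x$method, partial = x$partial)
}

#' @export
tidy.rs_anosim <- function(x, ...) {
  tibble(R = x$R, p_value = x$p_value, n_perm = x$n_perm,
         n_groups = x$n_groups)
}

#' @export
tidy.rs_nmds <- function(x, ...) x$coordinates

#' @export
glance.rs_nmds <- function(x, ...) {
  tibble(stress = x$stress, n_starts = x$n_starts, converged = x$converged)
}

#' @export
tidy.rs_decay <- function(x, ...) x$pairs

#' @export
glance.rs_decay <- function(x, ...) {
  tibble(r = x$mantel$r, p_value = x$mantel$p_value, slope = x$slope,
         intercept = x$intercept, method = x$mantel$method)
}

#' @export
tidy.rs_forward <- function(x, ...) x$trace

#' @export
tidy.rs_pcnm <- function(x, ...) {
  dplyr::bind_cols(tibble(sample_id = x$labels),
                   as_tibble(x$vectors, .name_repair = "minimal"))
}

#' @export
tidy.rs_ordination <- function(x, ...) {
  sc <- x$site_scores
  dplyr::bind_cols(tibble(sample_id = rownames(sc)),
                   as_tibble(as.data.frame(sc)))
}

#' @export
glance.rs_ordination <- function(x, ...) {
  tibble(method = x$method, constrained_fraction = x$constrained_fraction,
         adj_r2 = x$adj_r2, n_vars = length(x$selected_vars))
}
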