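#' Configuration for the full analysis pipeline
#'
#' @param rarefaction_depth even depth to subsample every sample to.
#' @param thresholds a [threshold_config()].
#' @param transform community transform for Bray-Curtis / NMDS (`"sqrt"`).
#' @param ord_transform community transform for RDA (`"hellinger"`).
#' @param n_perm permutations for ANOSIM / Mantel / ANOVA.
#' @param n_perm_select permutations per forward-selection step.
#' @param vif_threshold collinearity ceiling.
#' @param alpha forward-selection entry threshold.
#' @param env_variables env variable names to use (`NULL` = all present).
#' @param seed master seed; per-stage seeds are derived deterministically
#'   from it and the stage name, so stages can be re-run in isolation.
#' @export
pipeline_config <- function(rarefaction_depth = 28923L,
                            thresholds = threshold_config(),
                            transform = "sqrt",
                            ord_transform = "hellinger",
                            n_perm = 999L, n_perm_select = 199L,
                            vif_threshold = 20, alpha = 0.05,
                            env_variables = NULL, seed = 1L) {
  structure(list(rarefaction_depth = as.integer(rarefaction_depth),
                 thresholds = thresholds, transform = transform,
                 ord_transform = ord_transform, n_perm = as.integer(n_perm),
                 n_perm_select = as.integer(n_perm_select),
                 vif_threshold = vif_threshold, alpha = alpha,
                 env_variables = env_variables, seed = as.integer(seed)),
            class = "rs_pipeline_config")
}

write_stage <- function(tbl, output_dir, name) {
  if (is.null(output_dir)) return(invisible(NULL))
  readr::write_tsv(tbl, file.path(output_dir, paste0(name, ".tsv")))
  invisible(name)
}

#' Run the full abundant/rare biogeography analysis
#'
#' Mirrors the study workflow: rarefy to even depth, classify OTUs with the
#' dual-threshold rule, then for each of the three community levels (all,
#' abundant, rare): partition bookkeeping, alpha diversity, Bray-Curtis +
#' NMDS + ANOSIM by bay, distance-decay against geographic distance,
#' environmental distance, PCNM construction, VIF filtering, forward
#' selection of env variables and PCNM axes, RDA or CCA per the DCA gradient
#' gate, variation partitioning, and Mantel / partial Mantel tests; finally a
#' Sloan neutral-model fit on the entire community. Any stage failure aborts
#' with the stage name; results produced so far are kept in the output
#' directory alongside a MANIFEST.
#'
#' @param counts OTU x sample count matrix.
#' @param metadata sample metadata tibble (coordinates, bay, env variables).
#' @param config a [pipeline_config()].
#' @param output_dir directory for TSV outputs (`NULL` = don't write).
#' @return a named list of per-level results plus the NCM fit, invisibly
#'   classed `rs_report`.
#' @export
run_full_analysis <- function(counts, metadata, config = pipeline_config(),
                              output_dir = NULL) {
  stopifnot(inherits(config, "rs_pipeline_config"))
  metadata <- validate_sample_metadata(metadata)
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  manifest <- character()
  note <- function(x) manifest <<- c(manifest, x)
  stage <- "setup"
  res <- tryCatch({
    stage <- "rarefy"
    cm <- rarefy_even_depth(counts, config$rarefaction_depth,
                            seed = derive_seed(config$seed, "rarefy"),
                            prune_empty = TRUE)
    metadata <- metadata[match(colnames(cm), metadata$sample_id), ]
    ra <- relative_abundance(cm)

    stage <- "classify"
    cls <- classify_otus(ra, config$thresholds)
    summary_tbl <- partition_summary(cls, cm)
    note(write_stage(summary_tbl, output_dir, "partition_summary"))
    note(write_stage(cls, output_dir, "classification"))

    stage <- "spatial-setup"
    geo <- haversine_matrix(metadata)
    envd <- env_distance(metadata, config$env_variables)
    pcnm <- pcnm_basis(geo)
    env_x <- prepare_env_predictors(metadata, config$env_variables)

    levels <- list(
      all = rownames(cm),
      abundant = cls$otu_id[cls$label == "abundant"],
      rare = cls$otu_id[cls$label == "rare"]
    )
    out <- purrr::imap(levels, function(ids, lev) {
      stage <<- paste0("level-", lev)
      analyse_level(cm[ids, , drop = FALSE], metadata, geo, envd, pcnm, env_x,
                    config, lev, output_dir, note)
    })

    stage <- "ncm"
    ncm <- fit_ncm(cm)
    note(write_stage(glance(ncm), output_dir, "ncm_summary"))
    note(write_stage(tidy(ncm), output_dir, "ncm_otus"))

    c(out, list(partition_summary = summary_tbl, classification = cls,
                ncm = ncm, pcnm = pcnm, config = config))
  }, error = function(e) {
    if (!is.null(output_dir)) {
      writeLines(c(manifest, sprintf("INCOMPLETE at stage '%s': %s",
                                     stage, conditionMessage(e))),
                 file.path(output_dir, "MANIFEST"))
    }
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
  if (!is.null(output_dir)) {
    writeLines(c(manifest, "COMPLETE"), file.path(output_dir, "MANIFEST"))
  }
  invisible(structure(res, class = "rs_report"))
}

#' Environmental predictor matrix for constrained ordination
#'
#' Applies the same convention as [env_distance()] — log(x+1) on every
#' physico-chemical variable except pH, then a z-score per variable — and
#' returns a samples x variables matrix ready for [rda_fit()],
#' [forward_select()], or [variation_partition()]. Constant variables
#' (no information) are dropped.
#'
#' @param metadata sample metadata tibble.
#' @param vars env variable names; default all via [env_vars()].
#' @export
prepare_env_predictors <- function(metadata, vars = NULL) {
  vars <- vars %||% env_vars(metadata)
  x <- as.matrix(metadata[, vars, drop = FALSE])
  rownames(x) <- metadata$sample_id
  x <- scale(transform_env(x))
  x[, apply(x, 2L, function(v) all(is.finite(v))), drop = FALSE]
}

analyse_level <- function(cm, metadata, geo, envd, pcnm, env_x, config, lev,
                          output_dir, note) {
  if (nrow(cm) < 5L) {
    warn(sprintf("level '%s' has %d OTUs; skipping", lev, nrow(cm)))
    return(NULL)
  }
  empty <- colSums(cm) == 0
  if (any(empty)) {
    warn(sprintf("level '%s': dropping sample(s) without reads: %s", lev,
                 paste(colnames(cm)[empty], collapse = ", ")))
    keep <- colnames(cm)[!empty]
    cm <- cm[, keep, drop = FALSE]
    metadata <- metadata[match(keep, metadata$sample_id), ]
    sub <- function(d) stats::as.dist(as.matrix(d)[keep, keep])
    geo <- sub(geo); envd <- sub(envd)
    pcnm <- pcnm_basis(geo)
    env_x <- env_x[keep, , drop = FALSE]
  }
  ra <- relative_abundance(cm)  # subcommunity RAs renormalized
  alpha <- alpha_diversity(cm)
  note(write_stage(alpha, output_dir, paste0(lev, "_alpha")))
  bc <- bray_curtis(ra, transform = config$transform)
  ord <- nmds(bc, seed = derive_seed(config$seed, paste0(lev, "-nmds")))
  note(write_stage(ord$coordinates, output_dir, paste0(lev, "_nmds")))
  groups <- metadata$bay[match(dist_labels(bc), metadata$sample_id)]
  ano <- anosim_test(bc, groups, n_perm = config$n_perm,
                     seed = derive_seed(config$seed, paste0(lev, "-anosim")))
  decay <- distance_decay(bc, geo, n_perm = config$n_perm,
                          seed = derive_seed(config$seed, paste0(lev, "-decay")))
  mantel_env <- mantel_test(bc, envd, n_perm = config$n_perm,
                            seed = derive_seed(config$seed, paste0(lev, "-menv")))
  pm_env <- partial_mantel_test(bc, envd, geo, n_perm = config$n_perm,
                                seed = derive_seed(config$seed, paste0(lev, "-pmenv")))
  pm_geo <- partial_mantel_test(bc, geo, envd, n_perm = config$n_perm,
                                seed = derive_seed(config$seed, paste0(lev, "-pmgeo")))

  comm_lin <- transform_community(cm, config$ord_transform)
  gate <- dca_gradient_length(comm_lin)
  env_f <- vif_filter(cbind(env_x, pcnm$vectors), threshold = config$vif_threshold)
  keep_env <- intersect(colnames(env_f$x), colnames(env_x))
  keep_spa <- intersect(colnames(env_f$x), colnames(pcnm$vectors))
  method <- if (gate$recommendation == "cca") "cca" else "rda"
  comm_ord <- if (method == "cca") t(cm) else comm_lin
  sel_env <- forward_select(comm_ord, env_x[, keep_env, drop = FALSE],
                            method = method, alpha = config$alpha,
                            n_perm = config$n_perm_select,
                            seed = derive_seed(config$seed, paste0(lev, "-fse")))
  sel_spa <- forward_select(comm_ord, pcnm$vectors[, keep_spa, drop = FALSE],
                            method = method, alpha = config$alpha,
                            n_perm = config$n_perm_select,
                            seed = derive_seed(config$seed, paste0(lev, "-fss")))
  note(write_stage(dplyr::bind_rows(
    dplyr::mutate(sel_env$trace, set = "env"),
    dplyr::mutate(sel_spa$trace, set = "pcnm")
  ), output_dir, paste0(lev, "_forward_selection")))
  xe <- env_x[, if (length(sel_env$selected)) sel_env$selected else keep_env,
              drop = FALSE]
  xs <- pcnm$vectors[, if (length(sel_spa$selected)) sel_spa$selected else keep_spa,
                     drop = FALSE]
  ordfit <- if (method == "rda") rda_fit(comm_ord, cbind(xe, xs)) else {
    cca_fit(comm_ord, cbind(xe, xs),
            seed = derive_seed(config$seed, paste0(lev, "-cca")))
  }
  # The adjusted-R2 partition is defined on the linear engine; VPA stays on
  # RDA regardless of the gate, with the CCA route available to callers.
  vp <- variation_partition(comm_lin, xe, xs, method = "rda",
                            n_perm = config$n_perm,
                            seed = derive_seed(config$seed, paste0(lev, "-vpa")))
  note(write_stage(tidy(vp), output_dir, paste0(lev, "_varpart")))
  list(alpha = alpha, bray_curtis = bc, nmds = ord, anosim = ano,
       decay = decay, mantel_env = mantel_env, partial_mantel_env = pm_env,
       partial_mantel_geo = pm_geo, dca = gate,
       forward_env = sel_env, forward_spa = sel_spa,
       ordination = ordfit, varpart = vp)
}

#' @export
print.rs_report <- function(x, ...) {
  cat("Full-analysis report; levels:",
      paste(intersect(c("all", "abundant", "rare"), names(x)), collapse = ", "),
      "\n")
  if (!is.null(x$partition_summary)) print(x$partition_summary)
  if (!is.null(x$ncm)) print(x$ncm)
  invisible(x)
}
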