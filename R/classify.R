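#' Dual local/regional thresholds for abundant and rare taxa
#'
#' An OTU is *abundant* when it reaches at least `local_abundant` (default 1%)
#' of the reads in at least one sample AND its regional mean relative abundance
#' (the average of its per-sample fractions across all samples, zeros
#' included) is at least `regional_abundant` (default 0.1%). It is *rare* when
#' it falls below `local_rare` (default 0.01%) in at least one sample AND its
#' regional mean is below `regional_rare` (default 0.001%). Everything else is
#' *intermediate*. By convention the regional thresholds are the local ones
#' divided by `regional_divisor` (default 10); they can also be set directly.
#'
#' @param local_abundant,local_rare local (within-sample) fractions.
#' @param regional_abundant,regional_rare regional (mean across samples)
#'   fractions; when `NULL`, derived as local / `regional_divisor`.
#' @param regional_divisor divisor linking local and regional thresholds.
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(local_abundant = 0.01, local_rare = 1e-4,
                             regional_abundant = NULL, regional_rare = NULL,
                             regional_divisor = 10) {
  if (!(0 < local_rare && local_rare < local_abundant && local_abundant <= 1)) {
    abort("need 0 < local_rare < local_abundant <= 1")
  }
  cfg <- list(
    local_abundant = local_abundant,
    local_rare = local_rare,
    regional_abundant = regional_abundant %||% (local_abundant / regional_divisor),
    regional_rare = regional_rare %||% (local_rare / regional_divisor),
    regional_divisor = regional_divisor
  )
  if (cfg$regional_rare >= cfg$regional_abundant) {
    abort("regional_rare must be below regional_abundant")
  }
  structure(cfg, class = "threshold_config")
}

#' Classify OTUs as abundant, rare, or intermediate
#'
#' @param ra relative-abundance matrix (OTUs x samples, columns sum to 1).
#' @param cfg a [threshold_config()].
#' @return a tibble with one row per OTU: `otu_id`, `label`
#'   (abundant/rare/intermediate), `regional_mean`, `max_local`,
#'   `n_local_abundant` (samples at or above the local-abundant cutoff) and
#'   `n_local_rare` (samples below the local-rare cutoff, zeros included).
#' @export
classify_otus <- function(ra, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "threshold_config"))
  regional_mean <- rowMeans(ra)
  max_local <- apply(ra, 1L, max)
  n_local_abundant <- rowSums(ra >= cfg$local_abundant)
  n_local_rare <- rowSums(ra < cfg$local_rare)
  abundant <- max_local >= cfg$local_abundant & regional_mean >= cfg$regional_abundant
  rare <- n_local_rare >= 1L & regional_mean < cfg$regional_rare
  label <- ifelse(abundant, "abundant", ifelse(rare, "rare", "intermediate"))
  tibble(
    otu_id = rownames(ra),
    label = factor(label, levels = c("abundant", "intermediate", "rare")),
    regional_mean = unname(regional_mean),
    max_local = unname(max_local),
    n_local_abundant = unname(as.integer(n_local_abundant)),
    n_local_rare = unname(as.integer(n_local_rare))
  )
}

#' OTUs that are always locally abundant / always locally rare
#'
#' @inheritParams classify_otus
#' @return a list with character vectors `always_abundant` (at or above the
#'   local-abundant cutoff in every sample) and `always_rare` (below the
#'   local-rare cutoff in every sample; absences count as below).
#' @export
local_status_profiles <- function(ra, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "threshold_config"))
  list(
    always_abundant = rownames(ra)[rowSums(ra >= cfg$local_abundant) == ncol(ra)],
    always_rare = rownames(ra)[rowSums(ra < cfg$local_rare) == ncol(ra)]
  )
}

#' @rdname partition_summary
#' @param otu_n,seq_n named per-label OTU and sequence counts; exposed so the
#'   percentage bookkeeping can be applied to externally tallied counts.
#' @param otu_total,seq_total denominators for the percentages.
#' @export
summarise_partition_counts <- function(otu_n, seq_n, otu_total, seq_total) {
  tibble(
    label = names(otu_n) %||% as.character(seq_along(otu_n)),
    otu_n = as.integer(otu_n),
    otu_pct = round_half_up(100 * otu_n / otu_total, 2),
    seq_n = as.numeric(seq_n),
    seq_pct = round_half_up(100 * seq_n / seq_total, 2)
  )
}

#' Partition bookkeeping: OTU and sequence tallies per abundance class
#'
#' Reproduces the usual summary table: for each label, how many OTUs (and what
#' percentage of all OTUs, half-up to 2 decimals) and how many sequences (and
#' what percentage of all sequences).
#'
#' @param cls the classification tibble from [classify_otus()].
#' @param cm the count matrix the classification refers to.
#' @export
partition_summary <- function(cls, cm) {
  validate_count_matrix(cm)
  if (!setequal(cls$otu_id, rownames(cm)) || nrow(cls) != nrow(cm)) {
    abort("classification and count matrix disagree on OTU ids")
  }
  tot <- rowSums(cm)[cls$otu_id]
  otu_n <- table(cls$label)
  seq_n <- tapply(tot, cls$label, sum, default = 0)
  summarise_partition_counts(otu_n, seq_n, nrow(cm), sum(cm))
}

#' Abundance-occupancy relationship within an OTU subset
#'
#' Computes, for each OTU in `subset`, its mean relative abundance across all
#' samples and its occupancy (fraction of samples where it is detected), and
#' the Spearman rank correlation between the two (average ranks on ties; p
#' from the t approximation, exact enumeration for 8 or fewer OTUs).
#'
#' @inheritParams classify_otus
#' @param subset character vector of OTU ids (at least 3).
#' @return a list: `data` (per-OTU tibble), `rho`, `p_value`.
#' @export
abundance_occupancy <- function(ra, subset = rownames(ra)) {
  subset <- intersect(subset, rownames(ra))
  if (length(subset) < 3L) abort("too few OTUs for correlation")
  sub <- ra[subset, , drop = FALSE]
  dat <- tibble(
    otu_id = subset,
    mean_ra = unname(rowMeans(sub)),
    occupancy = unname(rowMeans(sub > 0))
  )
  if (sd(dat$mean_ra) == 0 || sd(dat$occupancy) == 0) {
    abort("zero-variance input: rho undefined")
  }
  ct <- suppressWarnings(cor.test(dat$mean_ra, dat$occupancy, method = "spearman",
                                  exact = length(subset) <= 8L))
  list(data = dat, rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Rank abundance of the top OTUs within each sample group
#'
#' Within each group (e.g. bay), OTUs are ranked by their summed relative
#' abundance over the group's samples, ties broken by OTU id. Returns the top
#' `top_k` per group plus the pairwise overlap of those top lists.
#'
#' @param cm count matrix.
#' @param groups named character vector mapping every sample id to a group.
#' @param top_k how many top-ranked OTUs to keep per group.
#' @return a list: `ranks` (tibble group/rank/otu_id/summed_ra) and
#'   `overlap` (tibble group1/group2/shared).
#' @export
rank_abundance_by_group <- function(cm, groups, top_k = 100L) {
  validate_count_matrix(cm)
  if (top_k < 1L) abort("top_k must be >= 1")
  miss <- setdiff(colnames(cm), names(groups))
  if (length(miss)) abort(sprintf("unmapped sample(s): %s", paste(miss, collapse = ", ")))
  ra <- relative_abundance(cm)
  lv <- unique(unname(groups[colnames(cm)]))
  ranks <- purrr::map_dfr(lv, function(g) {
    cols <- colnames(cm)[groups[colnames(cm)] == g]
    tot <- rowSums(ra[, cols, drop = FALSE])
    ord <- order(-tot, rownames(cm))
    k <- min(top_k, sum(tot > 0))
    tibble(group = g, rank = seq_len(k), otu_id = rownames(cm)[ord[seq_len(k)]],
           summed_ra = unname(tot[ord[seq_len(k)]]))
  })
  pairs <- if (length(lv) > 1L) t(combn(lv, 2L)) else matrix(character(), 0, 2)
  overlap <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- ranks$otu_id[ranks$group == pairs[i, 1]]
    b <- ranks$otu_id[ranks$group == pairs[i, 2]]
    tibble(group1 = pairs[i, 1], group2 = pairs[i, 2],
           shared = length(intersect(a, b)))
  })
  list(ranks = ranks, overlap = overlap)
}

#' Venn region counts of OTUs shared between sample groups
#'
#' An OTU belongs to a group when its summed count over the group's samples is
#' positive. Supports 2 or 3 groups; returns counts for every non-empty region
#' of the Venn diagram, named by the sorted group combination
#' (e.g. `"A&B"` for OTUs found in exactly A and B).
#'
#' @inheritParams rank_abundance_by_group
#' @param subset OTU ids to consider (default all).
#' @export
shared_otu_counts <- function(cm, groups, subset = rownames(cm)) {
  validate_count_matrix(cm)
  miss <- setdiff(colnames(cm), names(groups))
  if (length(miss)) abort(sprintf("unmapped sample(s): %s", paste(miss, collapse = ", ")))
  lv <- sort(unique(unname(groups[colnames(cm)])))
  if (length(lv) < 2L || length(lv) > 3L) abort("Venn regions need 2-3 groups")
  subset <- intersect(subset, rownames(cm))
  present <- vapply(lv, function(g) {
    cols <- colnames(cm)[groups[colnames(cm)] == g]
    rowSums(cm[subset, cols, drop = FALSE]) > 0
  }, logical(length(subset)))
  if (length(subset) == 1L) present <- matrix(present, nrow = 1, dimnames = list(subset, lv))
  pat <- apply(present, 1L, function(z) paste(lv[z], collapse = "&"))
  pat <- pat[pat != ""]
  regions <- unlist(lapply(seq_along(lv), function(k) {
    apply(combn(lv, k), 2L, paste, collapse = "&")
  }))
  counts <- vapply(regions, function(r) sum(pat == r), integer(1))
  tibble(region = regions, n_otus = unname(counts))
}
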