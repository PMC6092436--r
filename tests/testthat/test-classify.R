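ra_from <- function(m) {
  m <- as.matrix(m)
  rownames(m) <- paste0("OTU", seq_len(nrow(m)))
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  m
}

test_that("dual-threshold classification follows local AND regional rules", {
  n <- 22
  # one sample at 2%: locally abundant but regional mean 0.02/22 < 0.1%
  ra1 <- matrix(0, 1, n); ra1[1, 1] <- 0.02
  # 5% everywhere: abundant on both criteria
  ra2 <- matrix(0.05, 1, n)
  # 5e-6 everywhere: regional mean 5e-6 < 1e-5 and locally rare everywhere
  ra3 <- matrix(5e-6, 1, n)
  ra <- ra_from(rbind(ra1, ra2, ra3))
  cls <- classify_otus(ra)
  expect_identical(as.character(cls$label),
                   c("intermediate", "abundant", "rare"))
  expect_equal(cls$regional_mean, c(0.02 / 22, 0.05, 5e-6))
  expect_identical(cls$n_local_abundant, c(1L, 22L, 0L))
})

test_that("classification labels partition the OTU set and tighten monotonically", {
  cm <- random_counts(200, 10, lambda = 2, seed = 7)
  ra <- relative_abundance(cm)
  cls <- classify_otus(ra)
  expect_identical(nrow(cls), nrow(cm))
  expect_true(all(table(cls$label)["abundant"] +
                    table(cls$label)["intermediate"] +
                    table(cls$label)["rare"] == nrow(cm)))
  # raising the local-abundant cutoff can only shrink the abundant set
  loose <- sum(classify_otus(ra, threshold_config(local_abundant = 0.01))$label == "abundant")
  tight <- sum(classify_otus(ra, threshold_config(local_abundant = 0.05))$label == "abundant")
  expect_lte(tight, loose)
})

test_that("always-abundant and always-rare profiles nest inside the labels", {
  ra <- ra_from(rbind(
    rep(0.02, 4),                 # always locally abundant
    c(5e-5, 5e-5, 5e-5, 0.5),     # neither profile
    rep(0, 4),                    # absent everywhere: always rare
    rep(0.3, 4)
  ))
  prof <- local_status_profiles(ra)
  expect_setequal(prof$always_abundant, c("OTU1", "OTU4"))
  expect_identical(prof$always_rare, "OTU3")
  # under defaults, always_rare OTUs present in the table are labelled rare
  cm <- random_counts(500, 8, lambda = 0.5, seed = 2)
  ra2 <- relative_abundance(cm)
  cls <- classify_otus(ra2)
  prof2 <- local_status_profiles(ra2)
  rare_ids <- cls$otu_id[cls$label == "rare"]
  always_rare_regional <- intersect(
    prof2$always_rare,
    cls$otu_id[cls$regional_mean < threshold_config()$regional_rare]
  )
  expect_true(all(always_rare_regional %in% rare_ids))
})

test_that("partition summary reports exact half-up percentages", {
  cm <- toy_counts(rbind(c(50L, 40L), c(5L, 4L), c(0L, 1L)))
  ra <- relative_abundance(cm)
  cls <- classify_otus(ra, threshold_config(local_abundant = 0.3, local_rare = 0.02))
  tab <- partition_summary(cls, cm)
  expect_equal(sum(tab$otu_n), 3L)
  expect_equal(sum(tab$seq_n), 100)
  expect_equal(sum(tab$otu_pct), 100, tolerance = 0.02)
  # single-label toy: everything abundant
  all_ab <- toy_counts(matrix(c(60L, 40L), 2, 1))
  cls2 <- classify_otus(relative_abundance(all_ab),
                        threshold_config(local_abundant = 0.1))
  tab2 <- partition_summary(cls2, all_ab)
  expect_equal(tab2$otu_pct[tab2$label == "abundant"], 100)
  expect_equal(tab2$seq_pct[tab2$label == "abundant"], 100)
  expect_error(partition_summary(cls2, cm), "disagree")
})

test_that("abundance-occupancy correlation matches a hand-ranked oracle", {
  # perfect monotone case
  ra <- ra_from(diag(c(0.5, 0.3, 0.2)) %*% matrix(1, 3, 4))
  ra[2, 4] <- 0; ra[3, 3:4] <- 0
  ao <- abundance_occupancy(ra)
  expect_equal(ao$rho, 1)
  # 5-OTU toy against the direct Spearman rank formula
  ra5 <- ra_from(rbind(c(0.4, 0.4), c(0.1, 0), c(0.05, 0.05),
                       c(0.02, 0), c(0, 0.01)))
  ao5 <- abundance_occupancy(ra5)
  mr <- rowMeans(ra5); occ <- rowMeans(ra5 > 0)
  oracle <- cor(rank(mr), rank(occ))
  expect_equal(ao5$rho, oracle)
  # degenerate: identical values
  flat <- ra_from(matrix(0.25, 4, 3))
  expect_error(abundance_occupancy(flat), "zero-variance")
  expect_error(abundance_occupancy(ra5, c("OTU1", "OTU2")), "too few")
})

test_that("group rank-abundance lists and overlaps behave on constructions", {
  cm <- toy_counts(rbind(c(10L, 12L, 11L, 9L), c(5L, 6L, 0L, 0L),
                         c(0L, 0L, 7L, 8L)))
  gr <- c(S1 = "A", S2 = "A", S3 = "B", S4 = "B")
  res <- rank_abundance_by_group(cm, gr, top_k = 2)
  # shared dominant OTU ranks first in both groups
  expect_true(all(res$ranks$otu_id[res$ranks$rank == 1] == "OTU1"))
  expect_identical(res$overlap$shared, 1L)
  # identical groups overlap fully
  gr_same <- c(S1 = "A", S2 = "B", S3 = "A", S4 = "B")
  cm_same <- cm[, c(1, 1, 2, 2)]
  colnames(cm_same) <- names(gr_same)
  res2 <- rank_abundance_by_group(cm_same, gr_same, top_k = 2)
  expect_identical(res2$overlap$shared, 2L)
  expect_error(rank_abundance_by_group(cm, gr[-1], top_k = 2), "unmapped")
})

test_that("Venn region counts match exhaustive hand enumeration", {
  cm <- toy_counts(rbind(
    c(1L, 0L, 0L),  # A only
    c(1L, 1L, 0L),  # A & B
    c(1L, 1L, 1L),  # central
    c(0L, 0L, 2L),  # C only
    c(0L, 1L, 1L)   # B & C
  ))
  gr <- c(S1 = "A", S2 = "B", S3 = "C")
  venn <- shared_otu_counts(cm, gr)
  counts <- setNames(venn$n_otus, venn$region)
  expect_identical(counts[["A"]], 1L)
  expect_identical(counts[["A&B"]], 1L)
  expect_identical(counts[["A&B&C"]], 1L)
  expect_identical(counts[["C"]], 1L)
  expect_identical(counts[["B&C"]], 1L)
  expect_identical(counts[["B"]], 0L)
  expect_identical(sum(venn$n_otus), 5L)
  expect_identical(sum(shared_otu_counts(cm, gr, subset = character())$n_otus), 0L)
})
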