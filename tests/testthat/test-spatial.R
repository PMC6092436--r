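test_that("haversine distances match closed forms and the triangle inequality", {
  meta <- tibble::tibble(sample_id = c("A", "B", "C"),
                         latitude = c(0, 1, 0), longitude = c(0, 0, 180))
  d <- as.matrix(haversine_matrix(meta))
  expect_equal(d["A", "B"], pi * 6371.0088 / 180, tolerance = 1e-6)  # 111.195
  expect_equal(d["A", "C"], pi * 6371.0088, tolerance = 1e-6)        # antipodal
  expect_equal(d["A", "A"], 0)
  # triangle inequality on random coordinate triples
  withr::with_seed(17, {
    for (i in 1:20) {
      m <- tibble::tibble(sample_id = c("P", "Q", "R"),
                          latitude = runif(3, -90, 90),
                          longitude = runif(3, -180, 180))
      dd <- as.matrix(haversine_matrix(m))
      expect_lte(dd["P", "R"], dd["P", "Q"] + dd["Q", "R"] + 1e-6)
    }
  })
  meta$latitude[2] <- NA
  expect_error(haversine_matrix(meta), "B")
})

test_that("environmental distance standardizes and log-transforms correctly", {
  meta <- tibble::tibble(sample_id = c("S1", "S2"),
                         TN = c(1, 3), pH = c(8, 8))
  d <- env_distance(meta)
  # with 2 samples each z-score is +/- 1/sqrt(2); one varying variable
  expect_equal(as.vector(d), sqrt(2), tolerance = 1e-9)
  # identical env: distance 0
  same <- tibble::tibble(sample_id = c("S1", "S2"), TN = c(2, 2), pH = c(8, 8))
  expect_equal(as.vector(env_distance(same)), 0)
  # pH is NOT log-compressed: doubling pH moves distance differently than TN
  m1 <- tibble::tibble(sample_id = c("S1", "S2", "S3"),
                       pH = c(4, 8, 6), TN = c(5, 5, 5))
  m2 <- tibble::tibble(sample_id = c("S1", "S2", "S3"),
                       pH = c(7, 7, 7), TN = c(4, 8, 6))
  r_ph <- as.matrix(env_distance(m1))["S1", "S2"] /
    as.matrix(env_distance(m1))["S2", "S3"]
  r_tn <- as.matrix(env_distance(m2))["S1", "S2"] /
    as.matrix(env_distance(m2))["S2", "S3"]
  expect_false(isTRUE(all.equal(r_ph, r_tn)))
  expect_error(env_distance(tibble::tibble(sample_id = "S1", TN = -1,
                                           pH = 8)), "negative")
  # invariance to variable order and affine rescaling
  meta3 <- toy_metadata(8)
  d1 <- env_distance(meta3, c("temperature", "TN"))
  d2 <- env_distance(meta3, c("TN", "temperature"))
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-9)
})

test_that("distance-decay reports a Mantel fit plus decay slope", {
  withr::with_seed(23, {
    n <- 12
    geo_pos <- sort(runif(n, 0, 500))
    geo <- dist(geo_pos)
    comm <- dist(geo_pos / 500)  # dissimilarity strictly increasing with distance
    attr(geo, "Labels") <- attr(comm, "Labels") <- paste0("S", 1:n)
  })
  dd <- distance_decay(comm, geo, n_perm = 99, seed = 1)
  expect_equal(dd$mantel$r, 1)
  expect_equal(dd$slope, 1 / 500, tolerance = 1e-9)
  expect_lte(dd$mantel$p_value, 0.05)
  # shuffled geography: r centred near zero
  rs <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      g2 <- dist(sample(geo_pos))
      attr(g2, "Labels") <- paste0("S", 1:12)
      distance_decay(comm, g2, n_perm = 9, seed = s)$mantel$r
    })
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("PCNM basis has orthogonal centred axes and sinusoid structure on a transect", {
  # 20 equally spaced collinear points
  n <- 20
  meta <- tibble::tibble(sample_id = sprintf("S%02d", 1:n),
                         latitude = seq(0, 2, length.out = n), longitude = 0)
  geo <- haversine_matrix(meta)
  pb <- pcnm_basis(geo)
  # truncation = MST longest edge = the spacing between neighbours
  spacing <- as.matrix(geo)[1, 2]
  expect_equal(pb$truncation, spacing, tolerance = 1e-6)
  v <- pb$vectors
  # orthogonality and centring
  cp <- crossprod(sweep(v, 2, sqrt(colSums(v^2)), "/"))
  expect_lt(max(abs(cp - diag(ncol(v)))), 1e-8)
  expect_lt(max(abs(colMeans(v))), 1e-10)
  # the first axes track cos(k pi x / L) waves: strong cosine correlation and
  # exactly k sign changes (oscillation frequency increases with axis number)
  x <- seq(0, 1, length.out = n)
  for (k in 1:3) {
    expect_gt(abs(cor(v[, k], cos(k * pi * x))), 0.85)
    expect_identical(sum(diff(sign(v[, k])) != 0), k)
  }
  expect_identical(colnames(v)[1], "PCNM1")
  expect_true(all(diff(pb$eigenvalues) <= 1e-9))
})

test_that("PCNM handles simple geometries and limit cases", {
  tri <- tibble::tibble(sample_id = c("A", "B", "C"),
                        latitude = c(0, 1, 0.5), longitude = c(0, 0, sqrt(3) / 2))
  pb <- pcnm_basis(haversine_matrix(tri))
  expect_gte(pb$n_positive, 1)
  # truncation beyond the max distance: plain principal coordinates
  meta <- tibble::tibble(sample_id = paste0("S", 1:6),
                         latitude = seq(0, 1, length.out = 6), longitude = 0)
  geo <- haversine_matrix(meta)
  pb2 <- pcnm_basis(geo, truncation = 2 * max(geo))
  pco <- cmdscale(geo, k = pb2$n_positive)
  for (j in seq_len(pb2$n_positive)) {
    expect_gt(abs(cor(pb2$vectors[, j], pco[, j])), 1 - 1e-6)
  }
  co <- tibble::tibble(sample_id = c("A", "B", "C"), latitude = 1, longitude = 2)
  expect_error(pcnm_basis(haversine_matrix(co)), "coincident")
})

test_that("PCNM axes agree with vegan's reference implementation", {
  meta <- toy_metadata(10)
  geo <- haversine_matrix(meta)
  ours <- pcnm_basis(geo)
  ref <- vegan::pcnm(geo)
  expect_equal(ours$n_positive, sum(ref$values > 1e-8))
  for (j in seq_len(min(4, ours$n_positive))) {
    expect_gt(abs(cor(ours$vectors[, j], ref$vectors[, j])), 1 - 1e-6)
  }
})
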