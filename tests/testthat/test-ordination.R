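sim_xy <- function(n = 20, p = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("x1", "x2", "x3")))
    y <- cbind(x %*% matrix(rnorm(3 * p), 3), matrix(rnorm(n * 2), n)) * 0.5
    list(x = x, y = y)
  })
}

test_that("DCA gradient lengths gate the RDA/CCA choice", {
  # short gradient: shallow Gaussian responses, every species everywhere
  withr::with_seed(31, {
    grad <- seq(-1, 1, length.out = 15)
    short <- sapply(seq(-1.2, 1.2, length.out = 30), function(opt) {
      50 * exp(-(grad - opt)^2 / 8) + 5
    })
    short <- matrix(as.integer(round(short)), nrow = 15)
    dimnames(short) <- list(paste0("S", 1:15), paste0("sp", 1:30))
    # long gradient: complete species turnover
    grad2 <- seq(0, 10, length.out = 15)
    long <- sapply(seq(0, 10, length.out = 40), function(opt) {
      80 * exp(-(grad2 - opt)^2 / 0.5)
    })
    long <- matrix(as.integer(round(long)), nrow = 15)
    dimnames(long) <- list(paste0("S", 1:15), paste0("sp", 1:40))
  })
  g_short <- dca_gradient_length(short)
  expect_lt(g_short$longest, 3)
  expect_identical(g_short$recommendation, "rda")
  g_long <- dca_gradient_length(long)
  expect_gt(g_long$longest, 4)
  expect_identical(g_long$recommendation, "cca")
  # duplicated identical samples: essentially no turnover
  dup <- short[rep(1, 5), ]
  rownames(dup) <- paste0("S", 1:5)
  expect_error(dca_gradient_length(dup[, 1, drop = FALSE]), "degenerate")
})

test_that("RDA constrained fraction and Ezekiel adjustment are exact", {
  d <- sim_xy(seed = 41)
  # y an exact linear map of x
  y_exact <- d$x %*% matrix(rnorm(3 * 8), 3)
  fit <- rda_fit(y_exact, d$x)
  expect_equal(fit$constrained_fraction, 1, tolerance = 1e-9)
  # orthogonal x: constructed residual response
  q <- qr.Q(qr(cbind(1, d$x)))
  y_orth <- d$y - q %*% crossprod(q, d$y)
  fit0 <- rda_fit(y_orth, d$x)
  expect_lt(fit0$constrained_fraction, 1e-9)
  expect_lte(fit0$adj_r2, 0)
  # Ezekiel closed form
  expect_equal(adjusted_r2(0.5, 22, 5), 1 - 0.5 * 21 / 16)
  expect_equal(adjusted_r2(0.5, 22, 5), 0.34375)
  expect_error(rda_fit(d$y[1:5, ], matrix(rnorm(25), 5)), "overdetermined")
})

test_that("RDA fraction is invariant to non-singular reparameterisation of x", {
  d <- sim_xy(seed = 43)
  f1 <- rda_fit(d$y, d$x)$constrained_fraction
  withr::with_seed(7, {
    repeat {
      mix <- matrix(rnorm(9), 3)
      if (abs(det(mix)) > 0.1) break
    }
  })
  x2 <- d$x %*% mix
  colnames(x2) <- colnames(d$x)
  f2 <- rda_fit(d$y, x2)$constrained_fraction
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("CCA captures constructed separation and rejects degenerate tables", {
  # two compositionally disjoint groups split by one binary predictor
  y <- rbind(matrix(rep(c(20, 0), each = 5 * 4), 5),
             matrix(rep(c(0, 20), each = 5 * 4), 5))
  y <- y + matrix(rpois(80, 0.2), 10)
  dimnames(y) <- list(paste0("S", 1:10), paste0("sp", 1:8))
  x <- matrix(rep(c(0, 1), each = 5), dimnames = list(NULL, "grp"))
  fit <- cca_fit(y, x, n_perm = 49, seed = 1)
  expect_gt(fit$constrained_fraction, 0.9)
  same <- matrix(5, 6, 4, dimnames = list(paste0("S", 1:6), paste0("sp", 1:4)))
  expect_error(cca_fit(same, matrix(rnorm(6))), "inertia")
})

test_that("the projection engine reproduces vegan's constrained inertia", {
  d <- sim_xy(seed = 47)
  y_pos <- abs(d$y) + 0.1
  ref_rda <- vegan::rda(d$y ~ ., data = as.data.frame(d$x))
  resp <- rarescape:::ord_response(d$y, "rda")
  expect_equal(rarescape:::ord_r2(resp, rarescape:::ord_design(d$x)),
               ref_rda$CCA$tot.chi / ref_rda$tot.chi, tolerance = 1e-10)
  ref_cca <- vegan::cca(y_pos ~ ., data = as.data.frame(d$x))
  respc <- rarescape:::ord_response(y_pos, "cca")
  expect_equal(rarescape:::ord_r2(respc, rarescape:::ord_design(d$x, respc$w)),
               ref_cca$CCA$tot.chi / ref_cca$tot.chi, tolerance = 1e-10)
})

test_that("VIF filtering drops collinear predictors, later columns first on ties", {
  withr::with_seed(51, {
    orth <- qr.Q(qr(scale(matrix(rnorm(30 * 3), 30), scale = FALSE)))
    colnames(orth) <- c("a", "b", "c")
  })
  res <- vif_filter(orth)
  expect_identical(nrow(res$dropped), 0L)
  expect_true(all(abs(res$vif - 1) < 1e-8))
  dup <- cbind(orth, d = orth[, 1])
  res2 <- vif_filter(dup)
  expect_identical(res2$dropped$variable, "d")
  withr::with_seed(52, {
    x3 <- matrix(rnorm(40 * 2), 40, dimnames = list(NULL, c("p", "q")))
    x3 <- cbind(x3, r = x3[, 1] + x3[, 2] + rnorm(40, 0, 0.01))
  })
  res3 <- vif_filter(x3)
  expect_identical(nrow(res3$dropped), 1L)
  expect_true(all(res3$vif <= 20))
})

test_that("permutation ANOVA saturates on strong effects and has exact granularity", {
  d <- sim_xy(seed = 53)
  y_strong <- d$x %*% matrix(rnorm(3 * 8), 3) +
    0.01 * matrix(rnorm(20 * 8), 20)
  pa <- permutation_anova(y_strong, d$x, n_perm = 99, seed = 1)
  expect_equal(pa$p_value, 1 / 100)
  pa9 <- permutation_anova(d$y, d$x[, 1, drop = FALSE], n_perm = 9, seed = 1)
  expect_true(pa9$p_value %in% ((1:10) / 10))
})

test_that("forward selection recovers a planted driver and respects contracts", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(100 + s, {
      n <- 30
      x <- matrix(rnorm(n * 4), n,
                  dimnames = list(NULL, c("x1", "x2", "x3", "x4")))
      y <- outer(x[, 1], rnorm(12)) + 0.5 * matrix(rnorm(n * 12), n)
    })
    fs <- forward_select(y, x, n_perm = 99, seed = s)
    length(fs$selected) >= 1 && fs$selected[1] == "x1"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # collinear input violates the contract
  withr::with_seed(61, {
    x <- matrix(rnorm(20 * 2), 20, dimnames = list(NULL, c("a", "b")))
    y <- matrix(rnorm(20 * 5), 20)
  })
  expect_error(forward_select(y, cbind(x, a2 = x[, "a"])), "collinear")
  # selection is stable under column permutation of x
  withr::with_seed(62, {
    x4 <- matrix(rnorm(25 * 3), 25, dimnames = list(NULL, c("u", "v", "w")))
    y4 <- outer(x4[, 2], rnorm(10)) + 0.4 * matrix(rnorm(250), 25)
  })
  s1 <- forward_select(y4, x4, n_perm = 199, seed = 9)$selected
  s2 <- forward_select(y4, x4[, c(3, 1, 2)], n_perm = 199, seed = 9)$selected
  expect_identical(sort(s1), sort(s2))
})

test_that("variation partitioning identities hold and match vegan's varpart", {
  # in-print arithmetic: adjusted fractions must close to 100%
  fr <- varpart_fractions(adj_e = 0.054, adj_s = 0.055, adj_es = 0.089)
  expect_equal(fr$pure_env + fr$pure_spatial + fr$shared + fr$residual, 1,
               tolerance = 1e-12)
  d <- sim_xy(seed = 71)
  withr::with_seed(72, {
    xe <- d$x[, 1:2]
    xs <- cbind(s1 = rnorm(20), s2 = rnorm(20))
  })
  vp <- variation_partition(d$y, xe, xs, n_perm = 49, seed = 3)
  expect_equal(vp$pure_env + vp$pure_spatial + vp$shared + vp$residual, 1,
               tolerance = 1e-9)
  ref <- vegan::varpart(d$y, xe, xs)
  # vegan rows: [a] = X1|X2, [b] = X2|X1, [c] = shared, [d] = residual
  ind <- ref$part$indfract$Adj.R.squared
  expect_equal(vp$pure_env, ind[1], tolerance = 1e-8)
  expect_equal(vp$pure_spatial, ind[2], tolerance = 1e-8)
  expect_equal(vp$shared, ind[3], tolerance = 1e-8)
  expect_equal(vp$residual, ind[4], tolerance = 1e-8)
  # a spatial set of pure noise: pure-spatial and shared fractions near zero
  y_env <- d$x[, 1:2] %*% matrix(rnorm(2 * 10), 2) +
    0.3 * matrix(rnorm(200), 20)
  vp0 <- variation_partition(y_env, xe, xs, n_perm = 0)
  expect_lt(abs(vp0$pure_spatial), 0.1)
  expect_lt(abs(vp0$shared), 0.1)
})
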