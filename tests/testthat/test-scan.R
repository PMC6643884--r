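# Two-dimensional scan, LOD statistic, profile traces.

scan_fixture <- function(n = 60, seed = 17) {
  g <- tiny_genome(n = n, seed = seed)
  probs <- g$probs[[1]]
  kin <- g$kinship[[1]]
  set.seed(seed + 1)
  Y <- sim_trait_pair(probs, 5, 7, make_effects(2, "ABCD:EFGH"),
                      var_comp(diag(2), diag(2)), kin, seed = seed + 2)
  list(probs = probs, kin = kin, Y = Y)
}

test_that("every grid entry equals an independent dense per-pair computation", {
  set.seed(20)
  fx <- scan_fixture(n = 60)
  covar <- covariate_matrix(matrix(rnorm(60), 60, 1,
                                   dimnames = list(rownames(fx$Y), "sex")))
  vc <- var_comp(rand_spd2(), rand_spd2())
  s <- scan_pvl(fx$probs, fx$Y, covar, fx$kin, interval = c(2, 4),
                varcomp = vc)
  expect_equal(dim(s$grid), c(3, 3))
  idx <- match(s$markers, dimnames(fx$probs)[[3]])
  for (i in 1:3) for (j in 1:3) {
    X1 <- cbind(unclass(fx$probs)[, , idx[i]], unclass(covar))
    X2 <- cbind(unclass(fx$probs)[, , idx[j]], unclass(covar))
    o <- dense_gls_oracle(unclass(fx$Y), X1, X2, unclass(fx$kin), vc$Vg, vc$Ve)
    expect_equal(s$grid[i, j], o$ll10, tolerance = 1e-8)
  }
})

test_that("a duplicated marker yields equal grid rows and columns", {
  fx <- scan_fixture(n = 60)
  p <- unclass(fx$probs)
  p[, , 6] <- p[, , 5]  # duplicate marker 5 at position 6
  probs2 <- alleleprob(p, attr(fx$probs, "map"), "1")
  s <- scan_pvl(probs2, fx$Y, kin = fx$kin, interval = c(3, 6))
  i5 <- match(dimnames(p)[[3]][5], s$markers)
  i6 <- match(dimnames(p)[[3]][6], s$markers)
  expect_equal(s$grid[i5, ], s$grid[i6, ], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(s$grid[, i5], s$grid[, i6], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("diagonal grid entries equal the pleiotropic-model GLS likelihood", {
  fx <- scan_fixture(n = 60)
  s <- scan_pvl(fx$probs, fx$Y, kin = fx$kin, interval = c(3, 5))
  idx <- match(s$markers, dimnames(fx$probs)[[3]])
  for (i in seq_along(idx)) {
    A <- unclass(fx$probs)[, , idx[i]]
    f <- gls_fit(fx$Y, pvl_design(A), fx$kin, s$varcomp)
    expect_equal(s$grid[i, i], f$loglik10, tolerance = 1e-9)
  }
  # and the pleiotropic-peak fit stored on the object matches the diagonal max
  expect_equal(s$pleio_fit$loglik10, max(diag(s$grid)), tolerance = 1e-9)
})

test_that("lod_statistic equals a brute-force two-loop maximum difference", {
  set.seed(23)
  for (rep in 1:20) {
    g <- matrix(rnorm(16, sd = 3), 4, 4)
    best <- -Inf; bestd <- -Inf
    for (i in 1:4) for (j in 1:4) {
      best <- max(best, g[i, j])
      if (i == j) bestd <- max(bestd, g[i, j])
    }
    expect_equal(lod_statistic(g), best - bestd)
  }
})

test_that("a grid whose maximum sits on the diagonal has LOD zero", {
  g <- matrix(c(1, 0, 0, 5), 2, 2)
  expect_equal(lod_statistic(g), 0)
})

test_that("the LOD statistic is invariant to adding a constant to the grid", {
  set.seed(24)
  g <- matrix(rnorm(25), 5, 5)
  expect_equal(lod_statistic(g), lod_statistic(g + 123.45), tolerance = 1e-12)
})

test_that("profile traces match a brute-force row/column/diagonal scan", {
  set.seed(25)
  for (rep in 1:10) {
    g <- matrix(rnorm(25, sd = 2), 5, 5)
    tr <- profile_traces(g, positions = 1:5)
    md <- max(diag(g))
    for (i in 1:5) {
      expect_equal(tr$profile1[i], max(g[i, ]) - md)
      expect_equal(tr$profile2[i], max(g[, i]) - md)
      expect_equal(tr$pleio[i], g[i, i] - md)
    }
    # identities: max pleio 0; profiles share the LOD maximum
    expect_equal(max(tr$pleio), 0)
    expect_equal(max(tr$profile1), lod_statistic(g))
    expect_equal(max(tr$profile2), lod_statistic(g))
    expect_gte(attr(tr, "lod"), 0)
  }
})

test_that("swapping the traits transposes the grid and preserves the LOD", {
  fx <- scan_fixture(n = 60)
  vc <- var_comp(diag(2), diag(2))
  s1 <- scan_pvl(fx$probs, fx$Y, kin = fx$kin, interval = c(2, 6),
                 varcomp = vc)
  Yswap <- trait_pair(unclass(fx$Y)[, 2:1])
  s2 <- scan_pvl(fx$probs, Yswap, kin = fx$kin, interval = c(2, 6),
                 varcomp = vc)
  expect_equal(unname(s1$grid), unname(t(s2$grid)), tolerance = 1e-9)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-9)
})

test_that("enlarging the scan interval never decreases the grid maximum", {
  fx <- scan_fixture(n = 60, seed = 31)
  vc <- var_comp(diag(2), diag(2))
  s_small <- scan_pvl(fx$probs, fx$Y, kin = fx$kin, interval = c(3, 5),
                      varcomp = vc)
  s_big <- scan_pvl(fx$probs, fx$Y, kin = fx$kin, interval = c(1, 8),
                    varcomp = vc)
  expect_gte(max(s_big$grid) + 1e-9, max(s_small$grid))
})

test_that("scans fail on intervals with fewer than two markers and name rank-deficient markers", {
  fx <- scan_fixture(n = 60)
  expect_error(scan_pvl(fx$probs, fx$Y, kin = fx$kin, interval = c(3, 3.2)),
               "fewer than 2 markers")
  # make marker 4 rank-deficient: identical probabilities for every subject
  p <- unclass(fx$probs)
  p[, , 4] <- matrix(rep(p[1, , 4], each = dim(p)[1]), nrow = dim(p)[1])
  probs2 <- alleleprob(p, attr(fx$probs, "map"), "1")
  expect_error(scan_pvl(probs2, fx$Y, kin = fx$kin, interval = c(2, 5)),
               "rank-deficient design at marker .*m004")
})

test_that("scan_pvl peak bookkeeping and methods are coherent", {
  fx <- scan_fixture(n = 60, seed = 41)
  s <- scan_pvl(fx$probs, fx$Y, kin = fx$kin, interval = c(2, 7))
  expect_s3_class(s, "pvl_scan")
  expect_equal(s$lod, lod_statistic(s$grid))
  expect_equal(max(s$traces$pleio), 0)
  expect_equal(max(s$traces$profile1), s$lod, tolerance = 1e-12)
  expect_equal(max(s$traces$profile2), s$lod, tolerance = 1e-12)
  expect_output(print(s), "LOD")
  expect_output(print(summary(s)), "pleiotropic peak")
  expect_true(is.matrix(coef(s)))
  expect_equal(nrow(coef(s)), dim(fx$probs)[2])
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(s); grDevices::dev.off()
  expect_true(file.exists(tf))
  unlink(tf)
})
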