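# Mixed-model core: covariance construction, GLS, EM-REML.

test_that("build_sigma handles degenerate and single-subject cases", {
  K <- rand_kinship(4)
  vc0 <- var_comp(matrix(0, 2, 2), diag(2))
  expect_equal(build_sigma(vc0, K), diag(8))

  K1 <- kinship_matrix(matrix(1, 1, 1, dimnames = list("s1", "s1")))
  vc <- var_comp(matrix(c(1, .3, .3, 2), 2), matrix(c(.5, -.1, -.1, .4), 2))
  expect_equal(build_sigma(vc, K1), vc$Vg + vc$Ve)
})

test_that("build_sigma matches an index-loop Kronecker oracle", {
  set.seed(2)
  K <- rand_kinship(3)
  vc <- var_comp(rand_spd2(), rand_spd2())
  S <- build_sigma(vc, K)
  for (a in 1:2) for (b in 1:2) for (i in 1:3) for (j in 1:3) {
    expect_equal(S[(a - 1) * 3 + i, (b - 1) * 3 + j],
                 vc$Vg[a, b] * unclass(K)[i, j] + vc$Ve[a, b] * (i == j))
  }
})

test_that("with K = I, Vg = 0, Ve = I the GLS solution is per-trait OLS", {
  set.seed(3)
  n <- 20
  Ki <- diag(n)
  dimnames(Ki) <- list(paste0("s", 1:n), paste0("s", 1:n))
  K <- kinship_matrix(Ki)
  A1 <- rand_alleles(n, 3); A2 <- rand_alleles(n, 3)
  Y <- rand_traits(rownames(K))
  f <- gls_fit(Y, pvl_design(A1, A2), K, var_comp(matrix(0, 2, 2), diag(2)))
  ols1 <- qr.coef(qr(A1), unclass(Y)[, 1])
  ols2 <- qr.coef(qr(A2), unclass(Y)[, 2])
  expect_equal(unname(f$coefficients$trait1), unname(ols1), tolerance = 1e-10)
  expect_equal(unname(f$coefficients$trait2), unname(ols2), tolerance = 1e-10)
})

test_that("noiseless traits recover the generating effects exactly", {
  set.seed(4)
  n <- 15
  K <- rand_kinship(n)
  A <- rand_alleles(n, 4)
  B <- cbind(c(1, -2, 0.5, 3), c(0, 1, 2, -1))
  Y <- trait_pair(matrix(c(A %*% B[, 1], A %*% B[, 2]), n, 2,
                         dimnames = list(rownames(K), c("y1", "y2"))))
  f <- gls_fit(Y, pvl_design(A, A), K, var_comp(rand_spd2(), rand_spd2()))
  expect_equal(unname(f$B), unname(B), tolerance = 1e-8)
})

test_that("rotation-based GLS equals the dense 2n x 2n oracle", {
  set.seed(6)
  for (rep in 1:10) {
    n <- 8; k <- 3
    K <- rand_kinship(n)
    A1 <- rand_alleles(n, k); A2 <- rand_alleles(n, k)
    Vg <- rand_spd2(); Ve <- rand_spd2()
    Y <- rand_traits(rownames(K))
    f <- gls_fit(Y, pvl_design(A1, A2), K, var_comp(Vg, Ve))
    o <- dense_gls_oracle(unclass(Y), A1, A2, unclass(K), Vg, Ve)
    expect_equal(f$loglik10, o$ll10, tolerance = 1e-8)
    got <- c(f$coefficients$trait1, f$coefficients$trait2)
    expect_equal(unname(got), unname(o$beta), tolerance = 1e-8)
  }
})

test_that("GLS log-likelihood is invariant to consistent subject permutation", {
  set.seed(8)
  n <- 12
  K <- rand_kinship(n)
  A <- rand_alleles(n, 3)
  Y <- rand_traits(rownames(K))
  vc <- var_comp(rand_spd2(), rand_spd2())
  f1 <- gls_fit(Y, pvl_design(A, A), K, vc)
  perm <- sample(n)
  Kp <- kinship_matrix(unclass(K)[perm, perm])
  f2 <- gls_fit(trait_pair(unclass(Y)[perm, ]), pvl_design(A[perm, ], A[perm, ]),
                Kp, vc)
  expect_equal(f1$loglik10, f2$loglik10, tolerance = 1e-9)
  expect_equal(f1$B, f2$B, tolerance = 1e-9)
})

test_that("rank-deficient designs are fatal and name the collinear columns", {
  set.seed(9)
  n <- 10
  K <- rand_kinship(n)
  A <- rand_alleles(n, 3)
  A_bad <- cbind(A, dup = A[, 1])
  colnames(A_bad) <- c("a1", "a2", "a3", "dup")
  Y <- rand_traits(rownames(K))
  expect_error(gls_fit(Y, pvl_design(A_bad, A), K, var_comp(diag(2), diag(2))),
               "collinear.*dup")
})

test_that("EM-REML has a nondecreasing restricted likelihood and PSD iterates", {
  set.seed(10)
  n <- 40
  K <- spread_kinship(n, seed = 2)
  Y <- simulate_traits(pvl_design(NULL, NULL, n = n),
                       matrix(0, 1, 2), var_comp(diag(2), diag(2)), K, seed = 1)
  fit <- reml_fit_null(Y, kin = K)
  tr <- attr(fit, "ll10_trace")
  expect_gt(length(tr), 3)
  expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
  for (V in fit) {
    expect_lt(max(abs(V - t(V))), 1e-10)
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("EM-REML converges to the dense REML optimum", {
  set.seed(12)
  n <- 14
  K <- spread_kinship(n, seed = 3)
  Y <- simulate_traits(pvl_design(NULL, NULL, n = n), matrix(c(1, -1), 1, 2),
                       var_comp(matrix(c(1, .5, .5, 1), 2), diag(2)), K,
                       seed = 2)
  fit <- reml_fit_null(Y, kin = K, tol = 1e-9, maxit = 50000L)
  em_rll <- utils::tail(attr(fit, "ll10_trace"), 1) * log(10)
  o <- dense_reml_oracle(unclass(Y), matrix(1, n, 1), unclass(K),
                         fit$Vg, fit$Ve)
  # starting BFGS at the EM solution must not find a materially better point
  expect_lt(o$rll - em_rll, 1e-3)
  expect_equal(fit$Vg, o$Vg, tolerance = 0.02)
  expect_equal(fit$Ve, o$Ve, tolerance = 0.02)
})

test_that("re-running EM from the converged estimates is a fixed point", {
  set.seed(13)
  n <- 30
  K <- spread_kinship(n, seed = 5)
  Y <- simulate_traits(pvl_design(NULL, NULL, n = n), matrix(0, 1, 2),
                       var_comp(diag(2), diag(2)), K, seed = 3)
  fit <- reml_fit_null(Y, kin = K, tol = 1e-8)
  refit <- suppressWarnings(reml_fit_null(Y, kin = K, tol = 1e-8, maxit = 2,
                                          init = fit))
  tr <- attr(refit, "ll10_trace")
  if (length(tr) > 1) {
    expect_lt(abs(diff(tr)[1]) * log(10), 1e-6 * (abs(tr[1] * log(10)) + 1))
  }
  expect_equal(refit$Vg, fit$Vg, tolerance = 1e-4)
})

test_that("identity kinship triggers the confounding warning", {
  n <- 12
  K <- diag(n); dimnames(K) <- list(paste0("s", 1:n), paste0("s", 1:n))
  Y <- rand_traits(paste0("s", 1:n))
  expect_warning(reml_fit_null(Y, kin = kinship_matrix(K)), "confounded")
})
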