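# Independent brute-force oracles: these form the dense 2n x 2n covariance
# explicitly and never share code with the rotation-based implementation.

# dense GLS + Gaussian log10-likelihood for a two-block design
dense_gls_oracle <- function(Y, X1, X2, K, Vg, Ve) {
  n <- nrow(Y)
  S <- kronecker(Vg, K) + kronecker(Ve, diag(n))
  Xf <- matrix(0, 2 * n, ncol(X1) + ncol(X2))
  Xf[seq_len(n), seq_len(ncol(X1))] <- X1
  Xf[n + seq_len(n), ncol(X1) + seq_len(ncol(X2))] <- X2
  y <- c(Y)
  Si <- solve(S)
  beta <- solve(t(Xf) %*% Si %*% Xf, t(Xf) %*% Si %*% y)
  r <- y - Xf %*% beta
  ll <- -0.5 * (2 * n * log(2 * pi) +
                  as.numeric(determinant(S)$modulus) +
                  drop(t(r) %*% Si %*% r))
  list(beta = drop(beta), ll10 = ll / log(10))
}

# dense restricted log-likelihood of (Vg, Ve) under the covariates-only model
dense_restricted_ll <- function(Vg, Ve, Y, X0, K) {
  n <- nrow(Y)
  S <- kronecker(Vg, K) + kronecker(Ve, diag(n))
  Xf <- kronecker(diag(2), X0)
  Si <- solve(S)
  C <- t(Xf) %*% Si %*% Xf
  beta <- solve(C, t(Xf) %*% Si %*% c(Y))
  r <- c(Y) - Xf %*% beta
  drop(-0.5 * ((2 * n - ncol(Xf)) * log(2 * pi) +
                 as.numeric(determinant(S)$modulus) +
                 as.numeric(determinant(C)$modulus) +
                 t(r) %*% Si %*% r))
}

# maximize the dense restricted ll over (Vg, Ve) via log-Cholesky + BFGS
dense_reml_oracle <- function(Y, X0, K, init_Vg, init_Ve) {
  chol_par <- function(V) {
    L <- t(chol(V + diag(2) * 1e-9))
    c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
  }
  unpar <- function(th) {
    L <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, byrow = FALSE)
    tcrossprod(L)
  }
  nll <- function(th) {
    -dense_restricted_ll(unpar(th[1:3]), unpar(th[4:6]), Y, X0, K)
  }
  o <- stats::optim(c(chol_par(init_Vg), chol_par(init_Ve)), nll,
                    method = "BFGS", control = list(maxit = 1000,
                                                    reltol = 1e-14))
  list(Vg = unpar(o$par[1:3]), Ve = unpar(o$par[4:6]), rll = -o$value)
}

# random symmetric positive-definite 2x2
rand_spd2 <- function() {
  A <- matrix(stats::rnorm(4), 2)
  crossprod(A) / 2 + diag(2) * 0.3
}

# random PSD kinship with subject IDs
rand_kinship <- function(n) {
  Z <- matrix(stats::rnorm(n * n), n)
  K <- tcrossprod(Z) / n
  K <- (K + t(K)) / 2
  rownames(K) <- colnames(K) <- paste0("s", seq_len(n))
  kinship_matrix(K)
}

# random allele-probability matrix (rows sum to 1)
rand_alleles <- function(n, k) {
  A <- matrix(stats::rexp(n * k), n)
  A / rowSums(A)
}

# random named trait pair on the given subject ids
rand_traits <- function(ids) {
  Y <- matrix(stats::rnorm(2 * length(ids)), ncol = 2,
              dimnames = list(ids, c("y1", "y2")))
  trait_pair(Y)
}

# small synthetic genome shared across tests
tiny_genome <- function(n = 60, seed = 11,
                        chroms = chrom_table(c("1", "2"), c(10, 10), c(11, 11))) {
  generate_genome(genome_spec(n_subjects = n, chromosomes = chroms),
                  seed = seed)
}

# kinship with well-spread eigenvalues for variance-component recovery
spread_kinship <- function(n, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(n * n), n)))
  ev <- seq(0.05, 2, length.out = n)
  K <- Q %*% (ev * t(Q))
  K <- (K + t(K)) / 2
  rownames(K) <- colnames(K) <- paste0("s", seq_len(n))
  kinship_matrix(K)
}
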