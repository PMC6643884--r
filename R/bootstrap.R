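# Parametric-bootstrap calibration of the pleiotropy LOD statistic.

# eigen-based symmetric square root of a PSD matrix
psd_sqrt <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("matrix is not positive semidefinite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate a trait pair from the bivariate mixed model
#'
#' Draws `Y = mean + G + E` where the mean is `X vec(B)` unstacked to n x 2,
#' `G` is matrix-normal with row covariance `K` and column covariance `Vg`,
#' and `E` is matrix-normal with identity row covariance and column covariance
#' `Ve`.  Identical seeds give bit-identical output.
#'
#' @param X a [pvl_design] (for bootstrap simulation: the pleiotropic design at
#'   the inferred common QTL position).
#' @param B effect matrix, one column per trait (as returned in a
#'   [gls_fit()]'s `B`).
#' @param varcomp a [var_comp].
#' @param kin n x n kinship matrix (PSD).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param kin_sqrt optional precomputed [psd_sqrt()] of `kin`.
#' @return a [trait_pair] matrix (subject IDs from the design rownames or
#'   `kin`).
#' @export
simulate_traits <- function(X, B, varcomp, kin, seed = NULL, kin_sqrt = NULL) {
  stopifnot(inherits(X, "pvl_design"), inherits(varcomp, "var_comp"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X$X1)
  B <- as.matrix(B)
  if (nrow(B) != ncol(X$X1) || ncol(B) != 2L) {
    stop("`B` must be (k+c) x 2, matching the design blocks")
  }
  mu <- cbind(X$X1 %*% B[, 1], X$X2 %*% B[, 2])
  if (is.null(kin_sqrt)) kin_sqrt <- psd_sqrt(unclass(as.matrix(kin)))
  G <- kin_sqrt %*% matrix(stats::rnorm(2 * n), n, 2) %*% psd_sqrt(varcomp$Vg)
  E <- matrix(stats::rnorm(2 * n), n, 2) %*% psd_sqrt(varcomp$Ve)
  Y <- mu + G + E
  ids <- rownames(as.matrix(kin))
  rownames(Y) <- if (!is.null(ids)) ids else paste0("s", seq_len(n))
  colnames(Y) <- c("trait1", "trait2")
  trait_pair(Y)
}

#' @rdname simulate_traits
#' @param object a [scan_pvl()] result; simulation uses its fitted pleiotropic
#'   model (effects at the pleiotropic peak and the null variance components).
#' @param nsim number of trait pairs to simulate.
#' @param ... unused.
#' @return for the `simulate` method, a list of `nsim` [trait_pair] matrices.
#' @export
simulate.pvl_scan <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eng <- object$engine
  A <- unclass(eng$probs)[, , eng$probs_idx[which.max(diag(object$grid))]]
  X <- pvl_design(A, covar = eng$covar)
  ks <- psd_sqrt(unclass(as.matrix(eng$kin)))
  replicate(nsim,
            simulate_traits(X, object$pleio_fit$B, object$varcomp, eng$kin,
                            seed = NULL, kin_sqrt = ks),
            simplify = FALSE)
}

# derive one reproducible child seed per replicate from a master seed, so
# parallel and serial execution give identical replicate streams
child_seeds <- function(seed, b) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, b)
}

# core bootstrap loop on a prebuilt engine; Y is the observed (aligned) trait
# matrix.  Returns observed lod, replicate lods, pvalue.
engine_boot <- function(eng, Y, b, seed, reuse_varcomp = FALSE, cores = 1L,
                        tol = 1e-6, maxit = 10000L) {
  if (b < 1L) stop("`b` must be at least 1")
  varcomp <- engine_reml(eng, Y, tol = tol, maxit = maxit)
  grid <- engine_grid(eng, Y, varcomp)
  observed_lod <- lod_statistic(grid)
  ipleio <- which.max(diag(grid))
  A <- unclass(eng$probs)[, , eng$probs_idx[ipleio]]
  X <- pvl_design(A, covar = eng$covar)
  Xr <- list(X1 = crossprod(eng$U, X$X1), X2 = crossprod(eng$U, X$X2))
  fit <- cpp_gls_pair(Xr$X1, Xr$X2, crossprod(eng$U, Y), eng$d,
                      varcomp$Vg, varcomp$Ve)
  B <- cbind(fit$beta1, fit$beta2)
  ks <- eng$U %*% (sqrt(eng$d) * t(eng$U))  # psd sqrt of K from cached eigen
  seeds <- child_seeds(seed, b)
  one_rep <- function(r) {
    set.seed(seeds[r])
    n <- nrow(Y)
    mu <- cbind(X$X1 %*% B[, 1], X$X2 %*% B[, 2])
    G <- ks %*% matrix(stats::rnorm(2 * n), n, 2) %*% psd_sqrt(varcomp$Vg)
    E <- matrix(stats::rnorm(2 * n), n, 2) %*% psd_sqrt(varcomp$Ve)
    Ysim <- mu + G + E
    # re-estimate per replicate; warm-started at the observed-data estimates,
    # which changes only the iteration count, not the REML optimum
    vc <- if (reuse_varcomp) varcomp else
      engine_reml(eng, Ysim, tol = tol, maxit = maxit, init = varcomp)
    lod_statistic(engine_grid(eng, Ysim, vc))
  }
  replicate_lods <- if (cores > 1L) {
    unlist(parallel::mclapply(seq_len(b), one_rep, mc.cores = cores))
  } else {
    vapply(seq_len(b), one_rep, numeric(1))
  }
  if (any(!is.finite(replicate_lods))) {
    stop("bootstrap replicate ", which(!is.finite(replicate_lods))[1],
         " failed to produce a finite LOD")
  }
  list(observed_lod = observed_lod,
       replicate_lods = replicate_lods,
       pvalue = mean(replicate_lods >= observed_lod),
       varcomp = varcomp,
       null_position = eng$positions[ipleio],
       null_marker = eng$markers[ipleio])
}

#' Parametric bootstrap for the pleiotropy test
#'
#' Calibrates the LOD statistic of [scan_pvl()].  The procedure: (1) estimate
#' the variance components under the no-QTL null; (2) scan the interval and
#' record the observed LOD; (3) locate the pleiotropic peak (the diagonal
#' maximum) and refit the allele and covariate effects there; (4) simulate `b`
#' trait pairs from that fitted pleiotropic model, and for each one re-estimate
#' the null variance components and rescan the interval to obtain a bootstrap
#' LOD; (5) report `p = #\{LOD*_i >= LOD\} / b`.
#'
#' A master seed spawns one child seed per replicate, so results are identical
#' whether replicates run serially or in parallel.
#'
#' @inheritParams scan_pvl
#' @param b number of bootstrap replicates (>= 1).
#' @param seed master integer seed.
#' @param reuse_varcomp if `TRUE`, reuse the observed-data variance components
#'   for every replicate instead of re-estimating (faster; off by default).
#' @param cores number of worker processes for the replicate loop.
#' @return object of class `pvl_boot`: list with `observed_lod`,
#'   `replicate_lods`, `b`, `pvalue`, `seed`, `null_position` (cM of the
#'   pleiotropic peak used for simulation), `null_marker`, `varcomp`.
#' @export
boot_pvl <- function(probs, traits, covar = NULL, kin, interval = NULL,
                     b = 400L, seed = 1L, reuse_varcomp = FALSE, cores = 1L,
                     tol = 1e-6, maxit = 10000L) {
  if (b < 1L) stop("`b` must be at least 1")
  al <- align_inputs(probs, traits, covar, kin)
  eng <- pvl_engine(al$probs, al$covar, al$kin, interval)
  res <- engine_boot(eng, unclass(as.matrix(al$traits)), b = b, seed = seed,
                     reuse_varcomp = reuse_varcomp, cores = cores,
                     tol = tol, maxit = maxit)
  structure(c(res, list(b = as.integer(b), seed = as.integer(seed),
                        trait_names = colnames(al$traits))),
            class = "pvl_boot")
}

#' @export
print.pvl_boot <- function(x, ...) {
  cat(sprintf("Parametric bootstrap, pleiotropy vs. separate QTL (%s, %s)\n",
              x$trait_names[1], x$trait_names[2]))
  cat(sprintf("  observed LOD = %.4f\n", x$observed_lod))
  cat(sprintf("  b = %d replicates simulated at the pleiotropic peak (%.2f cM)\n",
              x$b, x$null_position))
  cat(sprintf("  p-value = %.4g\n", x$pvalue))
  invisible(x)
}
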