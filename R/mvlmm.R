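# Bivariate linear mixed model with Kronecker covariance:
#   vec(Y) = X vec(B) + vec(G) + vec(E),
#   G ~ MN(0, K, Vg),  E ~ MN(0, I, Ve),
# so vec(Y) ~ N(X vec(B), Vg (x) K + Ve (x) I).  Everything is evaluated in
# the eigenbasis of K, where the covariance is block diagonal per subject.

#' Variance-component pair
#'
#' Bundle the 2 x 2 genetic (`Vg`) and residual (`Ve`) covariance matrices of
#' a trait pair, validating symmetry and positive semidefiniteness.
#'
#' @param Vg,Ve numeric 2 x 2 symmetric PSD matrices.
#' @return object of class `var_comp`: `list(Vg, Ve)`.
#' @export
var_comp <- function(Vg, Ve) {
  chk <- function(V, nm) {
    V <- as.matrix(V)
    if (!all(dim(V) == c(2L, 2L))) stop(nm, " must be 2 x 2")
    if (max(abs(V - t(V))) > 1e-8) stop(nm, " is not symmetric")
    if (min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop(nm, " is not positive semidefinite")
    }
    (V + t(V)) / 2
  }
  structure(list(Vg = chk(Vg, "Vg"), Ve = chk(Ve, "Ve")), class = "var_comp")
}

#' @export
print.var_comp <- function(x, ...) {
  cat("Genetic covariance (Vg):\n")
  print(round(x$Vg, 4))
  cat("Residual covariance (Ve):\n")
  print(round(x$Ve, 4))
  if (!is.null(attr(x, "converged")) && !attr(x, "converged")) {
    cat("(EM-REML did not converge; last iterate shown)\n")
  }
  invisible(x)
}

#' Dense phenotype covariance matrix
#'
#' Forms the full 2n x 2n covariance `Vg %x% K + Ve %x% I` of the stacked
#' trait vector `vec(Y)` (column-major: the first n entries are trait 1).
#' Intended for small problems and cross-checks; the fitting code never forms
#' this matrix.
#'
#' @param varcomp a [var_comp] object.
#' @param kin n x n kinship matrix.
#' @return 2n x 2n numeric matrix.
#' @export
build_sigma <- function(varcomp, kin) {
  stopifnot(inherits(varcomp, "var_comp"))
  K <- unclass(as.matrix(kin))
  kronecker(varcomp$Vg, K) + kronecker(varcomp$Ve, diag(nrow(K)))
}

#' Block-diagonal design for a trait pair
#'
#' Builds the two per-trait design blocks of the bivariate model.  When
#' founder-allele dosages are supplied for a trait, its block is
#' `[alleles | covariates]` with no intercept column, because the k dosages
#' sum to one and already span the intercept; the no-QTL null design uses
#' `[1 | covariates]`.
#'
#' @param alleles1,alleles2 n x k matrices of founder-allele probabilities at
#'   the QTL position for trait 1 / trait 2, or `NULL` for a no-QTL block.
#'   `alleles2` defaults to `alleles1` (a pleiotropic design).
#' @param covar optional n x c covariate matrix (no intercept column).
#' @param n number of subjects; required only when both allele blocks are
#'   `NULL` and `covar` is `NULL`.
#' @return object of class `pvl_design`: list with elements `X1`, `X2`.
#' @export
pvl_design <- function(alleles1 = NULL, alleles2 = alleles1, covar = NULL,
                       n = NULL) {
  block <- function(A) {
    if (is.null(A)) {
      nn <- if (!is.null(covar)) nrow(covar) else n
      if (is.null(nn)) stop("supply `n` when a block has neither alleles nor covariates")
      X <- matrix(1, nn, 1, dimnames = list(NULL, "intercept"))
    } else {
      X <- as.matrix(A)
      if (is.null(colnames(X))) colnames(X) <- paste0("allele", seq_len(ncol(X)))
    }
    if (!is.null(covar) && ncol(covar) > 0) {
      cv <- as.matrix(covar)
      if (is.null(colnames(cv))) colnames(cv) <- paste0("covar", seq_len(ncol(cv)))
      X <- cbind(X, cv)
    }
    X
  }
  x <- structure(list(X1 = block(alleles1), X2 = block(alleles2)),
                 class = "pvl_design")
  if (nrow(x$X1) != nrow(x$X2)) stop("trait blocks have differing numbers of subjects")
  x
}

#' @export
as.matrix.pvl_design <- function(x, ...) {
  n <- nrow(x$X1)
  p1 <- ncol(x$X1); p2 <- ncol(x$X2)
  out <- matrix(0, 2 * n, p1 + p2)
  out[seq_len(n), seq_len(p1)] <- x$X1
  out[n + seq_len(n), p1 + seq_len(p2)] <- x$X2
  colnames(out) <- c(paste0("t1:", colnames(x$X1)), paste0("t2:", colnames(x$X2)))
  out
}

# check a design block for rank deficiency; report offending columns
check_full_rank <- function(X, label) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design (%s): collinear columns: %s",
                 label, paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

# eigendecomposition of a kinship matrix, cached-friendly
kinship_eigen <- function(kin) {
  e <- eigen(unclass(as.matrix(kin)), symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  e
}

#' Generalized least squares fit at fixed variance components
#'
#' Solves the GLS normal equations
#' `vec(B-hat) = (X' S^-1 X)^-1 X' S^-1 vec(Y)` with
#' `S = Vg %x% K + Ve %x% I`, and evaluates the log10 Gaussian likelihood of
#' `vec(Y)` at mean `X vec(B-hat)` and covariance `S`.  The computation uses
#' the eigendecomposition of K rather than forming S, but agrees with the
#' dense solve to numerical precision.
#'
#' @param traits n x 2 trait matrix ([trait_pair] or plain matrix).
#' @param X a [pvl_design].
#' @param kin n x n kinship matrix.
#' @param varcomp a [var_comp] (held fixed; typically from [reml_fit_null()]).
#' @param eig optional precomputed `eigen(kin)` to reuse across fits.
#' @return object of class `pvl_fit`: list with `B` ((k+c) x 2 effect matrix),
#'   `loglik10`, and the `varcomp` used.
#' @export
gls_fit <- function(traits, X, kin, varcomp, eig = NULL) {
  stopifnot(inherits(X, "pvl_design"), inherits(varcomp, "var_comp"))
  Y <- unclass(as.matrix(traits))
  if (any(!is.finite(Y))) stop("traits contain non-finite values; align inputs first")
  n <- nrow(Y)
  if (nrow(X$X1) != n) stop("design and traits have differing numbers of subjects")
  check_full_rank(X$X1, "trait 1 block")
  check_full_rank(X$X2, "trait 2 block")
  if (is.null(eig)) eig <- kinship_eigen(kin)
  U <- eig$vectors
  Yr <- crossprod(U, Y)
  fit <- cpp_gls_pair(crossprod(U, X$X1), crossprod(U, X$X2), Yr,
                      eig$values, varcomp$Vg, varcomp$Ve)
  b1 <- stats::setNames(drop(fit$beta1), colnames(X$X1))
  b2 <- stats::setNames(drop(fit$beta2), colnames(X$X2))
  B <- if (length(b1) == length(b2)) cbind(b1, b2) else NULL
  if (!is.null(B)) {
    dimnames(B) <- list(colnames(X$X1), colnames(unclass(as.matrix(traits))))
  }
  structure(list(B = B, coefficients = list(trait1 = b1, trait2 = b2),
                 loglik10 = fit$loglik10, varcomp = varcomp),
            class = "pvl_fit")
}

#' @export
print.pvl_fit <- function(x, ...) {
  cat(sprintf("<pvl_fit> log10-likelihood %.4f\n", x$loglik10))
  if (!is.null(x$B)) print(round(x$B, 4))
  invisible(x)
}

#' @export
coef.pvl_fit <- function(object, ...) {
  if (!is.null(object$B)) object$B else object$coefficients
}

#' @export
logLik.pvl_fit <- function(object, ...) {
  structure(object$loglik10 * log(10), class = "logLik", df = NA_integer_,
            nobs = NA_integer_)
}

#' EM-REML variance components under the no-QTL null
#'
#' Estimates the 2 x 2 genetic (`Vg`) and residual (`Ve`) covariance matrices
#' of a trait pair by restricted maximum likelihood under the null model with
#' intercept and covariates only, using an expectation-maximization algorithm
#' in the eigenbasis of the kinship matrix.  The restricted log-likelihood is
#' nondecreasing across iterations.  These estimates are then held fixed
#' throughout the two-dimensional scan.
#'
#' @param traits n x 2 trait matrix.
#' @param covar optional n x c covariate matrix (intercept added internally).
#' @param kin n x n kinship matrix (PSD).
#' @param tol convergence tolerance: stop when the relative change in the
#'   restricted log-likelihood falls below `tol`.
#' @param maxit maximum EM iterations; if reached without convergence the last
#'   iterate is returned with a warning and `converged = FALSE`.
#' @param standardize if `TRUE`, z-scale each trait before fitting (off by
#'   default; traits are analyzed as given).
#' @param eig optional precomputed `eigen(kin)`.
#' @param init optional [var_comp] used as the EM starting point.  The default
#'   start sets both `Vg` and `Ve` to half the residual covariance of an
#'   ordinary covariates-only regression.
#' @return a [var_comp] with attributes `ll10_trace` (restricted
#'   log10-likelihood per iteration), `converged`, and `n_iter`.
#' @export
reml_fit_null <- function(traits, covar = NULL, kin, tol = 1e-6,
                          maxit = 10000L, standardize = FALSE, eig = NULL,
                          init = NULL) {
  Y <- unclass(as.matrix(traits))
  if (any(!is.finite(Y))) stop("traits contain non-finite values; align inputs first")
  n <- nrow(Y)
  if (standardize) Y <- scale(Y)
  X0 <- cbind(intercept = rep(1, n),
              if (!is.null(covar)) unclass(as.matrix(covar)))
  if (n <= ncol(X0) + 1L) stop("too few subjects to estimate variance components")
  check_full_rank(X0, "null design")
  if (is.null(eig)) eig <- kinship_eigen(kin)
  if (stats::sd(eig$values) < 1e-10) {
    warning("kinship eigenvalues are all equal (e.g. K = identity): ",
            "Vg and Ve are confounded")
  }
  U <- eig$vectors
  Yr <- crossprod(U, Y)
  X0r <- crossprod(U, X0)
  if (is.null(init)) {
    # scale-appropriate symmetric start: half the OLS residual covariance
    res <- stats::lm.fit(X0r, Yr)$residuals
    V0 <- crossprod(res) / n / 2 + diag(2) * 1e-6
    Vg0 <- Ve0 <- V0
  } else {
    stopifnot(inherits(init, "var_comp"))
    Vg0 <- init$Vg + diag(2) * 1e-8
    Ve0 <- init$Ve + diag(2) * 1e-8
  }
  fit <- cpp_reml_em(Yr, X0r, eig$values, Vg0, Ve0, as.integer(maxit), tol, 1e-8)
  if (!fit$converged) {
    warning(sprintf("EM-REML did not converge in %d iterations; returning last iterate",
                    maxit))
  }
  out <- var_comp(fit$Vg, fit$Ve)
  attr(out, "ll10_trace") <- fit$ll10_trace
  attr(out, "converged") <- fit$converged
  attr(out, "n_iter") <- fit$n_iter
  out
}
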