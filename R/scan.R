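# Two-dimensional, two-QTL scan and the pleiotropy vs. separate-QTL LOD.

# Internal "engine": everything that can be rotated once per (genotypes,
# covariates, kinship, interval) and reused across many phenotype vectors
# (bootstrap replicates, simulation studies).
pvl_engine <- function(probs, covar = NULL, kin, interval = NULL) {
  stopifnot(inherits(probs, "alleleprob"))
  map <- attr(probs, "map")
  if (is.null(interval)) interval <- range(map)
  if (length(interval) != 2L || interval[1] > interval[2]) {
    stop("`interval` must be c(low, high) in cM with low <= high")
  }
  idx <- which(map >= interval[1] - 1e-9 & map <= interval[2] + 1e-9)
  if (length(idx) < 2L) stop("scan interval contains fewer than 2 markers")
  n <- dim(probs)[1]
  k <- dim(probs)[2]
  cv <- if (!is.null(covar) && ncol(covar) > 0) unclass(as.matrix(covar)) else
    matrix(0, n, 0)
  # per-marker rank pre-check so failures name the marker
  for (j in idx) {
    Xj <- cbind(unclass(probs)[, , j], cv)
    qx <- qr(Xj)
    if (qx$rank < ncol(Xj)) {
      stop(sprintf("rank-deficient design at marker %s (%.3f cM)",
                   dimnames(probs)[[3]][j], map[j]))
    }
  }
  eig <- kinship_eigen(kin)
  U <- eig$vectors
  Pr <- array(0, dim = c(n, k, length(idx)))
  for (s in seq_along(idx)) Pr[, , s] <- crossprod(U, unclass(probs)[, , idx[s]])
  X0 <- cbind(intercept = rep(1, n), cv)
  list(U = U, d = eig$values, Pr = Pr,
       Covr = if (ncol(cv) > 0) crossprod(U, cv) else matrix(0, n, 0),
       X0r = crossprod(U, X0),
       markers = dimnames(probs)[[3]][idx], positions = unname(map[idx]),
       founders = dimnames(probs)[[2]], n = n, k = k,
       probs_idx = idx, probs = probs, covar = covar, kin = kin)
}

engine_reml <- function(eng, Y, tol = 1e-6, maxit = 10000L, init = NULL) {
  Yr <- crossprod(eng$U, Y)
  if (is.null(init)) {
    res <- stats::lm.fit(eng$X0r, Yr)$residuals
    V0 <- crossprod(res) / nrow(Y) / 2 + diag(2) * 1e-6
    Vg0 <- Ve0 <- V0
  } else {
    Vg0 <- init$Vg + diag(2) * 1e-8
    Ve0 <- init$Ve + diag(2) * 1e-8
  }
  fit <- cpp_reml_em(Yr, eng$X0r, eng$d, Vg0, Ve0, as.integer(maxit), tol, 1e-8)
  out <- var_comp(fit$Vg, fit$Ve)
  attr(out, "ll10_trace") <- fit$ll10_trace
  attr(out, "converged") <- fit$converged
  attr(out, "n_iter") <- fit$n_iter
  out
}

engine_grid <- function(eng, Y, varcomp) {
  Yr <- crossprod(eng$U, Y)
  g <- cpp_scan_grid(eng$Pr, eng$Covr, Yr, eng$d, varcomp$Vg, varcomp$Ve)
  dimnames(g) <- list(eng$markers, eng$markers)
  g
}

#' LOD statistic for pleiotropy vs. separate QTL
#'
#' The log10 likelihood-ratio statistic: the maximum of the log10-likelihood
#' surface over all ordered position pairs minus its maximum along the
#' diagonal (where the two QTL coincide).  Always nonnegative because the
#' pleiotropic models are a subset of the two-QTL models.
#'
#' @param grid m x m matrix of log10 likelihoods (entry `[i, j]` has the
#'   trait-1 QTL at position i and the trait-2 QTL at position j), or a
#'   [scan_pvl()] result.
#' @return scalar LOD.
#' @export
lod_statistic <- function(grid) {
  if (inherits(grid, "pvl_scan")) grid <- grid$grid
  grid <- as.matrix(grid)
  if (nrow(grid) != ncol(grid)) stop("likelihood grid must be square")
  if (any(!is.finite(grid))) stop("likelihood grid contains non-finite entries")
  max(grid) - max(diag(grid))
}

#' Profile LOD traces
#'
#' Converts the two-dimensional log10-likelihood surface into the three traces
#' used to visualize the test: `profile1[i] = max_j ll10[i, j] - max_diag`,
#' `profile2[j] = max_i ll10[i, j] - max_diag`, and the pleiotropy trace
#' `pleio[i] = ll10[i, i] - max_diag`.  The two profile traces share the same
#' maximum, which equals the LOD statistic; the pleiotropy trace has maximum
#' zero.
#'
#' @param grid m x m log10-likelihood matrix or a [scan_pvl()] result.
#' @param positions optional marker positions (cM) for the rows/columns.
#' @return object of class `pvl_traces`: a data frame with columns `position`,
#'   `profile1`, `profile2`, `pleio`, plus attribute `lod`.
#' @export
profile_traces <- function(grid, positions = NULL) {
  if (inherits(grid, "pvl_scan")) {
    if (is.null(positions)) positions <- grid$positions
    grid <- grid$grid
  }
  grid <- as.matrix(grid)
  m <- nrow(grid)
  if (is.null(positions)) positions <- seq_len(m)
  max_diag <- max(diag(grid))
  out <- data.frame(position = positions,
                    profile1 = apply(grid, 1, max) - max_diag,
                    profile2 = apply(grid, 2, max) - max_diag,
                    pleio = diag(grid) - max_diag)
  rownames(out) <- rownames(grid)
  structure(out, lod = max(grid) - max_diag,
            class = c("pvl_traces", "data.frame"))
}

#' Two-dimensional two-QTL scan for a trait pair
#'
#' For every ordered pair of marker positions in the interval, fits the
#' bivariate mixed model with the trait-1 QTL at the first position and the
#' trait-2 QTL at the second, by GLS at variance components held fixed from
#' the no-QTL null fit.  The resulting log10-likelihood surface yields the
#' pleiotropy-vs-separate-QTL LOD statistic and the profile traces.
#'
#' @param probs an [alleleprob] array for the chromosome under test.
#' @param traits a [trait_pair] (or plain n x 2 matrix with subject IDs as
#'   rownames).
#' @param covar optional [covariate_matrix].
#' @param kin a [kinship_matrix], preferably leave-one-chromosome-out for this
#'   chromosome.
#' @param interval `c(low, high)` in cM; endpoints inclusive.  Default: the
#'   whole chromosome.  The scan grid consists of the observed markers inside
#'   the interval (no pseudomarkers).
#' @param varcomp optional [var_comp]; if `NULL` (the default), estimated by
#'   [reml_fit_null()] on the aligned data.
#' @param tol,maxit passed to the EM-REML fit when `varcomp` is `NULL`.
#' @return object of class `pvl_scan`: list with elements `grid` (m x m log10
#'   likelihoods), `positions`, `markers`, `lod`, `traces` (a
#'   [profile_traces()] data frame), `varcomp`, `pleio_fit` (the GLS fit at
#'   the pleiotropic peak), `peak` (peak positions), `n`, `trait_names`.
#' @seealso [boot_pvl()] for significance, [plot.pvl_scan()] for the
#'   profile-trace figure.
#' @export
#' @examples
#' g <- generate_genome(genome_spec(n_subjects = 60), seed = 4)
#' eff <- make_effects(6, "ABCD:EFGH")
#' yy <- sim_trait_pair(g$probs[[1]], marker1 = 11, marker2 = 11,
#'                      effects = eff, varcomp = var_comp(diag(2), diag(2)),
#'                      kin = g$kinship[[1]], seed = 7)
#' s <- scan_pvl(g$probs[[1]], yy, kin = g$kinship[[1]], interval = c(8, 12))
#' s$lod
scan_pvl <- function(probs, traits, covar = NULL, kin, interval = NULL,
                     varcomp = NULL, tol = 1e-6, maxit = 10000L) {
  al <- align_inputs(probs, traits, covar, kin)
  eng <- pvl_engine(al$probs, al$covar, al$kin, interval)
  Y <- unclass(as.matrix(al$traits))
  if (is.null(varcomp)) varcomp <- engine_reml(eng, Y, tol = tol, maxit = maxit)
  stopifnot(inherits(varcomp, "var_comp"))
  grid <- engine_grid(eng, Y, varcomp)
  traces <- profile_traces(grid, eng$positions)
  ipleio <- which.max(diag(grid))  # first index on ties
  imax <- arrayInd(which.max(grid), dim(grid))
  A <- unclass(al$probs)[, , eng$probs_idx[ipleio]]
  pleio_fit <- gls_fit(al$traits, pvl_design(A, covar = al$covar), al$kin,
                       varcomp)
  structure(list(grid = grid, positions = eng$positions,
                 markers = eng$markers, lod = attr(traces, "lod"),
                 traces = traces, varcomp = varcomp, pleio_fit = pleio_fit,
                 peak = list(
                   pleio = c(position = eng$positions[ipleio]),
                   pleio_marker = eng$markers[ipleio],
                   full = c(position1 = eng$positions[imax[1]],
                            position2 = eng$positions[imax[2]])),
                 n = eng$n, trait_names = colnames(al$traits),
                 interval = range(eng$positions), engine = eng,
                 traits = al$traits, call = match.call()),
            class = "pvl_scan")
}

#' @export
print.pvl_scan <- function(x, ...) {
  cat(sprintf("Pleiotropy vs. separate-QTL scan: %s and %s\n",
              x$trait_names[1], x$trait_names[2]))
  cat(sprintf("  %d markers in [%.2f, %.2f] cM, n = %d subjects\n",
              length(x$positions), x$interval[1], x$interval[2], x$n))
  cat(sprintf("  LOD (separate QTL vs. pleiotropy) = %.4f\n", x$lod))
  cat(sprintf("  pleiotropic peak at %.2f cM; separate-QTL peak at (%.2f, %.2f) cM\n",
              x$peak$pleio["position"], x$peak$full["position1"],
              x$peak$full["position2"]))
  invisible(x)
}

#' @export
summary.pvl_scan <- function(object, ...) {
  out <- list(trait_names = object$trait_names, n = object$n,
              interval = object$interval, n_markers = length(object$positions),
              lod = object$lod, peak = object$peak,
              varcomp = object$varcomp,
              allele_effects = coef(object))
  class(out) <- "summary.pvl_scan"
  out
}

#' @export
print.summary.pvl_scan <- function(x, ...) {
  cat(sprintf("Pleiotropy vs. separate-QTL scan: %s and %s\n",
              x$trait_names[1], x$trait_names[2]))
  cat(sprintf("  n = %d, %d markers in [%.2f, %.2f] cM\n", x$n, x$n_markers,
              x$interval[1], x$interval[2]))
  cat(sprintf("  LOD = %.4f\n", x$lod))
  cat(sprintf("  pleiotropic peak: %.2f cM (marker %s)\n",
              x$peak$pleio["position"], x$peak$pleio_marker))
  cat(sprintf("  separate-QTL peak: (%.2f, %.2f) cM\n\n",
              x$peak$full["position1"], x$peak$full["position2"]))
  print(x$varcomp)
  cat("\nEffects at the pleiotropic peak:\n")
  print(round(x$allele_effects, 4))
  invisible(x)
}

#' @export
coef.pvl_scan <- function(object, ...) {
  coef(object$pleio_fit)
}

#' Plot profile LOD traces
#'
#' Draws the two profile LOD traces and the pleiotropy trace against marker
#' position, the standard visualization of the test: the common maximum of the
#' two profile traces is the LOD statistic, and the pleiotropy trace peaks at
#' zero at the inferred common QTL position.
#'
#' @param x a [scan_pvl()] result (or `plot` a [profile_traces()] data frame
#'   directly).
#' @param col colors for (profile1, profile2, pleiotropy).
#' @param ... further arguments to [graphics::matplot()].
#' @return invisibly, `x`.
#' @export
plot.pvl_scan <- function(x, col = c("goldenrod3", "steelblue4", "gray50"),
                          ...) {
  plot(x$traces, col = col, trait_names = x$trait_names, ...)
  invisible(x)
}

#' @export
plot.pvl_traces <- function(x, col = c("goldenrod3", "steelblue4", "gray50"),
                            trait_names = c("trait 1", "trait 2"), ...) {
  graphics::matplot(x$position, cbind(x$profile1, x$profile2, x$pleio),
                    type = "l", lty = c(1, 1, 2), lwd = 2, col = col,
                    xlab = "position (cM)", ylab = "profile LOD", ...)
  graphics::legend("bottomright",
                   legend = c(paste("profile:", trait_names), "pleiotropy"),
                   col = col, lty = c(1, 1, 2), lwd = 2, bty = "n")
  invisible(x)
}
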