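# Core data containers: founder-allele probability arrays, trait pairs,
# covariates, kinship.  All are lightweight S3 wrappers around base matrices
# and arrays; subject IDs live in dimnames and every constructor validates.

#' Founder-allele probability array
#'
#' Construct an `alleleprob` object: an n-subject by k-founder by m-marker
#' array of founder-allele dosage probabilities on one chromosome, with a
#' centimorgan marker map.  For every subject and marker the probabilities
#' across founders must sum to one.
#'
#' @param probs numeric n x k x m array.  Dimnames, if present, are used as
#'   subject, founder and marker labels; otherwise defaults are generated.
#' @param map numeric vector of length m: marker positions in cM,
#'   nondecreasing.  Names, if present, must match marker labels.
#' @param chr chromosome name (single string).
#'
#' @return An object of class `alleleprob`: the array with a `map` and `chr`
#'   attribute.
#' @export
#' @examples
#' g <- generate_genome(genome_spec(n_subjects = 4, chromosomes = chrom_table(1, 10, 11)),
#'                      seed = 1)
#' ap <- g$probs[[1]]
#' dim(ap)
alleleprob <- function(probs, map, chr = "1") {
  if (!is.array(probs) || length(dim(probs)) != 3L) {
    stop("`probs` must be a 3-dimensional array (subjects x founders x markers)")
  }
  d <- dim(probs)
  dn <- dimnames(probs)
  if (is.null(dn)) dn <- vector("list", 3L)
  if (is.null(dn[[1]])) dn[[1]] <- paste0("s", seq_len(d[1]))
  if (is.null(dn[[2]])) dn[[2]] <- LETTERS[seq_len(d[2])]
  if (is.null(dn[[3]])) dn[[3]] <- paste0(chr, "_m", seq_len(d[3]))
  dimnames(probs) <- dn
  if (length(map) != d[3]) stop("`map` length must equal the number of markers")
  if (is.null(names(map))) names(map) <- dn[[3]]
  x <- structure(probs, map = as.numeric(stats::setNames(map, names(map))),
                 chr = as.character(chr), class = "alleleprob")
  attr(x, "map") <- stats::setNames(as.numeric(map), dn[[3]])
  validate_alleleprob(x)
}

#' Validate an allele probability array
#'
#' Checks the `alleleprob` invariants: entries in \[0, 1\], rows summing to one
#' across founders (within 1e-6), nondecreasing positions, no duplicated
#' subject or marker IDs.
#'
#' @param x an `alleleprob` object.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_alleleprob <- function(x) {
  stopifnot(inherits(x, "alleleprob"))
  dn <- dimnames(x)
  if (anyDuplicated(dn[[1]])) stop("duplicate subject IDs in allele probabilities")
  if (anyDuplicated(dn[[3]])) stop("duplicate marker IDs in allele probabilities")
  if (any(!is.finite(x))) stop("non-finite allele probabilities")
  if (min(x) < -1e-8 || max(x) > 1 + 1e-8) stop("allele probabilities outside [0, 1]")
  sums <- apply(unclass(x), c(1, 3), sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("allele probabilities must sum to 1 over founders for every subject and marker")
  }
  map <- attr(x, "map")
  if (is.unsorted(map)) stop("marker positions must be nondecreasing")
  invisible(x)
}

#' @export
print.alleleprob <- function(x, ...) {
  d <- dim(x)
  map <- attr(x, "map")
  cat(sprintf("<alleleprob> chr %s: %d subjects x %d founders x %d markers (%.1f-%.1f cM)\n",
              attr(x, "chr"), d[1], d[2], d[3], min(map), max(map)))
  invisible(x)
}

#' Trait pair matrix
#'
#' Bundle two phenotypes measured on the same subjects into the n x 2 matrix
#' the pleiotropy test consumes.
#'
#' @param values numeric n x 2 matrix; rownames are subject IDs.
#' @param trait_names length-2 character vector of trait labels; defaults to
#'   the column names of `values`.
#' @return a numeric matrix of class `trait_pair`.
#' @export
trait_pair <- function(values, trait_names = colnames(values)) {
  values <- as.matrix(values)
  if (ncol(values) != 2L) stop("a trait pair must have exactly 2 columns")
  if (is.null(rownames(values))) stop("`values` must carry subject IDs as rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate subject IDs in traits")
  if (is.null(trait_names)) trait_names <- c("trait1", "trait2")
  colnames(values) <- trait_names
  storage.mode(values) <- "double"
  structure(values, class = c("trait_pair", class(matrix())))
}

#' Covariate matrix
#'
#' @param values numeric n x c matrix with subject IDs as rownames; may have
#'   zero columns.
#' @return a numeric matrix of class `covariate_matrix`.
#' @export
covariate_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("`values` must carry subject IDs as rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate subject IDs in covariates")
  storage.mode(values) <- "double"
  if (ncol(values) > 0) {
    aug <- cbind(1, values)
    if (qr(aug)$rank < ncol(aug)) {
      stop("covariates are collinear with the intercept or each other")
    }
  }
  structure(values, class = c("covariate_matrix", class(matrix())))
}

#' Kinship matrix
#'
#' @param values symmetric positive-semidefinite n x n matrix with subject IDs
#'   as dimnames.
#' @param tag label recording which chromosome was left out, if any.
#' @return a numeric matrix of class `kinship`.
#' @export
kinship_matrix <- function(values, tag = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("kinship matrix must be square")
  if (is.null(rownames(values))) stop("kinship must carry subject IDs as dimnames")
  if (max(abs(values - t(values))) > 1e-8) stop("kinship matrix is not symmetric")
  ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("kinship matrix is not positive semidefinite")
  colnames(values) <- rownames(values)
  structure(values, tag = tag, class = c("kinship", class(matrix())))
}

subject_ids <- function(x) {
  if (inherits(x, "alleleprob")) dimnames(x)[[1]] else rownames(x)
}

# restrict a container to subjects `ids` (in that order)
restrict_subjects <- function(x, ids) {
  if (inherits(x, "alleleprob")) {
    out <- unclass(x)[ids, , , drop = FALSE]
    alleleprob(out, attr(x, "map"), attr(x, "chr"))
  } else if (inherits(x, "kinship")) {
    kinship_matrix(unclass(x)[ids, ids, drop = FALSE], tag = attr(x, "tag"))
  } else if (inherits(x, "trait_pair")) {
    trait_pair(unclass(x)[ids, , drop = FALSE])
  } else if (inherits(x, "covariate_matrix")) {
    covariate_matrix(unclass(x)[ids, , drop = FALSE])
  } else {
    x[ids, , drop = FALSE]
  }
}

#' Align genotypes, traits, covariates and kinship on shared subjects
#'
#' Restricts all four inputs to the intersection of their subject IDs, in the
#' order of the genotype object, after dropping subjects with any missing
#' trait or covariate value (complete-case analysis; no imputation).
#'
#' @param probs an [alleleprob] array.
#' @param traits a [trait_pair] matrix.
#' @param covar a [covariate_matrix]; `NULL` means no covariates.
#' @param kin a [kinship_matrix].
#' @return list with elements `probs`, `traits`, `covar`, `kin`, aligned.
#' @export
align_inputs <- function(probs, traits, covar = NULL, kin) {
  stopifnot(inherits(probs, "alleleprob"), inherits(kin, "kinship"))
  if (!inherits(traits, "trait_pair")) traits <- trait_pair(traits)
  ids <- subject_ids(probs)
  keep <- rownames(traits)[stats::complete.cases(traits)]
  if (!is.null(covar) && ncol(covar) > 0) {
    keep <- intersect(keep, rownames(covar)[stats::complete.cases(covar)])
  } else if (!is.null(covar)) {
    keep <- intersect(keep, rownames(covar))
  }
  ids <- ids[ids %in% intersect(keep, subject_ids(kin))]
  if (length(ids) == 0L) stop("no shared subjects across inputs after complete-case filtering")
  list(probs = restrict_subjects(probs, ids),
       traits = restrict_subjects(traits, ids),
       covar = if (is.null(covar)) NULL else restrict_subjects(covar, ids),
       kin = restrict_subjects(kin, ids))
}

#' Leave-one-chromosome-out kinship matrices
#'
#' For each chromosome, computes the kinship between subjects i and i' as the
#' average over all markers on all *other* chromosomes of the founder-allele
#' probability inner product `sum_a probs[i, a, j] * probs[i', a, j]`.  This
#' "LOCO" convention avoids proximal contamination when the kinship is used as
#' the polygenic covariance during a scan of the left-out chromosome.
#'
#' @param probs_by_chromosome list of [alleleprob] arrays, one per chromosome
#'   (at least two), with identical subjects in identical order.
#' @param normalize if `TRUE`, rescale each matrix so its mean diagonal entry
#'   is 1.  Off by default; note that the scale of the estimated genetic
#'   covariance `Vg` depends on the kinship scale.
#' @return list of [kinship_matrix] objects, one per left-out chromosome,
#'   tagged with the chromosome name.
#' @export
calc_kinship_loco <- function(probs_by_chromosome, normalize = FALSE) {
  if (length(probs_by_chromosome) < 2L) {
    stop("LOCO kinship requires at least two chromosomes")
  }
  ids <- subject_ids(probs_by_chromosome[[1]])
  for (ap in probs_by_chromosome) {
    stopifnot(inherits(ap, "alleleprob"))
    if (!identical(subject_ids(ap), ids)) {
      stop("all chromosomes must have identical subjects in identical order")
    }
  }
  n <- length(ids)
  cross <- lapply(probs_by_chromosome, function(ap) {
    A <- matrix(unclass(ap), nrow = n)  # n x (k*m) unfolding
    tcrossprod(A)
  })
  nmark <- vapply(probs_by_chromosome, function(ap) dim(ap)[3], integer(1))
  out <- vector("list", length(cross))
  for (c_i in seq_along(cross)) {
    # sum the retained chromosomes directly: the left-out chromosome must not
    # influence the result even at floating-point level
    K <- Reduce(`+`, cross[-c_i]) / (sum(nmark) - nmark[c_i])
    if (normalize) K <- K / mean(diag(K))
    dimnames(K) <- list(ids, ids)
    chrname <- attr(probs_by_chromosome[[c_i]], "chr")
    out[[c_i]] <- kinship_matrix((K + t(K)) / 2,
                                 tag = sprintf("%s left out", chrname))
  }
  names(out) <- vapply(probs_by_chromosome, attr, "", which = "chr")
  out
}
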