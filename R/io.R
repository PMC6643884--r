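# Plain-text serialization: wide CSV per chromosome for allele probabilities
# (columns marker:founder), a marker-map CSV, and header+ID CSVs for
# phenotypes, covariates and kinship.  Comma-separated, header row, empty
# cell = missing, UTF-8.

#' Write / read founder-allele probabilities as CSV
#'
#' The wide format has one row per subject (first column `id`) and one column
#' per marker-founder combination, named `<marker>:<founder>`.  The companion
#' map file has columns `marker`, `chr`, `pos`.
#'
#' @param x an [alleleprob].
#' @param file path for the probability CSV.
#' @param map_file path for the marker map CSV.
#' @return `write_alleleprob_csv`: invisibly, `file`.
#' @export
write_alleleprob_csv <- function(x, file, map_file) {
  stopifnot(inherits(x, "alleleprob"))
  d <- dim(x)
  dn <- dimnames(x)
  wide <- matrix(aperm(unclass(x), c(1, 2, 3)), nrow = d[1])
  colnames(wide) <- as.vector(outer(dn[[2]], dn[[3]],
                                    function(f, m) paste(m, f, sep = ":")))
  df <- data.frame(id = dn[[1]], wide, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  utils::write.csv(data.frame(marker = dn[[3]], chr = attr(x, "chr"),
                              pos = attr(x, "map")),
                   map_file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_alleleprob_csv
#' @return `read_alleleprob_csv`: an [alleleprob].
#' @export
read_alleleprob_csv <- function(file, map_file) {
  df <- utils::read.csv(file, check.names = FALSE)
  mp <- utils::read.csv(map_file)
  ids <- as.character(df[[1]])
  wide <- as.matrix(df[, -1, drop = FALSE])
  parts <- strsplit(colnames(wide), ":", fixed = TRUE)
  markers <- vapply(parts, function(p) paste(p[-length(p)], collapse = ":"), "")
  founders <- vapply(parts, function(p) p[length(p)], "")
  umark <- unique(markers)
  ufound <- unique(founders)
  arr <- array(NA_real_, dim = c(length(ids), length(ufound), length(umark)),
               dimnames = list(ids, ufound, umark))
  for (j in seq_along(markers)) {
    arr[, match(founders[j], ufound), match(markers[j], umark)] <- wide[, j]
  }
  pos <- mp$pos[match(umark, mp$marker)]
  alleleprob(arr, map = pos, chr = as.character(mp$chr[1]))
}

#' Read / write phenotype, covariate and kinship CSVs
#'
#' All three use a header row and the subject ID as the first column; kinship
#' additionally has subject IDs as the remaining column names.
#'
#' @param file CSV path.
#' @param traits for `read_trait_csv`: optional length-2 character vector
#'   naming the two phenotype columns to keep.
#' @return `read_trait_csv` a [trait_pair] (or a full numeric matrix when
#'   `traits` is `NULL` and the file has more than two phenotype columns);
#'   `read_covar_csv` a [covariate_matrix]; `read_kinship_csv` a
#'   [kinship_matrix].
#' @export
read_trait_csv <- function(file, traits = NULL) {
  df <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (!is.null(traits)) {
    missing_tr <- setdiff(traits, colnames(m))
    if (length(missing_tr) > 0) {
      stop("phenotype file ", file, " lacks trait(s): ",
           paste(missing_tr, collapse = ", "))
    }
    m <- m[, traits, drop = FALSE]
  }
  if (ncol(m) == 2) trait_pair(m) else m
}

#' @rdname read_trait_csv
#' @export
read_covar_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  covariate_matrix(m)
}

#' @rdname read_trait_csv
#' @export
read_kinship_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  kinship_matrix((m + t(m)) / 2)
}

#' @rdname read_trait_csv
#' @param x matrix to write (traits, covariates, or kinship).
#' @export
write_matrix_csv <- function(x, file) {
  df <- data.frame(id = rownames(x), as.matrix(unclass(x)),
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write a likelihood grid or profile traces as tidy CSV
#'
#' @param scan a [scan_pvl()] result.
#' @param file output path.
#' @param meta optional named character vector written as leading `#` comment
#'   lines (e.g. config hash and seed).
#' @return invisibly, `file`.
#' @export
write_grid_csv <- function(scan, file, meta = NULL) {
  g <- scan$grid
  m <- nrow(g)
  df <- data.frame(
    marker1 = rep(rownames(g), times = m),
    pos1 = rep(scan$positions, times = m),
    marker2 = rep(colnames(g), each = m),
    pos2 = rep(scan$positions, each = m),
    ll10 = as.vector(g))
  write_csv_with_meta(df, file, meta)
}

#' @rdname write_grid_csv
#' @export
write_traces_csv <- function(scan, file, meta = NULL) {
  tr <- scan$traces
  df <- data.frame(position = tr$position, profile1 = tr$profile1,
                   profile2 = tr$profile2, pleio = tr$pleio)
  write_csv_with_meta(df, file, meta)
}

write_csv_with_meta <- function(df, file, meta = NULL) {
  con <- file(file, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}
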