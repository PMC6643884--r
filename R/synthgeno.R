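# Synthetic multi-founder genotypes: founder-haplotype mosaics, allele
# probabilities, marker maps, LOCO kinship.  Emulates the structure of
# HMM-derived Diversity-Outbred allele probabilities (8 founders, cM map,
# probability rows summing to one) so the statistical machinery can be
# exercised without any external data.

#' Chromosome table for a genome specification
#'
#' @param name chromosome names.
#' @param length_cm chromosome lengths in cM.
#' @param n_markers marker counts (markers are equally spaced from 0 to
#'   `length_cm`).
#' @return data frame with columns `name`, `length_cm`, `n_markers`, recycled
#'   to a common length.
#' @export
chrom_table <- function(name = c("1", "2"), length_cm = 60, n_markers = 61) {
  data.frame(name = as.character(name), length_cm = length_cm,
             n_markers = as.integer(n_markers))
}

#' Specification for a synthetic multiparental genome
#'
#' Defines the population and map structure for [generate_genome()].  Founder
#' mosaics are haploid-equivalent: each subject carries one founder label per
#' position, matching the n x k allele-dosage interface the test consumes.
#'
#' @param n_subjects number of subjects.
#' @param n_founders number of founder alleles (default 8, labelled A-H).
#' @param chromosomes a [chrom_table()] (default: 2 chromosomes x 60 cM x 61
#'   markers, the smallest structure supporting LOCO kinship and short
#'   interlocus-distance grids).
#' @param crossover_rate expected crossovers per 100 cM (per Morgan) per
#'   meiosis-equivalent; default 1.
#' @param mosaic_generations meiosis-equivalents accumulated by the mosaic
#'   (default 23, as in a mature outbred population); the mean founder-segment
#'   length is `100 / (crossover_rate * mosaic_generations)` cM.
#' @param certainty probability mass placed on the true founder at each
#'   marker; the remainder is spread uniformly over the other founders.  Must
#'   exceed `1/n_founders`; 1 gives hard (one-hot) assignments.  Default 0.95,
#'   mimicking high-confidence HMM reconstructions.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(n_subjects, n_founders = 8L,
                        chromosomes = chrom_table(),
                        crossover_rate = 1, mosaic_generations = 23L,
                        certainty = 0.95) {
  stopifnot(n_subjects >= 1, n_founders >= 2,
            nrow(chromosomes) >= 1, all(chromosomes$n_markers >= 1),
            all(chromosomes$length_cm > 0),
            crossover_rate >= 0, mosaic_generations >= 1)
  if (certainty <= 1 / n_founders || certainty > 1) {
    stop("`certainty` must lie in (1/n_founders, 1]")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_founders = as.integer(n_founders),
                 chromosomes = chromosomes,
                 crossover_rate = crossover_rate,
                 mosaic_generations = as.integer(mosaic_generations),
                 certainty = certainty),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d subjects, %d founders, %d chromosome(s)\n",
              x$n_subjects, x$n_founders, nrow(x$chromosomes)))
  cat(sprintf("  mean founder segment %.2f cM, certainty %.2f\n",
              100 / max(x$crossover_rate * x$mosaic_generations, 1e-12),
              x$certainty))
  invisible(x)
}

# one subject's founder mosaic along a chromosome: piecewise-constant founder
# labels with Exp(mean_len) segment lengths; returns founder index per marker
mosaic_one <- function(positions, k, mean_len) {
  m <- length(positions)
  founder <- integer(m)
  cur <- sample.int(k, 1)
  if (!is.finite(mean_len)) return(rep(cur, m))  # no recombination
  pos <- 0
  lenmax <- max(positions)
  breaks <- numeric(0)
  labels <- cur
  while (pos <= lenmax) {
    pos <- pos + stats::rexp(1, rate = 1 / mean_len)
    if (pos > lenmax) break
    breaks <- c(breaks, pos)
    nxt <- sample.int(k - 1, 1)
    cur <- if (nxt >= cur) nxt + 1L else nxt  # uniform over the other founders
    labels <- c(labels, cur)
  }
  labels[findInterval(positions, breaks) + 1L]
}

#' Generate a synthetic multiparental genome
#'
#' Simulates, for every subject and chromosome, a Markov mosaic of founder
#' labels with exponentially distributed segment lengths (mean
#' `100 / (crossover_rate * mosaic_generations)` cM), converts the mosaics to
#' founder-allele probabilities placing `certainty` on the true founder, and
#' computes leave-one-chromosome-out kinship matrices.  The same seed always
#' reproduces the same genome.
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed.
#' @param keep_mosaic if `TRUE`, attach the true founder-label matrix
#'   (subjects x markers) to each chromosome as attribute `"mosaic"`.
#' @return list with elements `probs` (list of [alleleprob], one per
#'   chromosome) and `kinship` (list of LOCO [kinship_matrix], or `NULL` when
#'   only one chromosome is specified).
#' @export
generate_genome <- function(spec, seed = 1L, keep_mosaic = FALSE) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(seed)
  k <- spec$n_founders
  n <- spec$n_subjects
  founders <- LETTERS[seq_len(k)]
  subjects <- paste0("s", seq_len(n))
  rate <- spec$crossover_rate * spec$mosaic_generations
  mean_len <- if (rate > 0) 100 / rate else Inf
  off <- (1 - spec$certainty) / (k - 1)
  probs <- vector("list", nrow(spec$chromosomes))
  for (ci in seq_len(nrow(spec$chromosomes))) {
    chr <- spec$chromosomes$name[ci]
    m <- spec$chromosomes$n_markers[ci]
    len <- spec$chromosomes$length_cm[ci]
    positions <- if (m == 1) len / 2 else seq(0, len, length.out = m)
    mos <- t(vapply(seq_len(n), function(i) mosaic_one(positions, k, mean_len),
                    integer(m)))
    arr <- array(off, dim = c(n, k, m),
                 dimnames = list(subjects, founders,
                                 sprintf("c%s_m%03d", chr, seq_len(m))))
    for (j in seq_len(m)) {
      arr[cbind(seq_len(n), mos[, j], j)] <- spec$certainty
    }
    ap <- alleleprob(arr, map = positions, chr = chr)
    if (keep_mosaic) attr(ap, "mosaic") <- mos
    probs[[ci]] <- ap
  }
  names(probs) <- spec$chromosomes$name
  kinship <- if (length(probs) >= 2) calc_kinship_loco(probs) else NULL
  list(probs = probs, kinship = kinship)
}
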