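# Factorial simulation studies: type-I error of the pleiotropy test
# (2 allele-effect differences x 2 allele partitions x 2 genetic
# correlations) and power against separate QTL (2 effect differences x
# 2 partitions x 5 interlocus distances, with pooled bootstrap nulls).

#' QTL allele-effect specification
#'
#' Builds the 8-founder allele-effect vector for a simulated QTL: founders in
#' the first partition group get effect 0, founders in the second group get
#' effect `delta` (the trait intercept absorbs location).
#'
#' @param delta allele-effects difference between the two groups.
#' @param partition `"ABCD:EFGH"` (two equally frequent QTL alleles) or
#'   `"F:ABCDEGH"` (a private allele in founder F).
#' @return object of class `effect_spec`: list with `delta`, `partition`, and
#'   the named length-8 `effects` vector.
#' @export
#' @examples
#' make_effects(6, "ABCD:EFGH")$effects
make_effects <- function(delta, partition = c("ABCD:EFGH", "F:ABCDEGH")) {
  partition <- match.arg(partition)
  founders <- LETTERS[1:8]
  effects <- stats::setNames(rep(0, 8), founders)
  grp2 <- if (partition == "ABCD:EFGH") c("E", "F", "G", "H") else "F"
  effects[grp2] <- delta
  structure(list(delta = delta, partition = partition, effects = effects),
            class = "effect_spec")
}

#' Simulate one trait pair with QTL at specified markers
#'
#' The mean of trait t for subject i is the inner product of the subject's
#' founder-allele probabilities at the trait's QTL marker with the allele
#' effects; noise is `G + E` as in [simulate_traits()].  The same effect
#' vector is applied to both traits, so `marker1 == marker2` simulates a
#' pleiotropic pair.
#'
#' @param probs an [alleleprob] for the chromosome carrying the QTL.
#' @param marker1,marker2 marker indices (or names) for the trait-1 / trait-2
#'   QTL.
#' @param effects an [make_effects()] spec, or a named effect vector of length
#'   k.
#' @param varcomp a [var_comp]; `Vg = [[1, r], [r, 1]]`, `Ve = I` in the
#'   studies.
#' @param kin kinship matrix for the polygenic term.
#' @param seed integer seed or `NULL`.
#' @param kin_sqrt optional precomputed [psd_sqrt()] of `kin`.
#' @return a [trait_pair].
#' @export
sim_trait_pair <- function(probs, marker1, marker2 = marker1, effects,
                           varcomp, kin, seed = NULL, kin_sqrt = NULL) {
  if (inherits(effects, "effect_spec")) effects <- effects$effects
  k <- dim(probs)[2]
  if (length(effects) != k) stop("effect vector length must equal the founder count")
  A1 <- unclass(probs)[, , marker1]
  A2 <- unclass(probs)[, , marker2]
  X <- pvl_design(A1, A2)
  B <- cbind(effects, effects)
  simulate_traits(X, B, varcomp, kin, seed = seed, kin_sqrt = kin_sqrt)
}

#' Study design for the simulation experiments
#'
#' @param delta allele-effects differences to cross.
#' @param partition allele partitions to cross.
#' @param gencor genetic correlations (off-diagonal of Vg) — type-I study.
#' @param distance interlocus distances in cM — power study.
#' @param n_sim simulation replicates per cell.
#' @param b bootstrap replicates per simulation.
#' @param pool whether the power study pools bootstrap statistics within a
#'   cell (the distance-0 cells are always scored per replicate).
#' @param alpha nominal level.
#' @return a list of class `study_design`.
#' @export
study_design <- function(delta = c(6, 12),
                         partition = c("ABCD:EFGH", "F:ABCDEGH"),
                         gencor = c(0, 0.6),
                         distance = c(0, 0.5, 1, 2, 3),
                         n_sim = 100L, b = 100L, pool = TRUE, alpha = 0.05) {
  stopifnot(n_sim >= 1, b >= 1)
  structure(list(delta = delta, partition = partition, gencor = gencor,
                 distance = distance, n_sim = as.integer(n_sim),
                 b = as.integer(b), pool = pool, alpha = alpha),
            class = "study_design")
}

# default genotypes for the studies: 2 chromosomes at 0.5 cM marker spacing,
# scan chromosome first; LOCO kinship from the other chromosome
default_study_genome <- function(n = 150L, seed = 20260920L) {
  generate_genome(
    genome_spec(n_subjects = n,
                chromosomes = chrom_table(c("1", "2"), c(20, 20), c(41, 41))),
    seed = seed)
}

# deterministic per-cell seed from the master seed and the cell's factor
# levels, so study results do not depend on which cells run, or in what order
cell_seed <- function(seed, key) {
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 1900000000
  as.integer((h + (as.numeric(seed) %% 1e6) * 97003) %% (.Machine$integer.max - 1) + 1)
}

# shared cell runner: simulate n_sim pairs with QTL at (marker1, marker2),
# bootstrap each, return per-sim lods, pvalues and pooled replicate lods
run_cells <- function(eng, probs, kin, marker1, marker2, effects, varcomp_sim,
                      n_sim, b, seed, cores = 1L, tol = 1e-6, maxit = 10000L) {
  ks <- psd_sqrt(unclass(as.matrix(kin)))
  seeds <- child_seeds(seed, 2L * n_sim)
  one <- function(s) {
    Y <- sim_trait_pair(probs, marker1, marker2, effects, varcomp_sim, kin,
                        seed = seeds[s], kin_sqrt = ks)
    r <- engine_boot(eng, unclass(as.matrix(Y)), b = b,
                     seed = seeds[n_sim + s], cores = 1L,
                     tol = tol, maxit = maxit)
    c(lod = r$observed_lod, pvalue = r$pvalue, r$replicate_lods)
  }
  res <- if (cores > 1L) {
    parallel::mclapply(seq_len(n_sim), one, mc.cores = cores)
  } else {
    lapply(seq_len(n_sim), one)
  }
  res <- do.call(rbind, res)
  list(lods = res[, 1], pvalues = res[, 2],
       boot_lods = as.numeric(res[, -(1:2), drop = FALSE]))
}

#' Type-I-error simulation study
#'
#' For each design cell (allele-effects difference x allele partition x
#' genetic correlation), simulates `n_sim` pleiotropic trait pairs at a single
#' marker with `Vg = [[1, r], [r, 1]]` and `Ve = I`, runs the full
#' scan-plus-parametric-bootstrap test on each pair, and records the
#' proportion rejected at the nominal level.
#'
#' @param genotypes list of [alleleprob] arrays (scan chromosome first), or
#'   `NULL` to generate the default synthetic genome.
#' @param kinship LOCO kinship list matching `genotypes`, or `NULL`.
#' @param design a [study_design()]; its `distance` component is ignored here.
#' @param n number of subjects when generating the default genome.
#' @param interval scan interval in cM on the first chromosome; default: 7
#'   markers centred on the chromosome.  The QTL sits at the interval's
#'   central marker.
#' @param seed master seed; every cell derives its own child seeds, so results
#'   do not depend on cell execution order.
#' @param cores workers for the simulation loop.
#' @param tol,maxit EM-REML controls.
#' @return data frame of class `study_result`: one row per cell with the
#'   rejection proportion at `design$alpha` and its binomial standard error.
#' @export
run_type1_study <- function(genotypes = NULL, kinship = NULL,
                            design = study_design(), n = 150L,
                            interval = NULL, seed = 1L, cores = 1L,
                            tol = 1e-6, maxit = 10000L) {
  gk <- resolve_study_genome(genotypes, kinship, n)
  probs <- gk$probs; kin <- gk$kin
  map <- attr(probs, "map")
  if (is.null(interval)) interval <- default_interval(map, width = 3)
  eng <- pvl_engine(probs, NULL, kin, interval)
  qtl <- eng$probs_idx[ceiling(length(eng$probs_idx) / 2)]  # central marker
  cells <- expand.grid(delta = design$delta, partition = design$partition,
                       gencor = design$gencor, stringsAsFactors = FALSE)
  out <- cells
  out$n_sim <- design$n_sim
  out$b <- design$b
  out$rejections <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    eff <- make_effects(cells$delta[i], cells$partition[i])
    vc <- var_comp(matrix(c(1, cells$gencor[i], cells$gencor[i], 1), 2),
                   diag(2))
    key <- sprintf("type1|delta=%g|partition=%s|gencor=%g", cells$delta[i],
                   cells$partition[i], cells$gencor[i])
    r <- run_cells(eng, probs, kin, qtl, qtl, eff, vc,
                   design$n_sim, design$b, cell_seed(seed, key), cores = cores,
                   tol = tol, maxit = maxit)
    out$rejections[i] <- sum(r$pvalues < design$alpha)
  }
  out$proportion <- out$rejections / out$n_sim
  out$se <- sqrt(out$proportion * (1 - out$proportion) / out$n_sim)
  structure(out, alpha = design$alpha, qtl_position = eng$positions[
    match(qtl, eng$probs_idx)], class = c("study_result", "data.frame"))
}

#' Power simulation study
#'
#' For each design cell (allele-effects difference x allele partition x
#' interlocus distance), simulates `n_sim` trait pairs with the trait-1 QTL at
#' a base marker and the trait-2 QTL `distance` cM away (`Vg = Ve = I`), and
#' bootstraps each pair.  For positive distances the bootstrap statistics are
#' pooled within the cell (`n_sim * b` draws) and every simulated LOD is
#' compared against the pooled distribution's upper `alpha` tail; distance-0
#' cells are scored per replicate, exactly as in the type-I study.
#'
#' @inheritParams run_type1_study
#' @param interval scan interval; default: from the base marker to the largest
#'   distance requested.  The trait-1 QTL sits at the interval's first marker.
#' @return data frame of class `study_result`, one row per cell.
#' @export
run_power_study <- function(genotypes = NULL, kinship = NULL,
                            design = study_design(delta = c(1, 2)),
                            n = 150L, interval = NULL, seed = 1L, cores = 1L,
                            tol = 1e-6, maxit = 10000L) {
  gk <- resolve_study_genome(genotypes, kinship, n)
  probs <- gk$probs; kin <- gk$kin
  map <- attr(probs, "map")
  maxd <- max(design$distance)
  if (is.null(interval)) {
    base_pos <- map[which.min(abs(map - (max(map) - maxd) / 2))]
    interval <- c(base_pos, base_pos + maxd)
  }
  eng <- pvl_engine(probs, NULL, kin, interval)
  qtl1 <- eng$probs_idx[1]
  base_pos <- attr(probs, "map")[qtl1]
  vc <- var_comp(diag(2), diag(2))
  cells <- expand.grid(delta = design$delta, partition = design$partition,
                       distance = design$distance, stringsAsFactors = FALSE)
  out <- cells
  out$n_sim <- design$n_sim
  out$b <- design$b
  out$pooled <- design$pool & cells$distance > 0
  out$rejections <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    dist_i <- cells$distance[i]
    qtl2 <- which.min(abs(map - (base_pos + dist_i)))
    if (abs(map[qtl2] - (base_pos + dist_i)) > 0.1) {
      stop(sprintf("no marker within 0.1 cM of the requested position %.2f cM (nearest: %.2f cM)",
                   base_pos + dist_i, map[qtl2]))
    }
    eff <- make_effects(cells$delta[i], cells$partition[i])
    key <- sprintf("power|delta=%g|partition=%s|distance=%g", cells$delta[i],
                   cells$partition[i], dist_i)
    r <- run_cells(eng, probs, kin, qtl1, qtl2, eff, vc,
                   design$n_sim, design$b, cell_seed(seed, key), cores = cores,
                   tol = tol, maxit = maxit)
    out$rejections[i] <- if (out$pooled[i]) {
      # pooled empirical null: compare each simulated LOD to all b * n_sim
      # bootstrap statistics of the cell
      sum(vapply(r$lods, function(l) mean(r$boot_lods >= l), numeric(1))
          < design$alpha)
    } else {
      sum(r$pvalues < design$alpha)
    }
  }
  out$proportion <- out$rejections / out$n_sim
  out$se <- sqrt(out$proportion * (1 - out$proportion) / out$n_sim)
  structure(out, alpha = design$alpha, qtl1_position = unname(base_pos),
            class = c("study_result", "data.frame"))
}

resolve_study_genome <- function(genotypes, kinship, n) {
  if (is.null(genotypes)) {
    g <- default_study_genome(n)
    genotypes <- g$probs
    kinship <- g$kinship
  }
  if (inherits(genotypes, "alleleprob")) genotypes <- list(genotypes)
  probs <- genotypes[[1]]
  kin <- if (is.null(kinship)) {
    if (length(genotypes) < 2) {
      stop("supply a kinship matrix or at least two chromosomes for LOCO kinship")
    }
    calc_kinship_loco(genotypes)[[1]]
  } else if (inherits(kinship, "kinship")) kinship else kinship[[1]]
  list(probs = probs, kin = kin)
}

# centred interval of `width` cM on a marker map
default_interval <- function(map, width) {
  mid <- (min(map) + max(map)) / 2
  c(mid - width / 2, mid + width / 2)
}

#' @export
print.study_result <- function(x, digits = 3, ...) {
  cat(sprintf("Simulation study: rejection proportions at nominal %.2f\n",
              attr(x, "alpha")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
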