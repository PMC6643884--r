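# Containers, validation, alignment, and LOCO kinship.

make_ap <- function(arr, map, chr = "1") {
  alleleprob(arr, map = map, chr = chr)
}

test_that("alleleprob validation enforces row sums, range and map order", {
  arr <- array(0.5, dim = c(2, 2, 3),
               dimnames = list(c("s1", "s2"), c("A", "B"), c("m1", "m2", "m3")))
  expect_s3_class(make_ap(arr, c(0, 1, 2)), "alleleprob")

  bad <- arr; bad[1, 1, 1] <- 0.7
  expect_error(make_ap(bad, c(0, 1, 2)), "sum to 1")
  bad2 <- arr; bad2[1, , 1] <- c(1.4, -0.4)
  expect_error(make_ap(bad2, c(0, 1, 2)), "outside")
  expect_error(make_ap(arr, c(2, 1, 0)), "nondecreasing")
  dup <- arr; dimnames(dup)[[1]] <- c("s1", "s1")
  expect_error(make_ap(dup, c(0, 1, 2)), "duplicate")
})

test_that("align_inputs returns identical inputs unchanged and is idempotent", {
  g <- tiny_genome(n = 12)
  probs <- g$probs[[1]]
  kin <- g$kinship[[1]]
  tr <- rand_traits(dimnames(probs)[[1]])
  cv <- covariate_matrix(matrix(rnorm(12), 12, 1,
                                dimnames = list(rownames(tr), "sex")))
  al <- align_inputs(probs, tr, cv, kin)
  expect_identical(unclass(al$probs), unclass(probs))
  expect_identical(unclass(al$traits), unclass(tr))
  expect_identical(unclass(al$kin), unclass(kin))
  al2 <- align_inputs(al$probs, al$traits, al$covar, al$kin)
  expect_identical(al2, al)
})

test_that("align_inputs intersects subjects in genotype order", {
  arr <- array(1 / 2, dim = c(3, 2, 2),
               dimnames = list(c("s1", "s2", "s3"), c("A", "B"), c("m1", "m2")))
  probs <- make_ap(arr, c(0, 1))
  Y <- matrix(1:4 + 0.0, 2, 2, dimnames = list(c("s3", "s1"), c("y1", "y2")))
  K <- diag(3); dimnames(K) <- list(c("s1", "s2", "s3"), c("s1", "s2", "s3"))
  al <- align_inputs(probs, trait_pair(Y), NULL, kinship_matrix(K))
  expect_identical(rownames(al$traits), c("s1", "s3"))  # genotype order wins
  expect_identical(dimnames(al$probs)[[1]], c("s1", "s3"))
  expect_identical(rownames(al$kin), c("s1", "s3"))
  expect_equal(al$traits["s1", ], c(y1 = 2, y2 = 4))
})

test_that("subjects with a missing trait or covariate are dropped everywhere", {
  g <- tiny_genome(n = 6)
  probs <- g$probs[[1]]
  ids <- dimnames(probs)[[1]]
  tr <- rand_traits(ids)
  tr[3, 2] <- NA
  al <- align_inputs(probs, tr, NULL, g$kinship[[1]])
  expect_false(ids[3] %in% rownames(al$traits))
  expect_false(ids[3] %in% dimnames(al$probs)[[1]])
  expect_false(ids[3] %in% rownames(al$kin))
  expect_equal(nrow(al$traits), 5)
})

test_that("align_inputs fails on empty subject intersection", {
  g <- tiny_genome(n = 4)
  tr <- rand_traits(c("x1", "x2", "x3", "x4"))
  expect_error(align_inputs(g$probs[[1]], tr, NULL, g$kinship[[1]]),
               "no shared subjects")
})

test_that("LOCO kinship matches a brute-force double loop", {
  # 3 subjects x 2 chromosomes x 2 markers with hand-set probabilities
  set.seed(5)
  mk <- function(chr) {
    arr <- array(0, dim = c(3, 2, 2),
                 dimnames = list(paste0("s", 1:3), c("A", "B"),
                                 paste0("c", chr, "_m", 1:2)))
    for (j in 1:2) {
      p <- runif(3)
      arr[, 1, j] <- p
      arr[, 2, j] <- 1 - p
    }
    alleleprob(arr, map = c(0, 5), chr = chr)
  }
  probs <- list(mk("1"), mk("2"))
  kl <- calc_kinship_loco(probs)

  brute <- function(left_out) {
    K <- matrix(0, 3, 3)
    cnt <- 0
    for (ci in 1:2) {
      if (ci == left_out) next
      for (j in 1:2) {
        cnt <- cnt + 1
        for (i1 in 1:3) for (i2 in 1:3) {
          K[i1, i2] <- K[i1, i2] +
            sum(unclass(probs[[ci]])[i1, , j] * unclass(probs[[ci]])[i2, , j])
        }
      }
    }
    K / cnt
  }
  expect_equal(unclass(kl[[1]]), brute(1), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(kl[[2]]), brute(2), ignore_attr = TRUE, tolerance = 1e-12)
  expect_match(attr(kl[[1]], "tag"), "1 left out")
})

test_that("kinship for identical genomes equals the diagonal entry", {
  arr <- array(0, dim = c(2, 2, 3),
               dimnames = list(c("s1", "s2"), c("A", "B"), paste0("m", 1:3)))
  p <- c(0.2, 0.9, 0.5)
  for (j in 1:3) arr[, , j] <- rbind(c(p[j], 1 - p[j]), c(p[j], 1 - p[j]))
  probs <- list(alleleprob(arr, map = 0:2, chr = "1"),
                alleleprob(arr, map = 0:2, chr = "2"))
  K <- calc_kinship_loco(probs)[[1]]
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[2, 1], K[2, 2])
})

test_that("the left-out chromosome does not influence its LOCO matrix", {
  g <- tiny_genome(n = 8, seed = 3)
  k_before <- calc_kinship_loco(g$probs)[[1]]
  # perturb chromosome 1 only (mix each marker towards uniform)
  p1 <- unclass(g$probs[[1]])
  p1 <- 0.5 * p1 + 0.5 / dim(p1)[2]
  probs2 <- list(alleleprob(p1, attr(g$probs[[1]], "map"), "1"), g$probs[[2]])
  k_after <- calc_kinship_loco(probs2)[[1]]
  expect_identical(unclass(k_before), unclass(k_after))
})

test_that("LOCO kinship is invariant to marker order within a chromosome", {
  g <- tiny_genome(n = 8, seed = 9)
  k1 <- calc_kinship_loco(g$probs)[[1]]
  p2 <- unclass(g$probs[[2]])
  perm <- rev(seq_len(dim(p2)[3]))
  # reversing marker order also reverses the (equally spaced) map
  probs_rev <- alleleprob(p2[, , perm],
                          map = rev(max(attr(g$probs[[2]], "map")) -
                                      attr(g$probs[[2]], "map")),
                          chr = "2")
  k1b <- calc_kinship_loco(list(g$probs[[1]], probs_rev))[[1]]
  expect_equal(unclass(k1), unclass(k1b), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("kinship diagonal lies in (0, 1] and single chromosome is fatal", {
  g <- tiny_genome(n = 15, seed = 21)
  for (K in calc_kinship_loco(g$probs)) {
    expect_true(all(diag(K) > 0 & diag(K) <= 1 + 1e-12))
  }
  expect_error(calc_kinship_loco(g$probs[1]), "at least two chromosomes")
})
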