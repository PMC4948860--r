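test_that("individual-pool null preserves both margins on every draw", {
  withr::with_seed(301, {
    for (rep in 1:25) {
      m <- random_community(sample(2:8, 1), sample(2:10, 1))
      r <- individual_pool_null(m)
      expect_identical(rowSums(r), rowSums(m))
      expect_identical(colSums(r), colSums(m))
      expect_identical(dimnames(r), dimnames(m))
    }
  })
})

test_that("degenerate margins force the identity", {
  m <- matrix(c(3L, 0L, 2L), 1, 3,
              dimnames = list("only", c("a", "b", "c")))
  expect_identical(individual_pool_null(m, seed = 1), m)
  expect_error(individual_pool_null(m * 0L), class = "stageshift_invalid_argument")
})

test_that("the pool null is uniform over the two tables of a 2x2 permutation", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(c("i1", "i2"), c("s1", "s2")))
  withr::with_seed(302, {
    hits <- replicate(2000, individual_pool_null(m)[1, 1])
  })
  expect_lt(abs(mean(hits) - 0.5), 0.05)
})

test_that("the pool null reproduces the hypergeometric table weights", {
  # margins (2,2)/(2,2): cell11 in {0,1,2} with weights (1,4,1)/6 under the
  # individual-permutation law; r2dtable samples the same conditional law
  m <- matrix(c(1L, 1L, 1L, 1L), 2, 2,
              dimnames = list(c("i1", "i2"), c("s1", "s2")))
  m[1, 1] <- 2L; m[2, 2] <- 2L; m[1, 2] <- 0L; m[2, 1] <- 0L
  withr::with_seed(303, {
    ours <- table(factor(replicate(3000, individual_pool_null(m)[1, 1]),
                         levels = 0:2)) / 3000
    ref <- table(factor(vapply(stats::r2dtable(3000, c(2, 2), c(2, 2)),
                               function(t) t[1, 1], numeric(1)),
                        levels = 0:2)) / 3000
  })
  expect_equal(as.numeric(ours), c(1, 4, 1) / 6, tolerance = 0.12)
  expect_equal(as.numeric(ours), as.numeric(ref), tolerance = 0.12)
})

test_that("independent swap preserves occurrences, richness and species totals", {
  withr::with_seed(304, {
    for (rep in 1:25) {
      m <- random_community(sample(3:8, 1), sample(3:10, 1), lambda = 0.8)
      r <- independent_swap(m, n_iterations = 2000)
      expect_identical(colSums(r > 0), colSums(m > 0))   # occurrence frequency
      expect_identical(rowSums(r > 0), rowSums(m > 0))   # island richness
      expect_identical(colSums(r), colSums(m))           # species abundance
      # each species keeps its multiset of positive abundances
      for (s in seq_len(ncol(m))) {
        expect_identical(sort(unname(r[r[, s] > 0, s])),
                         sort(unname(m[m[, s] > 0, s])))
      }
    }
  })
})

test_that("a matrix with no checkerboard is returned unchanged with a notice", {
  m <- matrix(c(2L, 1L, 1L, 3L), 2, 2,
              dimnames = list(c("i1", "i2"), c("s1", "s2")))
  expect_message(r <- independent_swap(m, n_iterations = 500, seed = 1),
                 "checkerboard")
  expect_identical(r, m)
})

test_that("the two-state checkerboard chain visits both states equally", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(c("i1", "i2"), c("s1", "s2")))
  withr::with_seed(305, {
    states <- replicate(2000, independent_swap(m, n_iterations = 7)[1, 1])
  })
  expect_lt(abs(mean(states) - 0.5), 0.05)
})

test_that("null ensembles have the contracted shape and are seed-reproducible", {
  withr::with_seed(306, {
    older <- random_community(6, 12)
    younger <- random_community(6, 12)
  })
  ens <- null_diff_ensemble(older, younger, "SD", n_rand = 2, seed = 9)
  expect_equal(dim(ens$diffs), c(6, 2))
  e1 <- null_diff_ensemble(older, younger, "SD", n_rand = 50, seed = 11)
  e2 <- null_diff_ensemble(older, younger, "SD", n_rand = 50, seed = 11)
  expect_identical(e1$diffs, e2$diffs)
  phy <- withr::with_seed(307, ape::rphylo(12, 1, 0))
  colnames(older) <- colnames(younger) <- phy$tip.label
  p1 <- null_diff_ensemble(older, younger, "PD", phylo = phy, n_rand = 20,
                           seed = 13, n_swap = 2000)
  p2 <- null_diff_ensemble(older, younger, "PD", phylo = phy, n_rand = 20,
                           seed = 13, n_swap = 2000)
  expect_identical(p1$diffs, p2$diffs)
  expect_error(null_diff_ensemble(older, younger, "PD", n_rand = 10),
               class = "stageshift_invalid_argument")
})

test_that("identical stages give ensemble diffs centred on zero", {
  withr::with_seed(308, {
    m <- random_community(8, 15, lambda = 3)
    ens <- null_diff_ensemble(m, m, "SD", n_rand = 400)
    for (i in seq_len(nrow(m))) {
      se <- sd(ens$diffs[i, ]) / sqrt(ncol(ens$diffs))
      expect_lt(abs(mean(ens$diffs[i, ])), 2.5 * max(se, 1e-9))
    }
  })
})

test_that("older and younger stages are randomized independently", {
  withr::with_seed(309, {
    older <- random_community(10, 20, lambda = 2)
    younger <- random_community(10, 20, lambda = 4)
    rich <- function(m) rowSums(m > 0)
    draws <- replicate(500, c(rich(individual_pool_null(older))[1],
                              rich(individual_pool_null(younger))[1]))
    expect_lt(abs(cor(draws[1, ], draws[2, ])), 0.12)
  })
})
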