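test_that("per-island diversity follows the richness and PD definitions", {
  m <- matrix(c(3L, 0L, 1L,
                0L, 0L, 0L,
                2L, 2L, 2L), 3, 3, byrow = TRUE,
              dimnames = list(c("i1", "i2", "i3"), c("A", "B", "C")))
  expect_warning(sd_v <- diversity_by_island(m, "SD"), "no individuals")
  expect_equal(unname(sd_v), c(2, 0, 3))
  phy <- parse_newick("((A:1,B:1):1,C:2);")
  expect_warning(pd_v <- diversity_by_island(m, "PD", phy), "no individuals")
  expect_equal(unname(pd_v), c(4, 0, 5)) # {A,C} spans 1+1+2; all tips span 5
  expect_error(diversity_by_island(m, "PD"), class = "stageshift_invalid_argument")
})

test_that("z-scores use the sample sd and handle degenerate ensembles", {
  expect_equal(z_score(0, c(-1, 0, 1))$z, 0)
  zs <- z_score(3, c(-2, -1, 0, 1, 2))
  expect_equal(zs$z, 3 / sqrt(2.5), tolerance = 1e-12)
  expect_equal(zs$null_sd, sqrt(2.5))
  deg <- z_score(5, c(2, 2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$z, Inf)
  expect_equal(z_score(2, c(2, 2, 2))$z, 0)
  expect_error(z_score(1, 3), class = "stageshift_invalid_argument")
})

test_that("standardization is antisymmetric in the stage order", {
  withr::with_seed(401, {
    for (i in 1:20) {
      obs <- rnorm(1, sd = 3)
      nulls <- rnorm(sample(5:50, 1))
      expect_identical(z_score(-obs, -nulls)$z, -z_score(obs, nulls)$z)
    }
  })
})

test_that("significance follows the rank formula and the t-tail", {
  nulls <- seq_len(999)
  expect_equal(shift_significance(0, nulls, "rank"), 1 / 1000)
  expect_equal(shift_significance(1000, nulls, "rank"), 1 / 1000)
  sym <- c(-(1:500), 1:500)
  expect_equal(shift_significance(0, sym, "rank"), 0.5, tolerance = 0.01)
  z <- z_score(3, nulls)$z
  expect_equal(shift_significance(3, nulls), pt(-abs(z), df = 998))
  expect_error(shift_significance(1, nulls, "bogus"))
})

test_that("mechanism classification follows the joint SD/PD pattern table", {
  both_neg <- classify_assembly(-3, 0.001, -2.5, 0.004)
  expect_equal(both_neg$pattern_sd, "clustering")
  expect_setequal(both_neg$mechanisms[[1]],
                  c("environmental_filtering", "dispersal_limitation"))
  comp <- classify_assembly(-3, 0.001, 2.5, 0.004)
  expect_equal(comp$mechanisms[[1]], "interspecific_competition")
  rand <- classify_assembly(0.1, 0.8, -0.2, 0.7)
  expect_equal(rand$mechanisms[[1]], "random_process")
  expect_false(rand$unclassified)
  dens <- classify_assembly(2.2, 0.01, 3.0, 0.002)
  expect_equal(dens$mechanisms[[1]], "density_dependence")
  odd <- classify_assembly(2.2, 0.01, -3.0, 0.002)
  expect_true(odd$unclassified)
  expect_equal(odd$mechanisms[[1]], "random_process")
  expect_error(classify_assembly(1, 0.5, 1, 0.5, alpha = 1.2),
               class = "stageshift_invalid_argument")
})

test_that("classification is a pure, exhaustive function of (z, p, alpha)", {
  withr::with_seed(402, {
    z_sd <- rnorm(300); z_pd <- rnorm(300)
    p_sd <- runif(300); p_pd <- runif(300)
  })
  out <- classify_assembly(z_sd, p_sd, z_pd, p_pd, alpha = 0.1)
  out2 <- classify_assembly(z_sd, p_sd, z_pd, p_pd, alpha = 0.1)
  expect_identical(out, out2)
  expect_true(all(lengths(out$mechanisms) >= 1))
  # recompute the pattern logic independently
  pat <- function(z, p) {
    ifelse(p <= 0.1 & z < 0, "clustering",
           ifelse(p <= 0.1 & z > 0, "overdispersed", "random"))
  }
  expect_identical(out$pattern_sd, pat(z_sd, p_sd))
  expect_identical(out$pattern_pd, pat(z_pd, p_pd))
})

test_that("transition tables have the contracted shape and are reproducible", {
  ds <- simulate_dataset(scenario_config(n_islands = 5, n_species = 15, seed = 8))
  tt <- transition_table(ds, ds$phylogeny, n_rand = 39, seed = 10, n_swap = 3000)
  expect_equal(nrow(tt), 6 * 2 * 2) # 5 islands + reference site
  expect_setequal(unique(tt$transition), c("SS", "ST"))
  expect_setequal(unique(tt$metric), c("SD", "PD"))
  expect_true(all(tt$null_sd >= 0))
  expect_true(all(is.finite(tt$z[tt$null_sd > 0])))
  tt2 <- transition_table(ds, ds$phylogeny, n_rand = 39, seed = 10, n_swap = 3000)
  expect_identical(as.data.frame(tt), as.data.frame(tt2))
  # SS compares sapling - seedling, ST compares tree - sapling
  sd_ss <- tt[tt$transition == "SS" & tt$metric == "SD", ]
  rich <- function(m) rowSums(m > 0)
  expect_equal(sd_ss$obs_diff[match(rownames(ds$communities$seedling),
                                    sd_ss$island_id)],
               unname(rich(ds$communities$sapling) -
                        rich(ds$communities$seedling)))
  # misaligned labels rejected with offenders named
  bad <- ds$communities
  rownames(bad$tree)[1] <- "elsewhere"
  expect_error(transition_table(bad, ds$phylogeny, n_rand = 5),
               "elsewhere")
})

test_that("assembly calls join both metrics per island and transition", {
  ds <- simulate_dataset(scenario_config(n_islands = 5, n_species = 15, seed = 9))
  tt <- transition_table(ds, ds$phylogeny, n_rand = 39, seed = 12, n_swap = 3000)
  calls <- assembly_calls(tt, alpha = 0.05)
  expect_equal(nrow(calls), 6 * 2)
  expect_true(all(c("pattern_sd", "pattern_pd", "mechanisms") %in% names(calls)))
  expect_true(all(lengths(calls$mechanisms) >= 1))
})
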