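test_that("pure-birth phylogenies are binary, labelled, ultrametric, reproducible", {
  expect_error(simulate_phylogeny(1), class = "stageshift_invalid_argument")
  phy2 <- simulate_phylogeny(2, seed = 1)
  expect_equal(length(phy2$tip.label), 2)
  expect_equal(phy2$Nnode, 1)
  expect_identical(ape::write.tree(simulate_phylogeny(92, seed = 42)),
                   ape::write.tree(simulate_phylogeny(92, seed = 42)))
  phy <- simulate_phylogeny(50, seed = 7)
  depths <- ape::node.depth.edgelength(phy)[seq_len(50)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_true(all(phy$edge.length > 0))
  expect_false(anyDuplicated(phy$tip.label) > 0)
})

test_that("Brownian traits follow the branch-length covariance", {
  phy <- simulate_phylogeny(32, seed = 11)
  expect_error(simulate_traits_bm(phy, sigma2 = 0),
               class = "stageshift_invalid_argument")
  # vanishing-rate limit: traits collapse to the root value 0
  tiny <- simulate_traits_bm(phy, sigma2 = 1e-12, seed = 2)
  expect_lt(max(abs(tiny)), 1e-4)
  # near-star tree: tip traits near-independent
  star <- ape::stree(24, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  withr::with_seed(12, {
    xs <- replicate(300, simulate_traits_bm(star, sigma2 = 1))
    cc <- cor(t(xs))
    expect_lt(max(abs(cc[upper.tri(cc)])), 0.35)
  })
  # Monte-Carlo tip covariance vs sigma2 * vcv, relative Frobenius error
  # (2000 replicates keep the Monte-Carlo noise floor well under the bound)
  withr::with_seed(13, {
    reps <- replicate(2000, simulate_traits_bm(phy, sigma2 = 2))
  })
  emp <- cov(t(reps))
  expected <- 2 * ape::vcv(phy)[rownames(emp), colnames(emp)]
  rel <- norm(emp - expected, "F") / norm(expected, "F")
  expect_lt(rel, 0.10)
})

test_that("island attributes respect ranges, SI bound and determinism", {
  a1 <- simulate_island_attributes(40, seed = 5)
  a2 <- simulate_island_attributes(40, seed = 5)
  expect_identical(a1, a2)
  expect_true(all(a1$shape_index >= 1))
  expect_true(all(a1$area_ha >= 0.25 & a1$area_ha <= 200))
  expect_true(all(a1$isolation_km >= 0))
  expect_equal(shape_index(a1$area_ha, a1$perimeter_km), a1$shape_index,
               tolerance = 1e-12)
  ref <- simulate_island_attributes(10, seed = 6, include_reference = TRUE)
  expect_equal(nrow(ref), 11)
  expect_true(ref$is_reference[11])
  expect_equal(ref$isolation_km[11], 0)
  expect_gt(ref$area_ha[11], max(ref$area_ha[1:10]))
})

test_that("generated metacommunities are nested across stages for every process", {
  for (proc in c("neutral", "filtering", "competition",
                 "dispersal_limitation", "density_dependence")) {
    ds <- simulate_dataset(scenario_config(
      n_islands = 6, n_species = 20, process_ss = proc, process_st = proc,
      strength = 5, seed = 21
    ))
    expect_true(all(ds$communities$sapling <= ds$communities$seedling),
                label = paste("sapling <= seedling under", proc))
    expect_true(all(ds$communities$tree <= ds$communities$sapling),
                label = paste("tree <= sapling under", proc))
    expect_true(all(colnames(ds$communities$seedling) %in%
                      ds$phylogeny$tip.label))
  }
})

test_that("strength zero reduces every process to the neutral generator exactly", {
  base <- simulate_dataset(scenario_config(n_islands = 6, n_species = 20,
                                           strength = 0, seed = 33))
  for (proc in c("filtering", "competition", "dispersal_limitation",
                 "density_dependence")) {
    alt <- simulate_dataset(scenario_config(
      n_islands = 6, n_species = 20, process_ss = proc, process_st = proc,
      strength = 0, seed = 33
    ))
    expect_identical(alt$communities, base$communities)
  }
})

test_that("weak processes are statistically indistinguishable from neutral", {
  z_arm <- function(proc, strength, seeds) {
    vapply(seeds, function(s) {
      ds <- simulate_dataset(scenario_config(
        n_islands = 8, n_species = 25, process_ss = proc, strength = strength,
        seed = s, include_reference = FALSE
      ))
      tt <- transition_table(ds, ds$phylogeny, n_rand = 59, seed = s,
                             metrics_used = "SD")
      mean(abs(tt$z[tt$transition == "SS"]))
    }, numeric(1))
  }
  neutral <- z_arm("neutral", 0, 1:40)
  weak <- z_arm("filtering", 0.05, 41:80)
  expect_gt(stats::t.test(neutral, weak)$p.value, 0.01)
})

test_that("high-strength processes recover the predicted shift directions", {
  med_z <- function(proc, transition, strength = 8) {
    ds <- simulate_dataset(scenario_config(
      n_islands = 20, n_species = 40,
      process_ss = if (transition == "SS") proc else "neutral",
      process_st = if (transition == "ST") proc else "neutral",
      strength = strength, seed = 55, include_reference = FALSE
    ))
    tt <- transition_table(ds, ds$phylogeny, n_rand = 99, seed = 56,
                           n_swap = 10000)
    list(sd = median(tt$z[tt$transition == transition & tt$metric == "SD"]),
         pd = median(tt$z[tt$transition == transition & tt$metric == "PD"]))
  }
  filt <- med_z("filtering", "SS")
  expect_lt(filt$sd, 0)
  expect_lt(filt$pd, 0)
  disp <- med_z("dispersal_limitation", "SS")
  expect_lt(disp$sd, 0)
  expect_lt(disp$pd, 0)
  dens <- med_z("density_dependence", "ST")
  expect_gt(dens$sd, 0)
  expect_gt(dens$pd, 0)
})

test_that("trait/tip mismatches and bad configs are rejected", {
  cfg <- scenario_config(n_islands = 4, n_species = 10, seed = 1)
  phy <- simulate_phylogeny(10, seed = 1)
  attrs <- simulate_island_attributes(4, seed = 1)
  expect_error(
    simulate_metacommunity(cfg, phy, setNames(rnorm(10), paste0("x", 1:10)), attrs),
    class = "stageshift_schema_error"
  )
  expect_error(scenario_config(n_islands = 1), class = "stageshift_invalid_argument")
  expect_error(scenario_config(n_species = 2), class = "stageshift_invalid_argument")
  expect_error(scenario_config(strength = -1), class = "stageshift_invalid_argument")
})

test_that("quadrat subsampling thins only the observed seedling matrix", {
  full <- simulate_dataset(scenario_config(n_islands = 6, n_species = 20,
                                           seed = 44))
  sub <- simulate_dataset(scenario_config(n_islands = 6, n_species = 20,
                                          seed = 44, quadrat_sampling = TRUE))
  expect_identical(sub$communities$sapling, full$communities$sapling)
  expect_lte(sum(sub$communities$seedling), sum(full$communities$seedling))
})

test_that("datasets round-trip through the pipeline file formats", {
  ds <- simulate_dataset(scenario_config(n_islands = 5, n_species = 15, seed = 77))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  comm <- read_communities(paths["communities"])
  # zero-everywhere species are absent from the long format by design
  expect_identical(
    comm$seedling,
    ds$communities$seedling[rownames(comm$seedling), colnames(comm$seedling)]
  )
  phy <- read_phylogeny(paths["phylogeny"])
  expect_true(ape::all.equal.phylo(phy, ds$phylogeny, use.edge.length = TRUE))
  attrs <- island_attributes(readr::read_csv(paths["attributes"],
                                             show_col_types = FALSE))
  expect_equal(attrs$area_ha, ds$attributes$area_ha)
})
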