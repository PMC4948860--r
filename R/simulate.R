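#' Scenario configuration for the synthetic metacommunity generator
#'
#' Bundles the generative "truth" of a synthetic dataset: landscape size,
#' species pool, the assembly process acting on each life-stage transition,
#' and its strength. `strength = 0` reduces every process to neutral.
#'
#' Cohort-size defaults emulate natural stand thinning: seedling cohorts are
#' roughly an order of magnitude larger than sapling cohorts, which exceed
#' tree cohorts (`seedling_n` individuals per island, thinned by
#' `survival_ss` and then `survival_st`). Census effort is equal across
#' islands, so per-island statistical power is comparable.
#'
#' @param n_islands number of islands (>= 2), excluding the optional
#'   mainland reference site.
#' @param n_species size of the regional species pool (>= 3).
#' @param process_ss,process_st assembly process acting on the
#'   seedling-to-sapling and sapling-to-tree transition: one of
#'   `"neutral"`, `"filtering"`, `"competition"`, `"dispersal_limitation"`,
#'   `"density_dependence"`.
#' @param strength dimensionless process strength (>= 0); 0 is neutral.
#' @param abundance_distribution regional abundance model, `"logseries"`
#'   (default; strong rarity skew typical of tree communities) or
#'   `"lognormal"`.
#' @param seed integer seed governing every random choice downstream.
#' @param seedling_n seedling individuals censused per island.
#' @param survival_ss,survival_st mean survival fraction across each
#'   transition.
#' @param include_reference add a mainland-like reference site (largest
#'   area, zero isolation), flagged `is_reference`.
#' @param quadrat_sampling if `TRUE`, the returned seedling matrix is
#'   additionally subsampled as if censused in 1x1 m quadrats whose count
#'   scales with log island area (4 to 48); an observation-process option,
#'   off by default so that stages are full censuses.
#' @param logseries_theta log-series parameter in (0, 1).
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_islands = 29, n_species = 92,
                            process_ss = "neutral", process_st = "neutral",
                            strength = 0,
                            abundance_distribution = c("logseries", "lognormal"),
                            seed = 1, seedling_n = 1000,
                            survival_ss = 0.12, survival_st = 0.25,
                            include_reference = TRUE,
                            quadrat_sampling = FALSE,
                            logseries_theta = 0.98) {
  processes <- c("neutral", "filtering", "competition",
                 "dispersal_limitation", "density_dependence")
  cfg <- list(
    n_islands = check_count(n_islands, "n_islands", min = 2L),
    n_species = check_count(n_species, "n_species", min = 3L),
    process_ss = match.arg(process_ss, processes),
    process_st = match.arg(process_st, processes),
    strength = check_number(strength, "strength", min = 0),
    abundance_distribution = match.arg(abundance_distribution),
    seed = check_count(seed, "seed", min = 0L),
    seedling_n = check_count(seedling_n, "seedling_n", min = 10L),
    survival_ss = check_number(survival_ss, "survival_ss", min = 0, strict = TRUE),
    survival_st = check_number(survival_st, "survival_st", min = 0, strict = TRUE),
    include_reference = isTRUE(include_reference),
    quadrat_sampling = isTRUE(quadrat_sampling),
    logseries_theta = check_number(logseries_theta, "logseries_theta",
                                   min = 0, strict = TRUE)
  )
  if (cfg$survival_ss > 1 || cfg$survival_st > 1) {
    stop_invalid("survival fractions must be in (0, 1]")
  }
  if (cfg$logseries_theta >= 1) stop_invalid("logseries_theta must be < 1")
  structure(cfg, class = "scenario_config")
}

#' Simulate a pure-birth ultrametric phylogeny
#'
#' A Yule (pure-birth) tree with `n_species` uniquely labelled tips
#' (`sp001`, `sp002`, ...), strictly positive branch lengths, ultrametric by
#' construction.
#'
#' @param n_species number of tips (>= 2).
#' @param seed optional integer seed.
#' @return an [ape::phylo].
#' @export
simulate_phylogeny <- function(n_species, seed = NULL) {
  n_species <- check_count(n_species, "n_species", min = 2L)
  set_seed_if(seed)
  phy <- ape::rphylo(n_species, birth = 1, death = 0)
  phy$tip.label <- sprintf("sp%03d", seq_len(n_species))
  phy
}

#' Simulate a Brownian-motion trait on a phylogeny
#'
#' Tip values of a Brownian motion with variance rate `sigma2` started at 0
#' at the root, so the tip covariance equals `sigma2` times the
#' shared-branch-length matrix.
#'
#' @param phylo an [ape::phylo].
#' @param sigma2 Brownian variance rate (> 0).
#' @param seed optional integer seed.
#' @return named numeric vector over the tips.
#' @export
simulate_traits_bm <- function(phylo, sigma2 = 1, seed = NULL) {
  phylo <- validate_phylo(phylo)
  sigma2 <- check_number(sigma2, "sigma2", min = 0, strict = TRUE)
  set_seed_if(seed)
  ape::rTraitCont(phylo, model = "BM", sigma = sqrt(sigma2), root.value = 0)
}

#' Simulate island attributes for a fragmented landscape
#'
#' Areas log-uniform over `area_range` (default 0.25 to 200 ha), shape
#' indices >= 1 with a right-skewed excess, perimeters derived from area and
#' shape index, isolations log-uniform over `isolation_range`, and sampling
#' areas following the plot-census rule (full census below 1 ha, 0.5 ha
#' plots to 5 ha, 1 ha plots beyond). With `include_reference = TRUE` a
#' mainland-like site with zero isolation and area above the island range is
#' appended and flagged.
#'
#' @param n_islands number of islands (>= 1).
#' @param seed optional integer seed.
#' @param area_range island area range in hectares.
#' @param isolation_range isolation range in kilometers.
#' @param include_reference append the mainland reference row.
#' @return a tibble as in [island_attributes()].
#' @export
simulate_island_attributes <- function(n_islands, seed = NULL,
                                       area_range = c(0.25, 200),
                                       isolation_range = c(0.01, 4),
                                       include_reference = FALSE) {
  n_islands <- check_count(n_islands, "n_islands", min = 1L)
  set_seed_if(seed)
  area <- exp(runif(n_islands, log(area_range[1]), log(area_range[2])))
  si <- 1 + rgamma(n_islands, shape = 1.5, scale = 0.45)
  perim_km <- si * 2 * sqrt(pi * area * 1e4) / 1e3
  iso <- exp(runif(n_islands, log(isolation_range[1]), log(isolation_range[2])))
  out <- tibble::tibble(
    island_id = sprintf("isl%03d", seq_len(n_islands)),
    area_ha = area,
    perimeter_km = perim_km,
    shape_index = si,
    isolation_km = iso,
    sampling_area_ha = sampling_area_rule(area),
    is_reference = FALSE
  )
  if (include_reference) {
    ref_area <- area_range[2] * 6
    ref_si <- 1 + rgamma(1, shape = 1.5, scale = 0.45)
    out <- dplyr::bind_rows(out, tibble::tibble(
      island_id = "mainland",
      area_ha = ref_area,
      perimeter_km = ref_si * 2 * sqrt(pi * ref_area * 1e4) / 1e3,
      shape_index = ref_si,
      isolation_km = 0,
      sampling_area_ha = 1,
      is_reference = TRUE
    ))
  }
  out
}

# Early-burst rescaling of branch lengths: trait evolution concentrated
# near the root (rate decaying as exp(-rate * relative depth)), so the
# resulting niche trait is conserved deep in the phylogeny.
early_burst_tree <- function(phylo, rate = 6) {
  depths <- ape::node.depth.edgelength(phylo)
  total <- max(depths)
  h0 <- depths[phylo$edge[, 1]] / total
  h1 <- depths[phylo$edge[, 2]] / total
  phylo$edge.length <- (exp(-rate * h0) - exp(-rate * h1)) / rate * total
  phylo
}

# i.i.d. log-series abundances: P(k) proportional to theta^k / k
rlogseries <- function(n, theta, kmax = 5000L) {
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = theta^k / k)
}

regional_weights <- function(cfg) {
  if (cfg$abundance_distribution == "logseries") {
    w <- rlogseries(cfg$n_species, cfg$logseries_theta)
  } else {
    w <- stats::rlnorm(cfg$n_species, meanlog = 0, sdlog = 1.2)
  }
  w / sum(w)
}

# per-island per-species survival weights for one transition; `opt` is the
# vector of habitat-patch optima available on the island
process_weights <- function(process, strength, comm_row, traits, disp01,
                            opt, iso01, phylo_sim, priority = NULL) {
  s_present <- comm_row > 0
  w <- rep(1, length(comm_row))
  if (strength == 0 || process == "neutral") return(w)
  if (process == "filtering") {
    # a species survives via its best-matching habitat patch; larger
    # islands hold more patches, so their communities are filtered less
    sd_t <- stats::sd(traits)
    dev2 <- vapply(opt, function(o) ((traits - o) / sd_t)^2,
                   numeric(length(traits)))
    w <- exp(-strength * apply(dev2, 1, min))
  } else if (process == "dispersal_limitation") {
    w <- exp(-strength * iso01 * disp01)
  } else if (process == "density_dependence") {
    n_tot <- sum(comm_row)
    s_n <- sum(s_present)
    if (n_tot > 0 && s_n > 0) {
      freq <- comm_row / n_tot
      w <- exp(-strength * freq * s_n)
    }
  } else if (process == "competition") {
    n_tot <- sum(comm_row)
    if (n_tot > 0) {
      # asymmetric competition among close relatives: a species is
      # suppressed by the abundance of phylogenetically similar species
      # that outrank it in the island's local competitive hierarchy
      # (priority), so each island keeps its own clade winners
      rel <- comm_row / n_tot
      outranked <- phylo_sim * outer(priority, priority, "<")
      # scale by local richness so the penalty is O(1) whatever the pool size
      crowd <- as.numeric(outranked %*% rel) * sum(comm_row > 0)
      w <- exp(-strength * crowd)
    }
  }
  w
}

thin_stage <- function(comm, rate, process, strength, traits, disp01, opts,
                       iso01, phylo_sim) {
  # competitive exclusion is a lottery with positive feedback: thinning in
  # rounds, recomputing crowding from the current survivors, lets locally
  # abundant lineages exclude their relatives island by island
  rounds <- if (process == "competition" && strength > 0) 10L else 1L
  rate_r <- rate^(1 / rounds)
  out <- comm
  for (i in seq_len(nrow(comm))) {
    row <- comm[i, ]
    # local competitive hierarchy, persistent across rounds on this island
    priority <- runif(length(row))
    for (k in seq_len(rounds)) {
      if (sum(row) == 0) break
      w <- process_weights(process, strength, row, traits, disp01,
                           opts[[i]], iso01[i], phylo_sim,
                           priority = priority)
      wbar <- sum(row * w) / sum(row)
      p <- pmin(1, rate_r * w / wbar)
      row <- rbinom(length(row), row, p)
    }
    out[i, ] <- row
  }
  out
}

#' Simulate a three-life-stage metacommunity with known assembly processes
#'
#' Seedling communities are assembled by multinomial colonization from a
#' shared regional pool (with isolation-dependent, dispersal-trait-weighted
#' colonization when the SS process is dispersal limitation). Each
#' transition then thins individuals binomially with species survival
#' weights set by the scenario's process:
#' * `filtering` — survival decays with squared distance between the
#'   species trait and the best-matching of the island's habitat-patch
#'   optima; patch number grows with log area, so small islands filter
#'   hardest (area-driven loss of rare habitats).
#' * `competition` — survival decays with abundance-weighted phylogenetic
#'   similarity to co-occurring heterospecifics.
#' * `dispersal_limitation` — survival decays with island isolation times a
#'   phylogenetically conserved dispersal-limitation score.
#' * `density_dependence` — survival decays with conspecific relative
#'   density.
#' * `neutral` — uniform thinning.
#'
#' Abundances are nested by construction: tree <= sapling <= seedling for
#' every island and species (unless `quadrat_sampling` subsamples the
#' observed seedling matrix).
#'
#' @param config a [scenario_config()].
#' @param phylo phylogeny over the species pool (tips = species labels).
#' @param traits named per-species trait vector (indexed by tip labels).
#' @param attributes island attribute tibble ([island_attributes()] layout);
#'   row count must match `n_islands` plus the reference row if present.
#' @return a `synthetic_dataset`: list with `communities` (named list of
#'   three islands x species integer matrices), `phylogeny`, `traits`,
#'   `attributes`, `truth` (the config).
#' @export
simulate_metacommunity <- function(config, phylo, traits, attributes) {
  if (!inherits(config, "scenario_config")) {
    stop_invalid("config must be a scenario_config")
  }
  phylo <- validate_phylo(phylo)
  sp <- phylo$tip.label
  if (is.null(names(traits)) || !setequal(names(traits), sp)) {
    stop_schema("traits must be named by the phylogeny tip labels")
  }
  traits <- traits[sp]
  attributes <- island_attributes(attributes)
  n_isl <- nrow(attributes)
  set.seed(config$seed)

  w_regional <- regional_weights(config)
  # phylogenetically conserved dispersal-limitation score in [0, 1]
  disp01 <- rank01(ape::rTraitCont(phylo, model = "BM", sigma = 1))
  # habitat patches: larger islands hold more habitat types (1 or 2 along
  # the log-area gradient), each with an optimum drawn from the empirical
  # trait distribution (with jitter) so every optimum corresponds to
  # viable niche space; area-driven loss of rare habitats is what makes
  # filtering strongest on the smallest islands
  n_patch <- 1L + as.integer(round(rank01(log(attributes$area_ha))))
  opts <- lapply(n_patch, function(k) {
    sample(as.numeric(traits), k, replace = TRUE) +
      stats::rnorm(k, 0, 0.1 * stats::sd(traits))
  })
  iso01 <- rank01(attributes$isolation_km)
  d <- ape::cophenetic.phylo(phylo)[sp, sp]
  # clade-local similarity kernel: decay scale set to a fifth of the mean
  # pairwise distance so only close relatives compete appreciably
  phylo_sim <- exp(-d / (0.12 * mean(d[upper.tri(d)])))

  # equal census effort: every island contributes a cohort of the same
  # size, so statistical power is comparable across islands and the
  # sampling-area attribute carries no signal of its own
  n_see <- rep(config$seedling_n, n_isl)
  seedling <- matrix(0L, n_isl, length(sp),
                     dimnames = list(attributes$island_id, sp))
  for (i in seq_len(n_isl)) {
    w <- w_regional
    if (config$process_ss == "dispersal_limitation" && config$strength > 0) {
      w <- w * exp(-config$strength * iso01[i] * disp01)
      w <- w / sum(w)
    }
    seedling[i, ] <- rmultinom(1, n_see[i], w)
  }

  sapling <- thin_stage(seedling, config$survival_ss, config$process_ss,
                        config$strength, traits, disp01, opts,
                        iso01, phylo_sim)
  tree <- thin_stage(sapling, config$survival_st, config$process_st,
                     config$strength, traits, disp01, opts,
                     iso01, phylo_sim)

  if (config$quadrat_sampling) {
    quadrats <- round(4 + 44 * rank01(log(attributes$area_ha)))
    frac <- quadrats / max(quadrats)
    for (i in seq_len(n_isl)) {
      seedling[i, ] <- rbinom(ncol(seedling), seedling[i, ], frac[i])
    }
  }
  storage.mode(seedling) <- "integer"
  storage.mode(sapling) <- "integer"
  storage.mode(tree) <- "integer"

  structure(
    list(
      communities = list(seedling = seedling, sapling = sapling, tree = tree),
      phylogeny = phylo, traits = traits, attributes = attributes,
      truth = config
    ),
    class = "synthetic_dataset"
  )
}

#' One-call synthetic dataset
#'
#' Generates phylogeny, traits, island attributes and the three-stage
#' metacommunity from a single [scenario_config()], deriving all component
#' seeds from `config$seed`.
#'
#' @param config a [scenario_config()] (or arguments forwarded to it).
#' @param ... forwarded to [scenario_config()] when `config` is missing.
#' @return a `synthetic_dataset`; see [simulate_metacommunity()].
#' @examples
#' ds <- simulate_dataset(scenario_config(n_islands = 5, n_species = 20, seed = 7))
#' sapply(ds$communities, sum)
#' @export
simulate_dataset <- function(config = scenario_config(...), ...) {
  if (!inherits(config, "scenario_config")) {
    stop_invalid("config must be a scenario_config")
  }
  set.seed(config$seed)
  seeds <- child_seeds(4L)
  phylo <- simulate_phylogeny(config$n_species, seed = seeds[1])
  # niche trait: Brownian on an early-burst rescaled tree, i.e. strongly
  # conserved deep in the phylogeny, as habitat niches of woody plants are
  traits <- simulate_traits_bm(early_burst_tree(phylo), sigma2 = 1,
                               seed = seeds[2])
  attributes <- simulate_island_attributes(
    config$n_islands, seed = seeds[3],
    include_reference = config$include_reference
  )
  cfg2 <- config
  cfg2$seed <- seeds[4]
  out <- simulate_metacommunity(cfg2, phylo, traits, attributes)
  out$truth <- config
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d sites x %d species, processes SS=%s ST=%s (strength %.2f)\n",
    nrow(x$communities$seedling), ncol(x$communities$seedling),
    x$truth$process_ss, x$truth$process_st, x$truth$strength
  ))
  counts <- vapply(x$communities, sum, numeric(1))
  cat("  individuals:", paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic dataset to the pipeline's file formats
#'
#' Writes the long-format community CSV, the Newick phylogeny and the
#' attribute CSV that [run_analysis()] and the command-line interface read,
#' so generated data are indistinguishable from user data.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "synthetic_dataset")) {
    stop_invalid("dataset must be a synthetic_dataset")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    communities = file.path(dir, "communities.csv"),
    phylogeny = file.path(dir, "phylogeny.nwk"),
    attributes = file.path(dir, "attributes.csv")
  )
  write_communities(dataset$communities, paths["communities"])
  write_phylogeny(dataset$phylogeny, paths["phylogeny"])
  readr::write_csv(dataset$attributes, paths["attributes"])
  invisible(paths)
}
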