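#' Per-island diversity
#'
#' Species diversity (SD) is species richness: the count of species with
#' positive abundance. Phylogenetic diversity (PD) is Faith's PD of the
#' island's species set (root path included). Islands with no individuals
#' get diversity 0 with a warning.
#'
#' @param comm islands x species abundance matrix with dimnames.
#' @param metric `"SD"` or `"PD"`.
#' @param phylo an [ape::phylo]; required when `metric = "PD"`.
#' @return named numeric vector, one value per island.
#' @export
diversity_by_island <- function(comm, metric = c("SD", "PD"), phylo = NULL) {
  metric <- match.arg(metric)
  comm <- check_community(comm)
  if (metric == "PD" && is.null(phylo)) {
    stop_invalid("metric = \"PD\" requires a phylogeny")
  }
  empty <- rowSums(comm) == 0
  if (any(empty)) {
    warning("island(s) with no individuals get diversity 0: ",
            paste(rownames(comm)[empty], collapse = ", "), call. = FALSE)
  }
  if (metric == "SD") {
    return(setNames(as.numeric(rowSums(comm > 0)), rownames(comm)))
  }
  phylo <- validate_phylo(phylo)
  absent <- setdiff(colnames(comm), phylo$tip.label)
  if (length(absent)) {
    stop_invalid("species not in tree: ", paste(absent, collapse = ", "))
  }
  eng <- edge_tip_incidence(prune_to_species(phylo, colnames(comm)))
  ord <- match(colnames(comm), colnames(eng$incidence))
  out <- pd_rows(eng, comm, ord)
  out[empty] <- 0
  setNames(out, rownames(comm))
}

#' Standardize an observed difference against a null ensemble
#'
#' \eqn{z = (obs - mean(null)) / sd(null)} with the sample (n-1) standard
#' deviation. A degenerate ensemble (sd = 0) yields z = 0 when the observed
#' difference equals the null mean and signed infinity otherwise, flagged in
#' the `degenerate` column.
#'
#' @param obs_diff observed (older - younger) diversity difference.
#' @param null_diffs numeric vector of null differences (length >= 2).
#' @return a one-row tibble: `z`, `null_mean`, `null_sd`, `degenerate`.
#' @export
z_score <- function(obs_diff, null_diffs) {
  if (length(null_diffs) < 2L) stop_invalid("need at least 2 null values")
  m <- mean(null_diffs)
  s <- sd(null_diffs)
  if (s == 0) {
    z <- if (obs_diff == m) 0 else sign(obs_diff - m) * Inf
    return(tibble::tibble(z = z, null_mean = m, null_sd = s, degenerate = TRUE))
  }
  tibble::tibble(z = (obs_diff - m) / s, null_mean = m, null_sd = s,
                 degenerate = FALSE)
}

#' Significance of an observed shift against its null ensemble
#'
#' `t_test` (default): the one-tailed Student-t tail probability of the
#' standardized deviate, `pt(-|z|, df = n - 1)`, in the direction of the
#' observed deviation. `rank`: the randomization p-value
#' `(count of null values as or more extreme in that direction + 1) / (n + 1)`.
#'
#' @inheritParams z_score
#' @param method `"t_test"` or `"rank"`.
#' @return a p-value in (0, 1].
#' @export
shift_significance <- function(obs_diff, null_diffs,
                               method = c("t_test", "rank")) {
  method <- match.arg(method)
  n <- length(null_diffs)
  if (n < 2L) stop_invalid("need at least 2 null values")
  if (method == "t_test") {
    zs <- z_score(obs_diff, null_diffs)
    if (zs$degenerate) return(if (zs$z == 0) 1 else 0)
    return(pt(-abs(zs$z), df = n - 1))
  }
  m <- mean(null_diffs)
  k <- if (obs_diff >= m) sum(null_diffs >= obs_diff) else sum(null_diffs <= obs_diff)
  (k + 1) / (n + 1)
}

mechanism_map <- tibble::tibble(
  pattern_sd = c("clustering", "clustering", "overdispersed", "random"),
  pattern_pd = c("clustering", "overdispersed", "overdispersed", "random"),
  mechanisms = list(
    c("environmental_filtering", "dispersal_limitation"),
    "interspecific_competition",
    "density_dependence",
    "random_process"
  )
)

#' Classify assembly mechanisms from joint SD and PD shifts
#'
#' Each metric's pattern is `clustering` when z < 0 with p <= alpha,
#' `overdispersed` when z > 0 with p <= alpha, and `random` otherwise. The
#' joint (SD, PD) pattern maps to candidate mechanisms: clustering of both
#' indicates environmental filtering or dispersal limitation; SD clustering
#' with PD overdispersion indicates interspecific competition; overdispersion
#' of both indicates density dependence; random/random indicates a random
#' process. Combinations outside this table are flagged `unclassified` and
#' reported as `random_process`.
#'
#' @param z_sd,p_sd,z_pd,p_pd standardized shifts and p-values (vectorized).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return a tibble: `pattern_sd`, `pattern_pd`, `mechanisms` (list column),
#'   `unclassified`.
#' @export
classify_assembly <- function(z_sd, p_sd, z_pd, p_pd, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop_invalid("alpha must be a single number in (0, 1)")
  }
  if (any(!is.finite(c(z_sd, z_pd))) || anyNA(c(p_sd, p_pd))) {
    stop_invalid("z and p inputs must be finite")
  }
  pat <- function(z, p) {
    dplyr::case_when(
      p <= alpha & z < 0 ~ "clustering",
      p <= alpha & z > 0 ~ "overdispersed",
      TRUE ~ "random"
    )
  }
  out <- tibble::tibble(pattern_sd = pat(z_sd, p_sd), pattern_pd = pat(z_pd, p_pd))
  key <- paste(out$pattern_sd, out$pattern_pd)
  map_key <- paste(mechanism_map$pattern_sd, mechanism_map$pattern_pd)
  hit <- match(key, map_key)
  out$mechanisms <- lapply(hit, function(h) {
    if (is.na(h)) "random_process" else mechanism_map$mechanisms[[h]]
  })
  out$unclassified <- is.na(hit)
  out
}

as_stage_list <- function(communities) {
  if (inherits(communities, "synthetic_dataset")) {
    communities <- communities$communities
  }
  if (!is.list(communities) || !all(stages %in% names(communities))) {
    stop_schema("communities must be a named list with elements ",
                paste(stages, collapse = ", "))
  }
  communities <- lapply(communities[stages], check_community)
  ref <- dimnames(communities$seedling)
  for (s in stages[-1]) {
    if (!identical(dimnames(communities[[s]]), ref)) {
      bad <- c(
        setdiff(rownames(communities[[s]]), ref[[1]]),
        setdiff(ref[[1]], rownames(communities[[s]])),
        setdiff(colnames(communities[[s]]), ref[[2]]),
        setdiff(ref[[2]], colnames(communities[[s]]))
      )
      stop_schema("stage '", s, "' labels misaligned with seedling stage: ",
                  paste(unique(bad), collapse = ", "))
    }
  }
  communities
}

#' Standardized diversity shifts for both transitions and metrics
#'
#' The workhorse of the pipeline: for each life-stage transition (SS =
#' sapling - seedling, ST = tree - sapling) and each metric (SD, PD), the
#' observed per-island diversity difference is standardized against a null
#' ensemble ([null_diff_ensemble()]) and tested for significance.
#'
#' @param communities a named list of islands x species matrices for
#'   `seedling`, `sapling` and `tree` (aligned dimnames), or a
#'   `synthetic_dataset`.
#' @param phylo an [ape::phylo] covering all species (for PD).
#' @param n_rand randomizations per ensemble (default 1000).
#' @param seed optional master seed.
#' @param method significance method, see [shift_significance()].
#' @param n_swap attempted swaps per independent-swap randomization.
#' @param metrics_used which metrics to compute (default both).
#' @return a `shift_table` tibble with one row per island x transition x
#'   metric: `island_id`, `transition`, `metric`, `d_obs_older`,
#'   `d_obs_younger`, `obs_diff`, `null_mean`, `null_sd`, `z`, `p`,
#'   `degenerate`.
#' @export
transition_table <- function(communities, phylo = NULL, n_rand = 1000,
                             seed = NULL, method = c("t_test", "rank"),
                             n_swap = 30000, metrics_used = metrics) {
  method <- match.arg(method)
  communities <- as_stage_list(communities)
  metrics_used <- match.arg(metrics_used, metrics, several.ok = TRUE)
  if ("PD" %in% metrics_used && is.null(phylo)) {
    stop_invalid("PD shifts require a phylogeny")
  }
  set_seed_if(seed)
  pairs <- tidyr::expand_grid(transition = transitions, metric = metrics_used)
  pair_seeds <- child_seeds(nrow(pairs))
  res <- purrr::pmap(
    list(pairs$transition, pairs$metric, pair_seeds),
    function(tr, me, sd_seed) {
      older <- if (tr == "SS") communities$sapling else communities$tree
      younger <- if (tr == "SS") communities$seedling else communities$sapling
      d_old <- suppressWarnings(diversity_by_island(older, me, phylo))
      d_young <- suppressWarnings(diversity_by_island(younger, me, phylo))
      ens <- null_diff_ensemble(older, younger, metric = me, phylo = phylo,
                                n_rand = n_rand, seed = sd_seed,
                                n_swap = n_swap)
      obs <- d_old - d_young
      zs <- purrr::map(seq_along(obs), function(i) {
        row <- z_score(obs[i], ens$diffs[i, ])
        row$p <- shift_significance(obs[i], ens$diffs[i, ], method)
        row
      })
      dplyr::bind_rows(zs) |>
        dplyr::mutate(
          island_id = names(obs), transition = tr, metric = me,
          d_obs_older = as.numeric(d_old), d_obs_younger = as.numeric(d_young),
          obs_diff = as.numeric(obs),
          .before = 1
        )
    }
  )
  out <- dplyr::bind_rows(res)
  out <- out[, c("island_id", "transition", "metric", "d_obs_older",
                 "d_obs_younger", "obs_diff", "null_mean", "null_sd", "z",
                 "p", "degenerate")]
  class(out) <- c("shift_table", class(out))
  out
}

#' Assembly mechanism calls for a shift table
#'
#' Pivots a [transition_table()] result to one row per island x transition
#' and applies [classify_assembly()]. Degenerate islands (null sd = 0) are
#' reported as `random` with the `degenerate` flag.
#'
#' @param shifts a `shift_table`.
#' @param alpha significance level, default 0.05.
#' @return a tibble: `island_id`, `transition`, `z_sd`, `p_sd`, `z_pd`,
#'   `p_pd`, `pattern_sd`, `pattern_pd`, `mechanisms` (list column),
#'   `unclassified`, `degenerate`.
#' @export
assembly_calls <- function(shifts, alpha = 0.05) {
  need <- c("island_id", "transition", "metric", "z", "p")
  if (!all(need %in% names(shifts))) {
    stop_schema("shifts must be a shift_table (missing columns)")
  }
  wide <- shifts |>
    dplyr::select(dplyr::all_of(c(need, "degenerate"))) |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("z", "p", "degenerate"),
                       names_glue = "{.value}_{tolower(metric)}")
  deg <- (wide$degenerate_sd %||% FALSE) | (wide$degenerate_pd %||% FALSE)
  z_sd <- ifelse(is.finite(wide$z_sd), wide$z_sd, 0)
  z_pd <- ifelse(is.finite(wide$z_pd), wide$z_pd, 0)
  cls <- classify_assembly(z_sd, wide$p_sd, z_pd, wide$p_pd, alpha = alpha)
  dplyr::bind_cols(
    wide[, c("island_id", "transition", "z_sd", "p_sd", "z_pd", "p_pd")],
    cls
  ) |>
    dplyr::mutate(degenerate = deg)
}
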