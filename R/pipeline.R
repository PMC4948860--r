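#' Read long-format life-stage communities
#'
#' Expects a CSV with header `island_id,species,life_stage,abundance`,
#' `life_stage` in `seedling`, `sapling`, `tree`. Returns three aligned
#' islands x species matrices over the union of islands and species; absent
#' combinations are 0.
#'
#' @param path CSV path, or a data frame already in that layout.
#' @return named list of three integer matrices (`seedling`, `sapling`,
#'   `tree`).
#' @export
read_communities <- function(path) {
  df <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  need <- c("island_id", "species", "life_stage", "abundance")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_schema("community table is missing column(s): ",
                paste(miss, collapse = ", "))
  }
  bad_stage <- which(!df$life_stage %in% stages)
  if (length(bad_stage)) {
    stop_schema("unknown life_stage value(s) at data row(s) ",
                paste(head(bad_stage, 5), collapse = ", "), ": ",
                paste(unique(df$life_stage[bad_stage]), collapse = ", "))
  }
  bad_ab <- which(is.na(df$abundance) | df$abundance < 0 |
                    df$abundance != round(df$abundance))
  if (length(bad_ab)) {
    stop_schema("abundance must be a non-negative integer; offending data row(s): ",
                paste(head(bad_ab, 5), collapse = ", "))
  }
  key <- paste(df$island_id, df$species, df$life_stage)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_schema("duplicate (island, species, stage) at data row(s): ",
                paste(head(dup, 5), collapse = ", "))
  }
  islands <- sort(unique(df$island_id))
  species <- sort(unique(df$species))
  out <- lapply(stages, function(st) {
    m <- matrix(0L, length(islands), length(species),
                dimnames = list(islands, species))
    d <- df[df$life_stage == st, ]
    m[cbind(match(d$island_id, islands), match(d$species, species))] <-
      as.integer(d$abundance)
    m
  })
  names(out) <- stages
  out
}

#' Write life-stage communities to long-format CSV
#'
#' Inverse of [read_communities()]; zero cells are omitted.
#'
#' @param communities named list of three matrices (or a
#'   `synthetic_dataset`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_communities <- function(communities, path) {
  communities <- as_stage_list(communities)
  long <- purrr::imap(communities, function(m, st) {
    idx <- which(m > 0, arr.ind = TRUE)
    tibble::tibble(
      island_id = rownames(m)[idx[, 1]],
      species = colnames(m)[idx[, 2]],
      life_stage = st,
      abundance = m[idx]
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$life_stage, .data$island_id, .data$species)
  readr::write_csv(long, path)
  invisible(path)
}

#' Sign counts of standardized shifts
#'
#' Per transition x metric, the number of sites with increasing (z > 0) and
#' decreasing (z < 0) standardized diversity, the style in which island
#' results are usually summarized; plus per-metric counts of sites whose SS
#' and ST shifts have opposite signs.
#'
#' @param shifts a `shift_table` (or an S3-style fixture from
#'   [ingest_supplement()]).
#' @return list with tibbles `by_transition` and `opposing`.
#' @export
sign_counts <- function(shifts) {
  by_tr <- shifts |>
    dplyr::group_by(.data$transition, .data$metric) |>
    dplyr::summarise(
      n_increase = sum(.data$z > 0),
      n_decrease = sum(.data$z < 0),
      n_zero = sum(.data$z == 0),
      .groups = "drop"
    )
  opp <- shifts |>
    dplyr::select(dplyr::all_of(c("island_id", "transition", "metric", "z"))) |>
    tidyr::pivot_wider(names_from = "transition", values_from = "z") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(n_opposing = sum(sign(.data$SS) != sign(.data$ST)),
                     .groups = "drop")
  list(by_transition = by_tr, opposing = opp)
}

#' Run the full assembly-shift analysis
#'
#' End-to-end pipeline: per-island diversities, null ensembles, standardized
#' shifts and significance for both transitions and metrics
#' ([transition_table()]), mechanism classification ([assembly_calls()]),
#' sign-count summary, stage-wise Spearman correlation between SD and PD,
#' and one regression tree per transition x metric attributing the shift to
#' island attributes (area, shape index, isolation, sampling area).
#' Reference (mainland) sites appear in the shift table but are excluded
#' from the regression trees. Fully reproducible under a fixed seed.
#'
#' @param communities named list of three stage matrices, a
#'   `synthetic_dataset`, or a path to a long-format community CSV.
#' @param phylogeny an [ape::phylo] or a Newick file path.
#' @param attributes an attribute table (see [island_attributes()]) or a CSV
#'   path; optional, but required for the regression trees.
#' @param n_rand randomizations per null ensemble.
#' @param seed master seed.
#' @param method significance method ([shift_significance()]).
#' @param alpha significance level for classification.
#' @param n_swap attempted swaps per independent-swap randomization.
#' @param tree_ctrl a [tree_control()] for the attribute trees.
#' @param include_reference_in_trees include reference sites in the trees.
#' @param out_dir if given, the report bundle is written there (TSV/JSON).
#' @return an `assembly_report`: list with `shifts`, `calls`, `sign_counts`,
#'   `spearman`, `trees`, `config`.
#' @export
run_analysis <- function(communities, phylogeny, attributes = NULL,
                         n_rand = 1000, seed = 1,
                         method = c("t_test", "rank"), alpha = 0.05,
                         n_swap = 30000, tree_ctrl = tree_control(),
                         include_reference_in_trees = FALSE,
                         out_dir = NULL) {
  method <- match.arg(method)
  t0 <- Sys.time()
  if (is.character(communities)) communities <- read_communities(communities)
  if (is.character(phylogeny)) phylogeny <- read_phylogeny(phylogeny)
  if (is.character(attributes)) {
    attributes <- readr::read_csv(attributes, show_col_types = FALSE)
  }
  if (!is.null(attributes)) attributes <- island_attributes(attributes)
  communities <- as_stage_list(communities)
  if (!is.null(attributes)) {
    miss <- setdiff(rownames(communities$seedling), attributes$island_id)
    if (length(miss)) {
      stop_schema("islands missing from attribute table: ",
                  paste(miss, collapse = ", "))
    }
  }

  shifts <- transition_table(communities, phylo = phylogeny, n_rand = n_rand,
                             seed = seed, method = method, n_swap = n_swap)
  calls <- assembly_calls(shifts, alpha = alpha)
  counts <- sign_counts(shifts)

  spearman <- purrr::map_dfr(stages, function(st) {
    sd_v <- suppressWarnings(diversity_by_island(communities[[st]], "SD"))
    pd_v <- suppressWarnings(diversity_by_island(communities[[st]], "PD", phylogeny))
    ct <- suppressWarnings(cor.test(sd_v, pd_v, method = "spearman"))
    tibble::tibble(stage = st, rho = unname(ct$estimate), p = ct$p.value)
  })

  trees <- NULL
  if (!is.null(attributes)) {
    attr_use <- if (include_reference_in_trees) {
      attributes
    } else {
      attributes[!attributes$is_reference, ]
    }
    pred_cols <- c("area_ha", "shape_index", "isolation_km", "sampling_area_ha")
    trees <- shifts |>
      dplyr::filter(.data$island_id %in% attr_use$island_id,
                    is.finite(.data$z)) |>
      dplyr::left_join(attr_use[, c("island_id", pred_cols)], by = "island_id") |>
      dplyr::group_by(.data$transition, .data$metric) |>
      dplyr::group_map(function(d, key) {
        list(transition = key$transition, metric = key$metric,
             model = fit_tree(d[, pred_cols], d$z, control = tree_ctrl))
      })
  }

  report <- structure(
    list(
      shifts = shifts, calls = calls, sign_counts = counts,
      spearman = spearman, trees = trees,
      config = list(n_rand = n_rand, seed = seed, method = method,
                    alpha = alpha, n_swap = n_swap,
                    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    ),
    class = "assembly_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.assembly_report <- function(x, ...) {
  cat("assembly_report\n")
  cat(sprintf("  %d islands, n_rand = %d, method = %s, seed = %s\n",
              length(unique(x$shifts$island_id)), x$config$n_rand,
              x$config$method, x$config$seed))
  cat("  sign counts (z > 0 / z < 0):\n")
  sc <- x$sign_counts$by_transition
  for (i in seq_len(nrow(sc))) {
    cat(sprintf("    %s %s: %d increase / %d decrease\n", sc$transition[i],
                sc$metric[i], sc$n_increase[i], sc$n_decrease[i]))
  }
  cat("  SD~PD Spearman rho by stage:",
      paste(sprintf("%s %.3f", x$spearman$stage, x$spearman$rho), collapse = ", "),
      "\n")
  if (!is.null(x$trees)) {
    for (tr in x$trees) {
      cat(sprintf("  tree %s/%s: driver %s, apparent R^2 %.3f\n",
                  tr$transition, tr$metric,
                  primary_driver(tr$model) %||% "none",
                  utils::tail(tr$model$cp_table$approx_r2, 1)))
    }
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  shifts_out <- report$shifts
  readr::write_tsv(shifts_out, file.path(out_dir, "shifts.tsv"))
  calls_out <- report$calls |>
    dplyr::mutate(mechanisms = vapply(.data$mechanisms, paste,
                                      character(1), collapse = ";"))
  readr::write_tsv(calls_out, file.path(out_dir, "assembly_calls.tsv"))
  summary_list <- list(
    sign_counts = report$sign_counts$by_transition,
    opposing_trends = report$sign_counts$opposing,
    spearman_sd_pd = report$spearman,
    config = report$config[c("n_rand", "seed", "method", "alpha", "n_swap")]
  )
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$trees)) {
    trees_json <- lapply(report$trees, function(tr) {
      c(list(transition = tr$transition, metric = tr$metric),
        tree_as_json_list(tr$model))
    })
    jsonlite::write_json(trees_json, file.path(out_dir, "trees.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cp <- purrr::map_dfr(report$trees, function(tr) {
      dplyr::mutate(tr$model$cp_table, transition = tr$transition,
                    metric = tr$metric, .before = 1)
    })
    readr::write_tsv(cp, file.path(out_dir, "cp_tables.tsv"))
  }
  log_line <- sprintf(
    "stageshift run: seed=%s n_rand=%d method=%s alpha=%g n_swap=%d elapsed_s=%.1f R=%s",
    report$config$seed, report$config$n_rand, report$config$method,
    report$config$alpha, report$config$n_swap, report$config$elapsed_s,
    as.character(getRversion())
  )
  writeLines(log_line, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Ingest a supplementary-style fixture table
#'
#' Validates user-supplied CSV exports of the study's supplementary tables
#' so they can feed the same summaries the pipeline produces.
#' * `kind = "s3"` — per-island standardized differences and island
#'   attributes: requires `island_id`, `z_sd_ss`, `z_pd_ss`, `z_sd_st`,
#'   `z_pd_st`, plus attribute columns (`area_ha`, `isolation_km`, ...).
#'   Returned both as the wide tibble and as a long `shift_table`-style
#'   tibble usable by [sign_counts()] and [fit_tree()].
#' * `kind = "s2"` — species list: requires `species`; the distinct species
#'   count is attached as an attribute.
#' * `kind = "s1"` — long-format species composition; forwarded to
#'   [read_communities()].
#'
#' @param path CSV path or data frame.
#' @param kind fixture flavor: `"s3"`, `"s2"` or `"s1"`.
#' @return see above; `s3` returns a list with `wide` and `shifts`.
#' @export
ingest_supplement <- function(path, kind = c("s3", "s2", "s1")) {
  kind <- match.arg(kind)
  if (kind == "s1") return(read_communities(path))
  df <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  if (kind == "s2") {
    if (!"species" %in% names(df)) {
      stop_schema("s2 fixture needs a `species` column")
    }
    attr(df, "n_species") <- dplyr::n_distinct(df$species)
    return(df)
  }
  need <- c("island_id", "z_sd_ss", "z_pd_ss", "z_sd_st", "z_pd_st")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_schema("s3 fixture is missing column(s): ", paste(miss, collapse = ", "))
  }
  shifts <- df |>
    dplyr::select(dplyr::all_of(need)) |>
    tidyr::pivot_longer(-"island_id", names_to = c("metric", "transition"),
                        names_pattern = "z_(sd|pd)_(ss|st)", values_to = "z") |>
    dplyr::mutate(metric = toupper(.data$metric),
                  transition = toupper(.data$transition))
  list(wide = df, shifts = shifts)
}
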