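#' Individual-pool randomization (fixed-margin null)
#'
#' Pools every individual in the matrix, shuffles the pooled list, and deals
#' the individuals back into islands so that each island keeps its observed
#' total abundance and each species keeps its observed total abundance: a
#' uniform draw from the fixed-margin (hypergeometric) distribution of
#' contingency tables. This is the null model used for species-diversity
#' shifts.
#'
#' @param comm islands x species integer abundance matrix with dimnames.
#' @param seed optional integer seed.
#' @return a matrix of the same shape and dimnames with identical row and
#'   column sums.
#' @export
individual_pool_null <- function(comm, seed = NULL) {
  comm <- check_community(comm)
  set_seed_if(seed)
  individual_pool_null_impl(comm)
}

individual_pool_null_impl <- function(comm) {
  ns <- ncol(comm)
  sp <- rep.int(seq_len(ns), colSums(comm))
  sp <- sp[sample.int(length(sp))]
  isl <- rep.int(seq_len(nrow(comm)), rowSums(comm))
  idx <- (isl - 1L) * ns + sp
  out <- matrix(tabulate(idx, nbins = nrow(comm) * ns),
                nrow = nrow(comm), byrow = TRUE,
                dimnames = dimnames(comm))
  storage.mode(out) <- "integer"
  out
}

#' Independent-swap randomization
#'
#' Randomizes the occurrence structure of a community matrix by repeated
#' 2x2 checkerboard swaps; abundance values travel with their occurrences
#' (moving within species columns), so per-species occurrence frequency,
#' per-island species richness, and per-species total abundance are all
#' preserved exactly. This is the null model used for phylogenetic-diversity
#' shifts. Matrices with no swappable checkerboard are returned unchanged
#' with a message.
#'
#' @inheritParams individual_pool_null
#' @param n_iterations number of attempted swaps (burn-in); default 30000,
#'   a common choice in the ecological null-model literature.
#' @return a randomized matrix of the same shape and dimnames.
#' @export
independent_swap <- function(comm, n_iterations = 30000, seed = NULL) {
  comm <- check_community(comm)
  n_iterations <- check_count(n_iterations, "n_iterations", min = 1L)
  set_seed_if(seed)
  out <- cpp_independent_swap(comm, n_iterations)
  dimnames(out) <- dimnames(comm)
  if (identical(out, comm) && !has_checkerboard(comm)) {
    message("matrix has no swappable 2x2 checkerboard; returned unchanged")
  }
  out
}

has_checkerboard <- function(m) {
  nr <- nrow(m)
  if (nr < 2L || ncol(m) < 2L) return(FALSE)
  for (i in seq_len(nr - 1L)) {
    for (j in (i + 1L):nr) {
      if (any(m[i, ] > 0 & m[j, ] == 0) && any(m[i, ] == 0 & m[j, ] > 0)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Null ensemble of per-island diversity differences
#'
#' For each replicate, the older and younger stage matrices are randomized
#' independently (individual-pool null for SD, independent swap for PD), the
#' per-island diversity of each randomized matrix is computed, and the
#' (older - younger) difference is stored. The ensemble supplies the null
#' mean and standard deviation that standardize the observed shift into
#' \eqn{Z_D}.
#'
#' @param older,younger islands x species matrices with identical dimnames
#'   (the older and younger life stage).
#' @param metric `"SD"` (species richness) or `"PD"` (Faith's PD).
#' @param phylo an [ape::phylo]; required when `metric = "PD"`.
#' @param n_rand number of randomizations (default 1000).
#' @param seed optional master seed; per-replicate substreams are derived
#'   from it deterministically.
#' @param n_swap attempted swaps per independent-swap randomization.
#' @return an object of class `null_ensemble`: list with `metric`, `diffs`
#'   (islands x n_rand matrix), `n_rand`.
#' @export
null_diff_ensemble <- function(older, younger, metric = c("SD", "PD"),
                               phylo = NULL, n_rand = 1000, seed = NULL,
                               n_swap = 30000) {
  metric <- match.arg(metric)
  older <- check_community(older, "older")
  younger <- check_community(younger, "younger")
  if (!identical(dimnames(older), dimnames(younger))) {
    stop_schema("older and younger stages must share island and species labels")
  }
  n_rand <- check_count(n_rand, "n_rand", min = 2L)
  if (metric == "PD" && is.null(phylo)) {
    stop_invalid("metric = \"PD\" requires a phylogeny")
  }
  set_seed_if(seed)
  rep_seeds <- child_seeds(n_rand)

  if (metric == "SD") {
    randomize <- individual_pool_null_impl
    div <- function(m) as.numeric(rowSums(m > 0))
  } else {
    phylo <- validate_phylo(phylo)
    absent <- setdiff(colnames(older), phylo$tip.label)
    if (length(absent)) {
      stop_invalid("species not in tree: ", paste(absent, collapse = ", "))
    }
    eng <- edge_tip_incidence(prune_to_species(phylo, colnames(older)))
    ord <- match(colnames(older), colnames(eng$incidence))
    randomize <- function(m) cpp_independent_swap(m, n_swap)
    div <- function(m) pd_rows(eng, m, ord)
  }

  diffs <- matrix(NA_real_, nrow(older), n_rand,
                  dimnames = list(rownames(older), NULL))
  for (r in seq_len(n_rand)) {
    set.seed(rep_seeds[r])
    diffs[, r] <- div(randomize(older)) - div(randomize(younger))
  }
  structure(list(metric = metric, diffs = diffs, n_rand = n_rand),
            class = "null_ensemble")
}

# PD for every row of an abundance matrix at once, via the edge incidence
pd_rows <- function(eng, m, ord) {
  pres <- m > 0
  pres <- pres[, order(ord), drop = FALSE] # align to incidence column order
  hits <- pres %*% t(eng$incidence) > 0   # islands x edges
  as.numeric(hits %*% eng$edge_length)
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: metric %s, %d islands x %d randomizations\n",
              x$metric, nrow(x$diffs), x$n_rand))
  invisible(x)
}
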