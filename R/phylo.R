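#' Parse a Newick string into a validated phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' diversity machinery relies on: unique non-empty tip labels and branch
#' lengths on every edge. Missing branch lengths are set to 0 with a warning
#' (megatree exports often drop internal lengths).
#'
#' @param text a Newick string.
#' @return an [ape::phylo] object.
#' @examples
#' parse_newick("((A:1,B:1):1,C:2);")
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    stop_invalid("text must be a single Newick string")
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop_schema("Newick parse failure: ", conditionMessage(e))
  )
  if (is.null(phy)) stop_schema("Newick parse failure: no tree found in string")
  validate_phylo(phy)
}

#' Read a phylogeny from a Newick file
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  validate_phylo(ape::read.tree(path))
}

#' Write a phylogeny to a Newick file
#' @param phylo an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylogeny <- function(phylo, path) {
  ape::write.tree(validate_phylo(phylo), file = path)
  invisible(path)
}

validate_phylo <- function(phy) {
  if (!inherits(phy, "phylo")) stop_invalid("not a phylo object")
  tips <- phy$tip.label
  if (any(!nzchar(tips))) stop_schema("empty tip labels are not allowed")
  if (anyDuplicated(tips)) {
    stop_schema("duplicate tip label(s): ",
                paste(unique(tips[duplicated(tips)]), collapse = ", "))
  }
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; setting all to 0", call. = FALSE)
    phy$edge.length <- rep(0, nrow(phy$edge))
  }
  if (anyNA(phy$edge.length)) {
    warning("missing branch lengths set to 0", call. = FALSE)
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  if (any(phy$edge.length < 0)) stop_schema("negative branch lengths")
  # rooted = a unique parentless node; basal polytomies (star trees) are fine
  roots <- setdiff(phy$edge[, 1], phy$edge[, 2])
  if (length(roots) != 1L) stop_schema("tree must have a single root")
  phy
}

# logical edges x tips incidence: inc[e, t] is TRUE when tip t descends
# from edge e. PD of a tip set is then sum(edge.length[inc %*% present > 0]).
edge_tip_incidence <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  node_desc <- matrix(FALSE, nnode, ntip)
  node_desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(phy$edge))) {
    parent <- phy$edge[e, 1L]
    child <- phy$edge[e, 2L]
    node_desc[parent, ] <- node_desc[parent, ] | node_desc[child, ]
  }
  inc <- node_desc[phy$edge[, 2L], , drop = FALSE]
  colnames(inc) <- phy$tip.label
  list(incidence = inc, edge_length = phy$edge.length, phylo = phy)
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree linking a set of species.
#' By default the subtree is anchored at the root (`include_root = TRUE`), so
#' the PD of a single species equals its root-to-tip distance and PD of all
#' tips equals the total tree length; this matches the common default of the
#' phylogenetic community ecology toolchain.
#'
#' @param phylo an [ape::phylo] object (rooted, branch lengths).
#' @param species character vector of tip labels present in the community.
#' @param include_root include the path connecting the set's most recent
#'   common ancestor to the root (default `TRUE`).
#' @param missing_species `"error"` (default) to fail on labels absent from
#'   the tree, `"drop"` to drop them with a warning.
#' @return a single non-negative number.
#' @examples
#' phy <- parse_newick("((A:1,B:1):1,C:2);")
#' faith_pd(phy, c("A", "B"))
#' @export
faith_pd <- function(phylo, species, include_root = TRUE,
                     missing_species = c("error", "drop")) {
  missing_species <- match.arg(missing_species)
  phylo <- validate_phylo(phylo)
  species <- unique(as.character(species))
  absent <- setdiff(species, phylo$tip.label)
  if (length(absent)) {
    if (missing_species == "error") {
      stop_invalid("species not in tree: ", paste(absent, collapse = ", "))
    }
    warning("dropping species not in tree: ", paste(absent, collapse = ", "),
            call. = FALSE)
    species <- setdiff(species, absent)
  }
  if (!length(species)) stop_invalid("species set is empty")
  eng <- edge_tip_incidence(phylo)
  present <- colnames(eng$incidence) %in% species
  pd_from_incidence(eng, present, include_root = include_root)
}

pd_from_incidence <- function(eng, present, include_root = TRUE) {
  hit <- (eng$incidence %*% present) > 0
  pd <- sum(eng$edge_length[hit])
  if (!include_root) {
    labs <- colnames(eng$incidence)[present]
    pd <- pd - root_to_mrca(eng$phylo, labs)
  }
  pd
}

root_to_mrca <- function(phy, labs) {
  depths <- ape::node.depth.edgelength(phy)
  if (length(labs) == 1L) {
    return(depths[match(labs, phy$tip.label)])
  }
  mrca <- ape::getMRCA(phy, labs)
  depths[mrca]
}

#' Prune a phylogeny to a species subset
#'
#' Drops all other tips and collapses the resulting unary internal nodes,
#' summing branch lengths, so root-to-tip distances of retained tips are
#' preserved.
#'
#' @inheritParams faith_pd
#' @return an [ape::phylo] with exactly `species` as tips.
#' @export
prune_to_species <- function(phylo, species) {
  phylo <- validate_phylo(phylo)
  species <- unique(as.character(species))
  if (!length(species)) stop_invalid("species set is empty")
  absent <- setdiff(species, phylo$tip.label)
  if (length(absent)) {
    stop_invalid("species not in tree: ", paste(absent, collapse = ", "))
  }
  if (length(species) == length(phylo$tip.label)) return(phylo)
  ape::keep.tip(phylo, species)
}

#' Blomberg's K phylogenetic signal with permutation test
#'
#' K compares the observed ratio of trait variance among tips to the variance
#' after accounting for phylogenetic covariance, against the expectation of
#' that ratio under Brownian motion on the same tree. K = 1 matches the
#' Brownian expectation; K < 1 indicates less signal than Brownian, K > 1
#' more. Significance is assessed by permuting trait values across tips and
#' recomputing K.
#'
#' @param phylo an [ape::phylo] with >= 4 tips.
#' @param traits named numeric vector covering every tip.
#' @param n_permutations number of trait permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return an object of class `phylo_signal`: list with `K`, `p_value`,
#'   `n_permutations`, and the permuted values `K_null`.
#' @references Blomberg, Garland & Ives (2003) Evolution 57:717-745.
#' @export
blomberg_k <- function(phylo, traits, n_permutations = 999, seed = NULL) {
  phylo <- validate_phylo(phylo)
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1L)
  n <- length(phylo$tip.label)
  if (n < 4L) stop_invalid("Blomberg's K needs at least 4 tips")
  if (is.null(names(traits)) || !all(phylo$tip.label %in% names(traits))) {
    stop_invalid("traits must be a named vector covering every tip label")
  }
  x <- as.numeric(traits[phylo$tip.label])
  if (anyNA(x)) stop_invalid("traits contain missing values")
  V <- ape::vcv(phylo)
  Vi <- tryCatch(solve(V), error = function(e) {
    stop_invalid("singular phylogenetic covariance matrix (duplicate ",
                 "zero-length tips?); add minimal branch lengths: ",
                 conditionMessage(e))
  })
  ones <- rep(1, n)
  denom_exp <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  k_of <- function(x) {
    ahat <- sum(Vi %*% x) / sum(Vi)
    d <- x - ahat
    mse0 <- sum(d^2) / (n - 1)
    mse <- drop(t(d) %*% Vi %*% d) / (n - 1)
    (mse0 / mse) / denom_exp
  }
  k_obs <- k_of(x)
  set_seed_if(seed)
  k_null <- vapply(seq_len(n_permutations),
                   function(i) k_of(x[sample.int(n)]), numeric(1))
  p <- (sum(k_null >= k_obs) + 1) / (n_permutations + 1)
  structure(
    list(K = k_obs, p_value = p, n_permutations = n_permutations,
         K_null = k_null, n_tips = n),
    class = "phylo_signal"
  )
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat("Blomberg's K phylogenetic signal\n")
  cat(sprintf("  K = %.4f  (n_tips = %d)\n", x$K, x$n_tips))
  cat(sprintf("  permutation p = %.4g  (%d permutations)\n",
              x$p_value, x$n_permutations))
  invisible(x)
}

#' @rdname blomberg_k
#' @param x a `phylo_signal` object.
#' @param ... unused.
#' @export
tidy.phylo_signal <- function(x, ...) {
  tibble::tibble(statistic = x$K, p.value = x$p_value,
                 n_permutations = x$n_permutations, n_tips = x$n_tips)
}

#' @rdname blomberg_k
#' @export
glance.phylo_signal <- function(x, ...) tidy.phylo_signal(x)
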