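# Independent oracles used to cross-check the implementation.

# Faith's PD by brute force: union of the edges on every root-to-tip path.
pd_oracle <- function(phy, species) {
  root <- length(phy$tip.label) + 1L
  edges <- integer(0)
  for (sp in species) {
    node <- match(sp, phy$tip.label)
    while (node != root) {
      e <- which(phy$edge[, 2] == node)
      edges <- c(edges, e)
      node <- phy$edge[e, 1]
    }
  }
  sum(phy$edge.length[unique(edges)])
}

# Exhaustive best single split: every (variable, threshold) pair, thresholds
# at midpoints of consecutive sorted unique values. Ties by column order,
# then smaller threshold (first candidate scanned wins).
best_split_oracle <- function(x, y, minbucket = 1L) {
  best <- NULL
  for (v in seq_along(x)) {
    u <- sort(unique(x[[v]]))
    if (length(u) < 2L) next
    for (thr in (u[-1] + u[-length(u)]) / 2) {
      l <- y[x[[v]] < thr]
      r <- y[x[[v]] >= thr]
      if (length(l) < minbucket || length(r) < minbucket) next
      sse <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
      if (is.null(best) || sse < best$sse - 1e-12) {
        best <- list(variable = names(x)[v], threshold = thr, sse = sse)
      }
    }
  }
  best
}

# random community matrix with at least one individual
random_community <- function(n_isl, n_sp, lambda = 1.5) {
  m <- matrix(rpois(n_isl * n_sp, lambda), n_isl, n_sp,
              dimnames = list(paste0("i", seq_len(n_isl)),
                              paste0("s", seq_len(n_sp))))
  if (sum(m) == 0) m[1, 1] <- 1L
  storage.mode(m) <- "integer"
  m
}
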