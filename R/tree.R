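#' Control parameters for regression-tree fitting
#'
#' Defaults mirror the conventions of recursive-partitioning software:
#' `minsplit = 20` (a node must hold at least this many rows to be split),
#' `minbucket = round(minsplit / 3)`, `cp = 0.01` (a split must improve R^2
#' by at least `cp`), `maxdepth = 30`. With ~30 islands these defaults
#' typically permit one or two splits.
#'
#' @param minsplit minimum node size to attempt a split.
#' @param minbucket minimum child size.
#' @param cp complexity parameter: minimum R^2 improvement per split.
#' @param maxdepth maximum node depth (root = 0).
#' @return a `tree_control` list.
#' @export
tree_control <- function(minsplit = 20, minbucket = round(minsplit / 3),
                         cp = 0.01, maxdepth = 30) {
  list(
    minsplit = check_count(minsplit, "minsplit", min = 2L),
    minbucket = check_count(minbucket, "minbucket", min = 1L),
    cp = check_number(cp, "cp", min = 0),
    maxdepth = check_count(maxdepth, "maxdepth", min = 1L)
  )
}

node_sse <- function(y) sum((y - mean(y))^2)

# best (variable, threshold) split of one node by SSE reduction.
# Ties broken by predictor column order, then by smaller threshold: the
# first strictly better candidate wins a scan in that order.
best_split <- function(x, y, minbucket) {
  n <- length(y)
  sse0 <- node_sse(y)
  best <- NULL
  for (v in seq_along(x)) {
    xv <- x[[v]]
    ord <- order(xv, method = "radix")
    xs <- xv[ord]
    ys <- y[ord]
    csum <- cumsum(ys)
    csq <- cumsum(ys^2)
    tot <- csum[n]
    totsq <- csq[n]
    # candidate cut after position k, only where the value changes
    ks <- which(diff(xs) > 0)
    ks <- ks[ks >= minbucket & (n - ks) >= minbucket]
    if (!length(ks)) next
    sse_l <- csq[ks] - csum[ks]^2 / ks
    sse_r <- (totsq - csq[ks]) - (tot - csum[ks])^2 / (n - ks)
    imp <- sse0 - (sse_l + sse_r)
    k_best <- ks[which.max(imp)]
    imp_best <- max(imp)
    if (is.null(best) || imp_best > best$improvement + 1e-12) {
      best <- list(
        variable = names(x)[v],
        threshold = (xs[k_best] + xs[k_best + 1L]) / 2,
        improvement = imp_best
      )
    }
  }
  best
}

#' Fit a regression tree by recursive binary partitioning
#'
#' Greedy CART for a continuous response: each split minimizes the summed
#' within-child sum of squared errors over every (predictor, threshold)
#' candidate, with thresholds at midpoints of consecutive sorted unique
#' values. Growth is best-first (the admissible split with the largest SSE
#' reduction anywhere in the tree is taken next) and a split is accepted
#' only when the node has `minsplit` rows, both children have `minbucket`
#' rows, the depth is below `maxdepth`, and the R^2 improvement is at least
#' `cp`. Deterministic: ties are broken by predictor column order, then by
#' the smaller threshold.
#'
#' @param data data frame of numeric predictors (one column per island
#'   attribute), or a data frame containing `response` plus predictors.
#' @param response either a numeric vector (one value per row of `data`) or
#'   the name of the response column in `data`.
#' @param control a [tree_control()].
#' @return a `shift_tree`: list with `nodes` (tibble: `id`, `parent`,
#'   `depth`, `n`, `mean`, `sse`, `split_variable`, `threshold`,
#'   `improvement`, `left`, `right`, `is_leaf`), `cp_table` (tibble:
#'   `n_splits`, `complexity`, `relative_error`, `approx_r2`), `control`,
#'   `sst`, `n`.
#' @examples
#' d <- data.frame(area = c(1:10, 101:110), iso = runif(20))
#' fit <- fit_tree(d, response = c(rep(0, 10), rep(5, 10)),
#'                 control = tree_control(minsplit = 4, minbucket = 2))
#' primary_driver(fit)
#' @export
fit_tree <- function(data, response, control = tree_control()) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop_invalid("data must be a non-empty data frame of predictors")
  }
  if (is.character(response) && length(response) == 1L) {
    if (!response %in% names(data)) {
      stop_schema("response column '", response, "' not found in data")
    }
    y <- as.numeric(data[[response]])
    x <- data[setdiff(names(data), response)]
    y_name <- response
  } else {
    y <- as.numeric(response)
    x <- data
    y_name <- "y"
  }
  if (length(y) != nrow(x)) stop_invalid("response length must match nrow(data)")
  x <- x[vapply(x, is.numeric, logical(1))]
  if (!length(x)) stop_invalid("no numeric predictor columns")
  if (anyNA(y) || anyNA(as.matrix(x))) {
    stop_invalid("missing values are not supported; complete the data upstream")
  }

  n <- length(y)
  sst <- node_sse(y)
  nodes <- tibble::tibble(
    id = 1L, parent = NA_integer_, depth = 0L, n = n, mean = mean(y),
    sse = sst, split_variable = NA_character_, threshold = NA_real_,
    improvement = NA_real_, left = NA_integer_, right = NA_integer_,
    is_leaf = TRUE
  )
  rows_of <- list(seq_len(n))
  cp_table <- tibble::tibble(n_splits = 0L, complexity = NA_real_,
                             relative_error = 1, approx_r2 = 0)

  if (sst > 0) {
    # candidate split per open leaf
    cand <- list()
    push_cand <- function(id) {
      idx <- rows_of[[id]]
      nd <- nodes[nodes$id == id, ]
      if (nd$n >= control$minsplit && nd$depth < control$maxdepth && nd$sse > 0) {
        b <- best_split(x[idx, , drop = FALSE], y[idx], control$minbucket)
        if (!is.null(b) && b$improvement >= control$cp * sst) {
          cand[[as.character(id)]] <<- c(b, list(id = id))
        }
      }
    }
    push_cand(1L)
    n_splits <- 0L
    total_sse <- sst
    while (length(cand)) {
      imps <- vapply(cand, function(cc) cc$improvement, numeric(1))
      ids <- vapply(cand, function(cc) cc$id, integer(1))
      pick <- order(-imps, ids)[1L] # deterministic: earliest node wins ties
      ch <- cand[[pick]]
      cand[[pick]] <- NULL
      idx <- rows_of[[ch$id]]
      go_left <- x[[ch$variable]][idx] < ch$threshold
      lid <- nrow(nodes) + 1L
      rid <- nrow(nodes) + 2L
      depth <- nodes$depth[nodes$id == ch$id] + 1L
      for (side in list(list(id = lid, rows = idx[go_left]),
                        list(id = rid, rows = idx[!go_left]))) {
        yy <- y[side$rows]
        nodes <- dplyr::bind_rows(nodes, tibble::tibble(
          id = side$id, parent = ch$id, depth = depth, n = length(yy),
          mean = mean(yy), sse = node_sse(yy),
          split_variable = NA_character_, threshold = NA_real_,
          improvement = NA_real_, left = NA_integer_, right = NA_integer_,
          is_leaf = TRUE
        ))
        rows_of[[side$id]] <- side$rows
      }
      i0 <- which(nodes$id == ch$id)
      nodes$split_variable[i0] <- ch$variable
      nodes$threshold[i0] <- ch$threshold
      nodes$improvement[i0] <- ch$improvement
      nodes$left[i0] <- lid
      nodes$right[i0] <- rid
      nodes$is_leaf[i0] <- FALSE
      n_splits <- n_splits + 1L
      total_sse <- total_sse - ch$improvement
      cp_table <- dplyr::bind_rows(cp_table, tibble::tibble(
        n_splits = n_splits,
        complexity = ch$improvement / sst,
        relative_error = total_sse / sst,
        approx_r2 = 1 - total_sse / sst
      ))
      push_cand(lid)
      push_cand(rid)
    }
  }

  structure(
    list(nodes = nodes, cp_table = cp_table, control = control,
         sst = sst, n = n, predictors = names(x), response = y_name),
    class = "shift_tree"
  )
}

#' Apparent R-squared sequence of a regression tree
#'
#' `1 - (summed leaf SSE) / SST` after each split, reported for
#' 0 to `n_splits` splits (the "approximate r-square" of recursive
#' partitioning reports). Non-decreasing and bounded in `[0, 1]`.
#'
#' @param model a `shift_tree`.
#' @return numeric vector of length `n_splits + 1`.
#' @export
approx_r_squared <- function(model) {
  if (!inherits(model, "shift_tree")) stop_invalid("model must be a shift_tree")
  model$cp_table$approx_r2
}

#' Primary driver of a fitted tree
#'
#' The attribute on which the root splits, or `NA` for a root-only tree.
#'
#' @param model a `shift_tree`.
#' @return a predictor name or `NA_character_`.
#' @export
primary_driver <- function(model) {
  if (!inherits(model, "shift_tree")) stop_invalid("model must be a shift_tree")
  model$nodes$split_variable[model$nodes$id == 1L]
}

#' @export
predict.shift_tree <- function(object, newdata, ...) {
  miss <- setdiff(object$predictors, names(newdata))
  if (length(miss)) stop_schema("newdata missing predictor(s): ",
                                paste(miss, collapse = ", "))
  nodes <- object$nodes
  vapply(seq_len(nrow(newdata)), function(i) {
    id <- 1L
    repeat {
      nd <- nodes[nodes$id == id, ]
      if (nd$is_leaf) return(nd$mean)
      id <- if (newdata[[nd$split_variable]][i] < nd$threshold) nd$left else nd$right
    }
  }, numeric(1))
}

#' @export
print.shift_tree <- function(x, ...) {
  r2 <- utils::tail(x$cp_table$approx_r2, 1)
  cat(sprintf("regression tree: n = %d, %d split(s), apparent R^2 = %.3f\n",
              x$n, max(x$cp_table$n_splits), r2))
  print_node <- function(id, indent) {
    nd <- x$nodes[x$nodes$id == id, ]
    pad <- strrep("  ", indent)
    if (nd$is_leaf) {
      cat(sprintf("%s* leaf: mean = %.4g (n = %d)\n", pad, nd$mean, nd$n))
    } else {
      cat(sprintf("%s%s < %.4g  (n = %d, mean = %.4g)\n", pad,
                  nd$split_variable, nd$threshold, nd$n, nd$mean))
      print_node(nd$left, indent + 1L)
      cat(sprintf("%s%s >= %.4g\n", pad, nd$split_variable, nd$threshold))
      print_node(nd$right, indent + 1L)
    }
  }
  print_node(1L, 0L)
  invisible(x)
}

#' @rdname fit_tree
#' @param x a `shift_tree`.
#' @param ... unused.
#' @export
tidy.shift_tree <- function(x, ...) x$nodes

#' @rdname fit_tree
#' @export
glance.shift_tree <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_splits = max(x$cp_table$n_splits),
    r_squared = utils::tail(x$cp_table$approx_r2, 1),
    sst = x$sst,
    primary_driver = primary_driver(x)
  )
}

# serialize a fitted tree for the report bundle
tree_as_json_list <- function(model) {
  node_list <- function(id) {
    nd <- model$nodes[model$nodes$id == id, ]
    if (nd$is_leaf) {
      list(n = nd$n, mean = nd$mean)
    } else {
      list(n = nd$n, mean = nd$mean, split_variable = nd$split_variable,
           threshold = nd$threshold, improvement = nd$improvement,
           left = node_list(nd$left), right = node_list(nd$right))
    }
  }
  list(tree = node_list(1L),
       cp_table = model$cp_table,
       approx_r2 = utils::tail(model$cp_table$approx_r2, 1),
       primary_driver = primary_driver(model))
}
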