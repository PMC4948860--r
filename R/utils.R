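# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  rlang::abort(paste0(...), class = "stageshift_invalid_argument")
}

stop_schema <- function(...) {
  rlang::abort(paste0(...), class = "stageshift_schema_error")
}

stop_geometry <- function(...) {
  rlang::abort(paste0(...), class = "stageshift_invalid_geometry")
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_invalid(name, " must be a single integer >= ", min, " (got ",
                 deparse(substitute(x)), " = ", format(x), ")")
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= min) || (!strict && x < min)) {
    stop_invalid(name, " must be a single number ",
                 if (strict) "> " else ">= ", min)
  }
  as.numeric(x)
}

# set the RNG from an optional user seed, restoring nothing: callers that
# want isolation wrap in withr::with_seed themselves
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    set.seed(check_count(seed, "seed", min = 0L))
  }
  invisible(NULL)
}

# deterministic per-task child seeds derived from the current RNG state
child_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

# rescale a numeric vector to [0, 1]; constant vectors map to 0
rank01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# validate an islands x species abundance matrix
check_community <- function(m, name = "community") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_schema(name, " must be a numeric islands x species matrix")
  }
  if (any(is.na(m))) stop_schema(name, " contains missing values")
  if (any(m < 0)) stop_schema(name, " contains negative abundances")
  if (any(m != round(m))) stop_schema(name, " abundances must be integers")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_schema(name, " must have island row names and species column names")
  }
  if (anyDuplicated(rownames(m))) stop_schema(name, " has duplicated island labels")
  if (anyDuplicated(colnames(m))) stop_schema(name, " has duplicated species labels")
  if (sum(m) == 0) stop_invalid(name, " has no individuals (all-zero matrix)")
  storage.mode(m) <- "integer"
  m
}

stages <- c("seedling", "sapling", "tree")
transitions <- c("SS", "ST")
metrics <- c("SD", "PD")
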