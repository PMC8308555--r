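# internal validation + seed plumbing

assert_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    all(if (open_left) x > 0 else x >= 0) &&
    all(if (open_right) x < 1 else x <= 1)
  if (!ok) {
    abort(sprintf(
      "`%s` must be %s finite probabilit%s in %s0, 1%s",
      name, if (length(x) > 1) "a vector of" else "a",
      if (length(x) > 1) "ies" else "y",
      if (open_left) "(" else "[", if (open_right) ")" else "]"
    ), class = "hcymr_validation_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "hcymr_validation_error")
  }
  invisible(as.integer(x))
}

assert_cols <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  name, paste(missing, collapse = ", ")),
          class = "hcymr_validation_error")
  }
  invisible(df)
}

# Stage offsets for deterministic child seeds derived from one master seed.
# child = (master * 2654435761 + offset * 40503) mod (2^31 - 1), kept >= 1.
# Each pipeline stage draws from its own stream so stages can be re-run in
# isolation without disturbing one another.
.seed_stages <- c(
  genotypes = 1L, phenotypes = 2L, cohort_two = 3L, cohort_three = 4L,
  bootstrap = 5L, median_boot = 6L, pipeline = 7L
)

#' Derive a deterministic child seed for a named stage
#'
#' One master seed drives the whole pipeline; each stochastic stage uses a
#' child seed derived by modular hashing so that re-running a single stage
#' reproduces its draws exactly.
#'
#' @param seed Master integer seed.
#' @param stage Stage name (`"genotypes"`, `"phenotypes"`, `"cohort_two"`,
#'   `"cohort_three"`, `"bootstrap"`, `"median_boot"`, `"pipeline"`) or any
#'   integer offset.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  seed <- assert_count(seed, "seed", min = 0L)
  off <- if (is.character(stage)) {
    if (!stage %in% names(.seed_stages)) {
      abort(sprintf("unknown seed stage '%s'", stage),
            class = "hcymr_validation_error")
    }
    .seed_stages[[stage]]
  } else {
    assert_count(stage, "stage", min = 0L)
  }
  m <- 2147483647
  child <- (as.numeric(seed) %% m * 2654435761 + as.numeric(off) * 40503) %% m
  as.integer(max(1, child))
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- rlang::`%||%`
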