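#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd quantile setNames lm
#'   nlminb wilcox.test kmeans predict var
#' @importFrom utils write.csv read.csv head tail packageVersion
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All randomized entry points funnel
# through this so that a seed argument never clobbers user RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logistic <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stopf("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stopf("`%s` must be a single non-negative number", name)
  as.numeric(x)
}
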