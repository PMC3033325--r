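#' @importFrom rlang abort warn inform .data
#' @importFrom dplyr %>%
#' @importFrom stats quantile rgamma runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Deterministic sub-seed derivation: one master seed drives every stochastic
# component (window, AHC step, cluster, EM restart); each gets its own stream.
# Polynomial hash mod a prime below 2^31 so the result is a valid R seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483629
  h <- as.double(seed %% m)
  for (k in idx) {
    h <- (h * 48271 + as.double(k) + 1) %% m
  }
  as.integer(h)
}

# Run expr with a local RNG state seeded from `seed`, restoring the caller's
# state afterwards (so package internals never disturb the user's RNG).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# symmetric Dirichlet(1) draw (normalized Exp(1) gammas)
rdirichlet1 <- function(k) {
  g <- rgamma(k, shape = 1)
  g / sum(g)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) && x >= min
}

# per-column mode of a non-negative integer vector (ties -> smallest value)
int_mode <- function(x) {
  x <- x[x >= 0L]
  tab <- tabulate(x + 1L)
  which.max(tab) - 1L
}
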