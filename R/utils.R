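#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so every
#' generator is a pure function of (parameters, seed).
#'
#' @param seed integer seed.
#' @param expr expression.
#' @return value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log-normal sdlog for a given coefficient of variation
cvToSdlog <- function(cv) sqrt(log(1 + cv^2))

# multiplicative log-normal noise with unit mean and the given CV
lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- cvToSdlog(cv)
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# attach per-filter drop counts to a result and log them
withDropCounts <- function(x, counts) {
  attr(x, "dropCounts") <- counts
  if (length(counts))
    message(paste(names(counts), counts, sep = "=", collapse = ", "))
  x
}

#' Per-filter drop counts of a filtering operation
#'
#' @param x result of a filtering operation.
#' @return named integer vector of records dropped by each filter.
#' @export
dropCounts <- function(x) attr(x, "dropCounts")
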