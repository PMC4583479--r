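#' Evaluate code with a temporary RNG state
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so that seeded operations do not perturb the global
#' random number stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with any number of integer indices (setting index,
#' replicate index, stage tag, ...) into a deterministic child seed below
#' 2^31, so every replicate of a grid has an independent, re-derivable seed.
#'
#' @param master Integer master seed.
#' @param ... Further integers identifying the stream.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  parts <- c(as.numeric(master), vapply(list(...), as.numeric, numeric(1)))
  h <- 0
  for (p in parts) {
    # 32-bit mixing done in double precision; 2147483647 is prime (Mersenne)
    h <- (h * 69069 + p * 40503 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

#' @keywords internal
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (!is.finite(s) || s <= 0) {
    g <- rep(0, length(alpha))
    g[which.max(alpha)] <- 1
    s <- 1
  }
  g / s
}

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Nearest-rank quantile
#'
#' The nearest-rank convention: the p-th centile of n sorted values is the
#' `ceiling(p * n)`-th order statistic.
#'
#' @param x Numeric vector.
#' @param p Probability in (0, 1].
#' @return A single value of `x`.
#' @export
nearest_rank_quantile <- function(x, p) {
  stopifnot(length(x) >= 1, p > 0, p <= 1)
  sort(x)[ceiling(p * length(x))]
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# data.table syntax is used inside this package
.datatable.aware <- TRUE
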