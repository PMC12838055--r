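#' @useDynLib semanchor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd quantile rnorm runif optim varimax promax cancor
#'   cov qnorm aggregate setNames dist median complete.cases
#' @importFrom utils head read.csv write.csv
NULL

# Derive a child seed from a master seed by counter. Keeps every bootstrap
# replicate reproducible independent of execution order (replicate b always
# uses the same seed, even if earlier replicates are skipped or parallelised).
derive_seed <- function(master, counter) {
  master <- as.numeric(master) %% 2147483647
  s <- (master * 48271 + counter * 30269 + 11) %% 2147483647
  as.integer(s)
}

# Evaluate expr under a local RNG state; the caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

# Deterministic 31-bit string hash (polynomial rolling hash over UTF-8 bytes).
# Used to embed out-of-vocabulary strings reproducibly across sessions.
string_hash <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero-norm vector: cosine undefined")
  v / nv
}

# Rows of `m` rescaled to unit Euclidean norm.
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) stop("zero-norm embedding vector: cosine undefined")
  m / n
}

cosine <- function(a, b) sum(unit(a) * unit(b))

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' 1 means identical partitions (up to label names), 0 is the expected
#' agreement of independent random partitions.
#'
#' @param a,b label vectors of equal length.
#' @return Adjusted Rand index in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
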