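`%||%` <- function(a, b) if (is.null(a)) b else a

#' Boltzmann constant in kcal/(mol K)
#' @export
k_boltzmann <- function() 0.0019872041

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(A) {
  m <- A[, 1]
  for (k in seq_len(ncol(A))[-1]) m <- pmax(m, A[, k])
  m + log(rowSums(exp(A - m)))
}

#' Derive a child seed from a master seed and a stream index
#'
#' All stochastic stages draw from streams derived deterministically from one
#' master seed, so a whole study is reproducible from a single integer.
#' Derived seeds stay below 2^31.
#'
#' @param seed master seed (integer-valued)
#' @param stream stream index (integer-valued, >= 0)
#' @return an integer-valued double usable as a seed
#' @export
derive_seed <- function(seed, stream) {
  (abs(seed) * 48271 + 62089911 * (stream + 1)) %% 2147483647
}

# evaluate expr with a local R RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# trapezoidal integral of y(x) on the sorted grid x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# djb2-style rolling hash over a serialized R object; stamps outputs with
# their configuration (not cryptographic, just a provenance fingerprint)
object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
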