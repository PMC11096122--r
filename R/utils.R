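# Internal numeric helpers shared across modules.

# log(sum(exp(x))) without overflow
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logSumExp of a matrix
rowLogSumExp <- function(x) {
  m <- apply(x, 1L, max)
  ok <- is.finite(m)
  out <- m
  out[ok] <- m[ok] + log(rowSums(exp(x[ok, , drop = FALSE] - m[ok])))
  out
}

# clip probabilities away from {0, 1} for stable log-likelihoods
clipProb <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# smallest modal value of an integer vector (tie -> smallest state)
modalState <- function(x) {
  tab <- table(x)
  min(as.integer(names(tab)[tab == max(tab)]))
}

# derive a substream seed (< 2^31) from a master seed and a stream label
deriveSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 69069 + h * 101 + 1) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
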