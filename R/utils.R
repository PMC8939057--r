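# numerically stable log(sum(exp(x))) by rows of a matrix
row_logsumexp <- function(M) {
  rmax <- M[, 1]
  if (ncol(M) > 1)
    for (j in 2:ncol(M)) rmax <- pmax(rmax, M[, j])
  out <- rmax + log(rowSums(exp(M - rmax)))
  out[!is.finite(rmax)] <- -Inf
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# round half away from zero (printed tables use this convention)
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Wilson-Hilferty cube-root normalization of a chi-square-like sum
wilson_hilferty <- function(y, df) {
  ((y / df)^(1 / 3) - (1 - 2 / (9 * df))) / sqrt(2 / (9 * df))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
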