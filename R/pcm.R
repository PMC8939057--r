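#' Partial credit model category probabilities
#'
#' Evaluates the category response probabilities of a polytomous Rasch
#' (partial credit) item at one or more person locations. For an item with
#' maximum score m and uncentered thresholds beta_1 < ... < beta_m, the
#' probability of scoring x is proportional to
#' exp(sum_{k <= x} (theta - beta_k)), with the empty sum for x = 0 equal to
#' zero. The thresholds are the points on the latent continuum where adjacent
#' categories are equally likely.
#'
#' @param theta numeric vector of person locations (logits).
#' @param beta numeric vector of the item's m uncentered thresholds (logits).
#' @return a matrix with \code{length(theta)} rows and m + 1 columns; each
#'   row is a probability vector over scores 0..m.
#' @export
pcm_probs <- function(theta, beta) {
  if (any(!is.finite(theta))) stop("theta must be finite")
  if (any(!is.finite(beta))) stop("thresholds must be finite")
  m <- length(beta)
  x <- 0:m
  # log psi_x = x * theta - sum_{k<=x} beta_k
  csb <- c(0, cumsum(beta))
  lp <- outer(theta, x) - matrix(csb, length(theta), m + 1, byrow = TRUE)
  lp <- lp - row_logsumexp(lp)
  exp(lp)
}

#' Expected score and score variance under the partial credit model
#'
#' First two moments of the category distribution of one item at the given
#' person locations; these feed every residual-based fit statistic.
#'
#' @inheritParams pcm_probs
#' @return a list with numeric vectors \code{E} (expected score, in
#'   \code{[0, m]}) and \code{W} (score variance).
#' @export
pcm_moments <- function(theta, beta) {
  p <- pcm_probs(theta, beta)
  x <- 0:length(beta)
  E <- drop(p %*% x)
  W <- drop(p %*% x^2) - E^2
  list(E = E, W = pmax(W, 0))
}

# log "epsilon" weights of one item: log eps_x = -sum_{k<=x} beta_k, x = 0..m
log_eps <- function(beta) c(0, -cumsum(beta))

# log elementary symmetric functions (polytomous summation algorithm):
# given the list of per-item log-eps vectors, returns log gamma_r for
# r = 0..sum(m_i), where gamma_r sums prod_i eps_{i, x_i} over all response
# patterns with total r. Carried in log space to avoid overflow.
log_esf <- function(le_list) {
  lg <- 0
  for (le in le_list) {
    m <- length(le) - 1L
    n_old <- length(lg)
    M <- matrix(-Inf, n_old + m, m + 1L)
    for (x in 0:m) M[(x + 1L):(x + n_old), x + 1L] <- lg + le[x + 1L]
    lg <- row_logsumexp(M)
  }
  lg
}

#' Conditional probability of a response pattern given its total score
#'
#' Under the partial credit model the total score is sufficient for the
#' person parameter, so the probability of a response pattern conditional on
#' its total does not involve theta. It equals the product of the pattern's
#' item-category weights divided by the corresponding elementary symmetric
#' function of the item parameters. These conditional probabilities are the
#' building blocks of conditional maximum likelihood estimation.
#'
#' @param fit a \code{\link{fit_pcm}} object, or a list of per-item
#'   uncentered threshold vectors.
#' @param pattern integer vector of scores, one per item.
#' @return the conditional probability (a number in \code{[0, 1]}).
#' @export
conditional_pattern_prob <- function(fit, pattern) {
  beta <- if (inherits(fit, "pcm_fit")) fit$beta else fit
  if (length(pattern) != length(beta))
    stop("pattern length must equal the number of items")
  m <- vapply(beta, length, 1L)
  if (any(pattern != round(pattern)) || any(pattern < 0) || any(pattern > m))
    stop("invalid pattern: scores must be integers in 0..m_i")
  le <- lapply(beta, log_eps)
  lg <- log_esf(le)
  r <- sum(pattern)
  lnum <- sum(vapply(seq_along(beta), function(i) le[[i]][pattern[i] + 1L], 0))
  exp(lnum - lg[r + 1L])
}
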