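#' Score-to-theta lookup table for a fitted instrument
#'
#' Under the partial credit model the raw total score is sufficient for the
#' person location, so person measurement reduces to one maximum-likelihood
#' estimate per possible total. For interior totals, theta solves
#' sum_i E_i(theta) = total; the standard error is 1/sqrt(test information).
#' Extreme totals (0 and the maximum) have no finite ML estimate; they are
#' adjusted inward by \code{extreme_adjust} score units before solving,
#' which yields finite, strictly ordered endpoint estimates suitable for
#' anchoring ordinal-to-interval conversion.
#'
#' @param fit a \code{\link{fit_pcm}} object.
#' @param extreme_adjust inward adjustment (score units) applied to the two
#'   extreme totals; default 0.3.
#' @return data frame with columns \code{total}, \code{theta}, \code{se},
#'   \code{extreme}.
#' @export
score_to_theta <- function(fit, extreme_adjust = 0.3) {
  stopifnot(inherits(fit, "pcm_fit"))
  if (extreme_adjust <= 0 || extreme_adjust >= 1)
    stop("extreme_adjust must be in (0, 1)")
  R <- sum(fit$max_score)
  expected_total <- function(theta)
    sum(vapply(fit$beta, function(b) pcm_moments(theta, b)$E, 0))
  info_total <- function(theta)
    sum(vapply(fit$beta, function(b) pcm_moments(theta, b)$W, 0))
  out <- data.frame(total = 0:R, theta = NA_real_, se = NA_real_,
                    extreme = c(TRUE, rep(FALSE, max(R - 1L, 0L)), TRUE))
  for (r in 0:R) {
    r_eff <- if (r == 0) extreme_adjust else if (r == R) R - extreme_adjust else r
    root <- stats::uniroot(function(th) expected_total(th) - r_eff,
                           lower = -30, upper = 30, extendInt = "upX",
                           tol = 1e-10)
    th <- root$root
    out$theta[r + 1L] <- th
    out$se[r + 1L] <- 1 / sqrt(info_total(th))
  }
  out
}

#' Person location estimates
#'
#' Maps every person's raw total to its maximum-likelihood location on the
#' logit scale (see \code{\link{score_to_theta}}). Persons with equal totals
#' receive identical estimates (sufficiency); persons at the minimum or
#' maximum possible total are flagged extreme and carry the adjusted
#' endpoint estimates.
#'
#' @param resp a \code{\link{response_matrix}} scored on the same items as
#'   \code{fit}.
#' @param fit a \code{\link{fit_pcm}} object.
#' @param extreme_adjust see \code{\link{score_to_theta}}.
#' @return object of class \code{person_estimates}: list with \code{theta},
#'   \code{se}, \code{total}, \code{extreme} (per person) and \code{lookup}
#'   (the score-to-theta table).
#' @export
person_estimates <- function(resp, fit, extreme_adjust = 0.3) {
  stopifnot(inherits(resp, "response_matrix"), inherits(fit, "pcm_fit"))
  if (!identical(resp$item_ids, fit$item_ids))
    stop("response matrix and fit cover different items")
  lookup <- score_to_theta(fit, extreme_adjust)
  totals <- rowSums(resp$scores)
  structure(list(
    theta = lookup$theta[totals + 1L],
    se = lookup$se[totals + 1L],
    total = totals,
    extreme = lookup$extreme[totals + 1L],
    lookup = lookup),
    class = "person_estimates")
}

#' @export
print.person_estimates <- function(x, ...) {
  cat("Person estimates:", length(x$theta), "persons,",
      sum(x$extreme), "extreme\n")
  cat(sprintf("mean theta %.3f (SD %.3f)\n", mean(x$theta), stats::sd(x$theta)))
  invisible(x)
}
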