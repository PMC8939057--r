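#' Linear logit-to-metric rescaling
#'
#' Maps person logits onto the instrument's 1-5 range through fixed anchors:
#' M = 1 + 4 (theta - theta_min) / (theta_max - theta_min). The anchors are
#' the (extrapolated) endpoint person estimates of the analyzed instrument,
#' so the mapping is endpoint-exact: M(theta_min) = 1 and M(theta_max) = 5.
#' Values outside the anchor range are clamped with a warning.
#'
#' @param theta numeric vector of person logits.
#' @param theta_min,theta_max anchor logits (theta_min < theta_max).
#' @return numeric vector of metric scores in [1, 5].
#' @export
metric_from_logit <- function(theta, theta_min, theta_max) {
  if (!is.finite(theta_min) || !is.finite(theta_max) || theta_max <= theta_min)
    stop("degenerate anchors: need theta_min < theta_max")
  out_of_range <- theta < theta_min | theta > theta_max
  if (any(out_of_range)) {
    warning(sum(out_of_range), " value(s) outside the anchor range clamped")
    theta <- pmin(pmax(theta, theta_min), theta_max)
  }
  1 + 4 * (theta - theta_min) / (theta_max - theta_min)
}

#' Ordinal-to-interval conversion table
#'
#' Builds the raw-mean to interval-metric conversion grid for a fitted
#' instrument. Every possible raw total r (0..R, R the maximum total) maps
#' to a raw mean score on the original 1-5 rating scale,
#' 1 + 4 r / R (step 1/I for I items with m = 4), to the person logit of
#' that total, and to the linear 1-5 interval metric anchored at the
#' extrapolated endpoint logits. Serialized output is rounded to 2 decimals
#' (half away from zero); full precision is retained in the returned object.
#'
#' @param fit a \code{\link{fit_pcm}} of the final instrument (items or
#'   testlets).
#' @param extreme_adjust inward score adjustment for the endpoint estimates.
#' @return object of class \code{conversion_table}: data frame with columns
#'   \code{total}, \code{raw_mean}, \code{logit}, \code{metric}, plus
#'   attributes \code{theta_min}, \code{theta_max}, \code{n_items}.
#' @export
conversion_table <- function(fit, extreme_adjust = 0.3) {
  stopifnot(inherits(fit, "pcm_fit"))
  lookup <- score_to_theta(fit, extreme_adjust)
  R <- sum(fit$max_score)
  theta_min <- lookup$theta[1]
  theta_max <- lookup$theta[R + 1]
  if (theta_max <= theta_min) stop("degenerate anchors from the score table")
  out <- data.frame(total = lookup$total,
                    raw_mean = 1 + 4 * lookup$total / R,
                    logit = lookup$theta,
                    metric = metric_from_logit(lookup$theta, theta_min, theta_max))
  attr(out, "theta_min") <- theta_min
  attr(out, "theta_max") <- theta_max
  attr(out, "n_items") <- length(fit$item_ids)
  class(out) <- c("conversion_table", "data.frame")
  out
}

#' Convert raw mean scores to interval metric scores
#'
#' Translates per-person raw mean scores (on the 1-5 rating scale) into
#' interval metric scores through a \code{\link{conversion_table}}. Valid
#' only for complete response vectors: a raw mean is accepted only when it
#' sits on the table's grid (within 1e-9); anything off-grid -- as produced
#' by incomplete answers -- is an error.
#'
#' @param raw_means numeric vector of raw mean scores.
#' @param table a \code{\link{conversion_table}}.
#' @return numeric vector of metric scores.
#' @export
apply_conversion <- function(raw_means, table) {
  stopifnot(inherits(table, "conversion_table"))
  if (any(!is.finite(raw_means)))
    stop("raw means contain missing values; conversion is valid for ",
         "complete answers only")
  idx <- vapply(seq_along(raw_means), function(v) {
    d <- abs(table$raw_mean - raw_means[v])
    j <- which.min(d)
    if (d[j] > 1e-9)
      stop("raw mean ", raw_means[v], " for person ", v,
           " is not on the conversion grid (incomplete answers?)")
    j
  }, 1L)
  table$metric[idx]
}
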