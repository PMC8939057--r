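#' Form subscale testlets
#'
#' Combines locally dependent items into subscale super-items (testlets): the
#' testlet score is the sum of its members' scores, so dependency within a
#' subscale is absorbed into the testlet's category structure and the data
#' can be re-analyzed as a short polytomous instrument. Categories of the
#' summed score that never occur are collapsed to consecutive ranks (logged
#' in the \code{collapse_log} attribute) so the testlets remain estimable,
#' or cause an error when \code{collapse = "error"}.
#'
#' @param resp a \code{\link{response_matrix}} with a subscale map.
#' @param collapse "auto" (default) or "error".
#' @return a \code{\link{response_matrix}} with one column per subscale and
#'   attributes \code{members} (list of member items) and
#'   \code{collapse_log}.
#' @export
form_testlets <- function(resp, collapse = c("auto", "error")) {
  stopifnot(inherits(resp, "response_matrix"))
  collapse <- match.arg(collapse)
  if (is.null(resp$subscale_map)) stop("a subscale map is required")
  subscales <- unique(resp$subscale_map)
  members <- lapply(subscales, function(s)
    resp$item_ids[resp$subscale_map == s])
  names(members) <- subscales
  scores <- vapply(members, function(it)
    as.integer(rowSums(resp$scores[, it, drop = FALSE])), integer(nrow(resp$scores)))
  max_score <- vapply(members, function(it) sum(resp$max_score[it]), 0L)
  out <- response_matrix(scores,
                         subscale_map = stats::setNames(subscales, subscales),
                         person_factors = resp$person_factors,
                         item_ids = subscales, max_score = max_score)
  log <- character(0)
  has_null <- tryCatch({ check_null_categories(out); FALSE },
                       error = function(e) TRUE)
  if (has_null) {
    if (collapse == "error")
      stop("null testlet categories after formation; rerun with collapse = \"auto\"")
    cl <- collapse_null_categories(out)
    out <- cl$resp
    log <- cl$log
    for (msg in log) message("form_testlets: ", msg)
  }
  attr(out, "members") <- members
  attr(out, "collapse_log") <- log
  out
}

#' Latent structure of the subscales
#'
#' Analyzes every subscale as its own short Rasch instrument: each person is
#' measured on each subscale, subscale reliability is the person separation
#' index of that fit, and the observed correlations between the subscale
#' person estimates are disattenuated by the reliabilities to give latent
#' correlations. The summary is how much non-error variance a single common
#' dimension accounts for when the subscales are combined into one score
#' (explained common variance, ECV). With true subscale variances
#' t_k = rho_k Var(theta_k), ECV = cbar (sum_k sqrt(t_k))^2 /
#' (sum_k t_k + sum_{k != l} r_kl sqrt(t_k t_l)), which is 1 when all
#' disattenuated correlations are 1 and tends to 0 under independence.
#'
#' @param resp item-level \code{\link{response_matrix}} with a subscale map
#'   (at least two subscales of at least two items each).
#' @param extreme_adjust passed to per-subscale person estimation.
#' @return object of class \code{latent_structure}: list with
#'   \code{theta} (persons x subscales), \code{reliability},
#'   \code{observed_correlations}, \code{latent_correlations} (capped at 1),
#'   \code{average_latent_correlation}, \code{ecv}.
#' @export
latent_structure <- function(resp, extreme_adjust = 0.3) {
  stopifnot(inherits(resp, "response_matrix"))
  if (is.null(resp$subscale_map)) stop("a subscale map is required")
  subscales <- unique(resp$subscale_map)
  K <- length(subscales)
  if (K < 2) stop("need at least 2 testlets")
  n <- nrow(resp$scores)
  theta <- matrix(NA_real_, n, K, dimnames = list(NULL, subscales))
  rho <- numeric(K)
  for (k in seq_len(K)) {
    members <- resp$item_ids[resp$subscale_map == subscales[k]]
    if (length(members) < 2)
      stop("subscale ", subscales[k], " has fewer than 2 items")
    sub <- subset_items(resp, members)
    pe <- person_estimates(sub, fit_pcm(sub), extreme_adjust)
    theta[, k] <- pe$theta
    rho[k] <- person_separation_index(pe)$raw
  }
  names(rho) <- subscales
  if (any(rho <= 0))
    stop("non-positive subscale reliability for: ",
         paste(subscales[rho <= 0], collapse = ", "))
  obs <- stats::cor(theta)
  lat <- obs / sqrt(outer(rho, rho))
  lat <- pmin(lat, 1)
  diag(lat) <- 1
  cbar <- mean(lat[upper.tri(lat)])
  t_k <- rho * apply(theta, 2, stats::var)
  s <- sqrt(t_k)
  # diagonal of outer(s, s) * lat contributes the t_k terms themselves
  total <- sum(outer(s, s) * lat)
  common <- cbar * sum(s)^2
  ecv <- min(max(common / total, 0), 1)
  structure(list(theta = theta, reliability = rho,
                 observed_correlations = obs, latent_correlations = lat,
                 average_latent_correlation = cbar, ecv = ecv),
            class = "latent_structure")
}

#' @export
print.latent_structure <- function(x, ...) {
  cat("Latent structure of", length(x$reliability), "subscales\n")
  cat("Reliabilities:", paste(sprintf("%s %.2f", names(x$reliability),
                                      x$reliability), collapse = ", "), "\n")
  cat(sprintf("Average latent correlation %.2f; explained common variance %.0f%%\n",
              x$average_latent_correlation, 100 * x$ecv))
  invisible(x)
}
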