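#' Standardized response residuals
#'
#' z_vi = (x_vi - E_vi) / sqrt(W_vi), with the expectation and variance of
#' the partial credit category distribution evaluated at each person's
#' estimated location. Persons with extreme totals carry no information
#' about fit and are excluded; the retained person indices are kept as the
#' \code{persons} attribute.
#'
#' @param resp a \code{\link{response_matrix}}.
#' @param fit a \code{\link{fit_pcm}} object.
#' @param persons a \code{\link{person_estimates}} object.
#' @return numeric matrix (non-extreme persons x items) of standardized
#'   residuals with attribute \code{persons} (row indices into \code{resp}).
#' @export
standardized_residuals <- function(resp, fit, persons) {
  stopifnot(inherits(resp, "response_matrix"), inherits(fit, "pcm_fit"),
            inherits(persons, "person_estimates"))
  keep <- which(!persons$extreme)
  theta <- persons$theta[keep]
  z <- matrix(NA_real_, length(keep), length(fit$item_ids),
              dimnames = list(NULL, fit$item_ids))
  for (i in seq_along(fit$item_ids)) {
    mom <- pcm_moments(theta, fit$beta[[i]])
    if (any(mom$W <= 0)) {
      v <- keep[which(mom$W <= 0)[1]]
      stop("zero response variance for person ", v, ", item ",
           fit$item_ids[i], "; cannot standardize")
    }
    z[, i] <- (resp$scores[keep, i] - mom$E) / sqrt(mom$W)
  }
  attr(z, "persons") <- keep
  z
}

#' Item and person fit residuals
#'
#' Summarizes each item's (or person's) squared standardized residuals into
#' an approximately standard-normal fit residual via the Wilson-Hilferty
#' cube-root normalization of the chi-square-like sum. Under a well-fitting
#' model these residuals have mean near 0 and SD near 1, and values are
#' screened against +/- 2.5. Negative values indicate overfit (redundancy,
#' Guttman-like over-discrimination); positive values indicate misfit
#' (under-discrimination).
#'
#' @param z standardized residual matrix from
#'   \code{\link{standardized_residuals}}.
#' The degrees of freedom account for person estimation: each estimated
#' person location absorbs one degree of freedom spread across the items,
#' giving df = n (I - 1) / I per item and df = I - 1 per person, which
#' centers the null distribution near zero.
#'
#' @return named numeric vector, one fit residual per item (or per person).
#' @export
item_fit_residuals <- function(z) {
  df <- nrow(z) * (ncol(z) - 1) / ncol(z)
  stats::setNames(wilson_hilferty(colSums(z^2), df), colnames(z))
}

#' @rdname item_fit_residuals
#' @export
person_fit_residuals <- function(z) {
  df <- ncol(z) - 1
  wilson_hilferty(rowSums(z^2), df)
}

# equal-count class intervals on the theta ranking; ties broken by stable
# person order. Returns an integer group vector of length nrow(z).
class_intervals <- function(theta, G) {
  n <- length(theta)
  if (G < 2) stop("need at least 2 class intervals")
  ord <- order(theta)                      # stable for ties
  bounds <- floor(seq(0, n, length.out = G + 1))
  sizes <- diff(bounds)
  if (any(sizes == 0)) stop("empty class interval: too many intervals for n")
  g <- integer(n)
  g[ord] <- rep(seq_len(G), sizes)
  g
}

default_G <- function(n) max(2L, min(10L, floor(n / 50)))

#' Item-trait interaction chi-square
#'
#' Ranks the (non-extreme) persons by estimated location, partitions them
#' into G equal-count class intervals, and compares observed and expected
#' class-interval score sums per item:
#' chi2_i = sum_g (sum_{v in g} (x_vi - E_vi))^2 / sum_{v in g} W_vi with
#' G - 1 degrees of freedom. The total statistic sums over items. Per-item
#' p-values are Bonferroni-adjusted within the item family at the given
#' alpha.
#'
#' @inheritParams standardized_residuals
#' @param G number of class intervals; default
#'   \code{min(10, floor(n/50))} bounded below by 2.
#' @param alpha family significance level (default 0.01).
#' @return list with per-item data frame \code{items} (chisq, df, p, p_adj,
#'   significant), \code{total} (chisq, df, p), \code{G}, and the class
#'   interval assignment \code{intervals}.
#' @export
item_trait_chisq <- function(resp, fit, persons, G = NULL, alpha = 0.01) {
  z_keep <- which(!persons$extreme)
  n <- length(z_keep)
  if (is.null(G)) G <- default_G(n)
  g <- class_intervals(persons$theta[z_keep], G)
  theta <- persons$theta[z_keep]
  I <- length(fit$item_ids)
  chisq <- numeric(I)
  for (i in seq_len(I)) {
    mom <- pcm_moments(theta, fit$beta[[i]])
    resid <- resp$scores[z_keep, i] - mom$E
    num <- tapply(resid, g, sum)^2
    den <- tapply(mom$W, g, sum)
    chisq[i] <- sum(num / den)
  }
  df <- G - 1
  p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  p_adj <- pmin(1, p * I)
  items <- data.frame(item = fit$item_ids, chisq = chisq, df = df, p = p,
                      p_adj = p_adj, significant = p_adj < alpha,
                      row.names = NULL)
  total_chisq <- sum(chisq)
  total_df <- I * df
  list(items = items,
       total = list(chisq = total_chisq, df = total_df,
                    p = stats::pchisq(total_chisq, total_df, lower.tail = FALSE)),
       G = G, intervals = g)
}

#' Person separation index
#'
#' Rasch reliability index: the proportion of observed person-estimate
#' variance attributable to true variance,
#' PSI = (Var(theta) - mean(SE^2)) / Var(theta), computed over non-extreme
#' persons. Interpreted like Cronbach's alpha. Raw values below zero are
#' floored to 0 in the reported value; the raw value is retained.
#'
#' @param persons a \code{\link{person_estimates}} object.
#' @return list with \code{psi} (floored) and \code{raw}.
#' @export
person_separation_index <- function(persons) {
  keep <- !persons$extreme
  if (sum(keep) < 2) stop("need at least 2 non-extreme persons")
  v <- stats::var(persons$theta[keep])
  raw <- (v - mean(persons$se[keep]^2)) / v
  list(psi = max(raw, 0), raw = raw)
}

#' Residual correlations and local dependency screening
#'
#' Pearson correlations between the items' standardized residual columns.
#' Any pair correlating more than 0.2 above the average off-diagonal
#' residual correlation is flagged as locally dependent (response
#' dependency). Under unidimensionality the average off-diagonal correlation
#' is close to -1/(k-1) for k items, so the critical value is close to
#' 0.2 - 1/(k-1).
#'
#' @param z standardized residual matrix.
#' @return object of class \code{residual_correlations}: list with
#'   \code{matrix}, \code{average} (mean off-diagonal), \code{critical}
#'   (average + 0.2), and \code{flagged} (data frame item_a, item_b, r,
#'   excess).
#' @export
residual_correlations <- function(z) {
  R <- stats::cor(z)
  k <- ncol(R)
  off <- R[upper.tri(R)]
  avg <- mean(off)
  crit <- avg + 0.2
  ut <- which(upper.tri(R), arr.ind = TRUE)
  sel <- off > crit
  flagged <- data.frame(item_a = colnames(R)[ut[sel, 1]],
                        item_b = colnames(R)[ut[sel, 2]],
                        r = off[sel], excess = off[sel] - crit,
                        row.names = NULL)
  flagged <- flagged[order(-flagged$r), , drop = FALSE]
  structure(list(matrix = R, average = avg, critical = crit, flagged = flagged),
            class = "residual_correlations")
}

#' @export
print.residual_correlations <- function(x, ...) {
  cat(sprintf("Residual correlations: average %.3f, critical value %.3f\n",
              x$average, x$critical))
  if (nrow(x$flagged)) print(x$flagged) else cat("No pairs flagged\n")
  invisible(x)
}

#' Threshold ordering check
#'
#' An item's response categories work as intended when its uncentered
#' thresholds increase strictly with category; disordered thresholds signal
#' categories that are never the most probable anywhere on the continuum.
#'
#' @param fit a \code{\link{fit_pcm}} object.
#' @return named logical vector, TRUE when ordered.
#' @export
check_threshold_ordering <- function(fit) {
  stopifnot(inherits(fit, "pcm_fit"))
  vapply(fit$beta, function(b) length(b) < 2 || all(diff(b) > 0), TRUE)
}

#' Summary fit statistics for one analysis step
#'
#' Assembles the summary table reported at every step of a shortening
#' analysis: item and person fit-residual mean and SD, total item-trait
#' chi-square with p, the person separation index, and the result of
#' Smith's unidimensionality test, together with the per-item indicator
#' table.
#'
#' @inheritParams standardized_residuals
#' @param label analysis label (e.g. "SCALE23").
#' @param G,alpha passed to \code{\link{item_trait_chisq}}.
#' @param smith optional precomputed \code{\link{smith_unidimensionality}}
#'   result; computed when NULL.
#' @return object of class \code{fit_report}: list with \code{label},
#'   \code{summary} (one-row data frame), \code{items} (per-item table),
#'   \code{residual_correlations}, \code{smith}, \code{psi}, \code{G},
#'   \code{n}, \code{n_extreme}.
#' @export
summary_fit <- function(resp, fit, persons, label = "SCALE",
                        G = NULL, alpha = 0.01, smith = NULL) {
  z <- standardized_residuals(resp, fit, persons)
  fr_item <- item_fit_residuals(z)
  fr_person <- person_fit_residuals(z)
  chi <- item_trait_chisq(resp, fit, persons, G = G, alpha = alpha)
  psi <- person_separation_index(persons)
  rc <- residual_correlations(z)
  ordered <- check_threshold_ordering(fit)
  if (is.null(smith))
    smith <- tryCatch(smith_unidimensionality(resp, fit, persons),
                      error = function(e) {
                        warning("Smith's test unavailable: ",
                                conditionMessage(e))
                        NULL
                      })
  items <- data.frame(
    item = fit$item_ids,
    location = unname(fit$delta),
    se = unname(fit$se_delta),
    fit_residual = unname(fr_item),
    chisq = chi$items$chisq, df = chi$items$df,
    p = chi$items$p, p_adj = chi$items$p_adj,
    chisq_significant = chi$items$significant,
    thresholds_ordered = unname(ordered),
    row.names = NULL)
  summary <- data.frame(
    analysis = label,
    item_res_mean = mean(fr_item), item_res_sd = stats::sd(fr_item),
    person_res_mean = mean(fr_person), person_res_sd = stats::sd(fr_person),
    chisq = chi$total$chisq, chisq_df = chi$total$df, chisq_p = chi$total$p,
    psi = psi$psi,
    unidim_pct = if (is.null(smith)) NA_real_ else smith$proportion,
    unidim_ci_low = if (is.null(smith)) NA_real_ else smith$ci[1],
    unidim_ci_high = if (is.null(smith)) NA_real_ else smith$ci[2],
    row.names = NULL)
  structure(list(label = label, summary = summary, items = items,
                 residual_correlations = rc, smith = smith, psi = psi,
                 G = chi$G, chisq_total = chi$total,
                 n = length(persons$theta), n_extreme = sum(persons$extreme)),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Fit report:", x$label, sprintf("(n = %d, %d extreme excluded)\n",
                                      x$n, x$n_extreme))
  s <- x$summary
  cat(sprintf("  item residual %.2f (SD %.2f); person residual %.2f (SD %.2f)\n",
              s$item_res_mean, s$item_res_sd, s$person_res_mean, s$person_res_sd))
  cat(sprintf("  total chi-square %.2f on %d df (p = %.4g); PSI %.2f\n",
              s$chisq, s$chisq_df, s$chisq_p, s$psi))
  cat(sprintf("  unidimensionality: %.1f%% significant t-tests (95%% CI %.1f; %.1f)\n",
              s$unidim_pct, s$unidim_ci_low, s$unidim_ci_high))
  invisible(x)
}
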