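#' Smith's test of unidimensionality
#'
#' Principal component analysis of the standardized residual correlations
#' identifies the strongest residual contrast; items loading positively and
#' negatively on the first component define two subsets. Each person is
#' measured on both subsets with item parameters anchored from the full
#' fit (so both estimates sit on one metric), and an independent t-test
#' t_v = (theta_A - theta_B) / sqrt(SE_A^2 + SE_B^2) is computed per person.
#' Fewer than 5% of |t| > 1.96 supports unidimensionality; an exact
#' (Clopper-Pearson) 95% binomial confidence interval is attached and the
#' verdict is positive when its lower limit falls below 5%.
#'
#' @inheritParams standardized_residuals
#' @param loading_cut items with |PC1 loading| below this are left out of
#'   both subsets (default 0.05).
#' @param extreme_adjust passed to subset person estimation.
#' @return object of class \code{smith_result}: list with \code{loadings},
#'   \code{positive}, \code{negative} (item sets), \code{t} (per-person,
#'   NA for persons extreme on either subset), \code{n_valid},
#'   \code{n_significant}, \code{proportion} (percent), \code{ci}
#'   (percent), \code{unidimensional} (verdict).
#' @export
smith_unidimensionality <- function(resp, fit, persons, loading_cut = 0.05,
                                    extreme_adjust = 0.3) {
  z <- standardized_residuals(resp, fit, persons)
  keep <- attr(z, "persons")
  ev <- eigen(stats::cor(z), symmetric = TRUE)
  loadings <- stats::setNames(ev$vectors[, 1] * sqrt(ev$values[1]),
                              colnames(z))
  pos <- names(loadings)[loadings >= loading_cut]
  neg <- names(loadings)[loadings <= -loading_cut]
  if (length(pos) < 2 || length(neg) < 2)
    stop("residual PC1 does not split the items: ",
         length(pos), " positive vs ", length(neg),
         " negative loadings beyond ", loading_cut)
  est_subset <- function(items) {
    sub_fit <- subset_fit(fit, items)
    lookup <- score_to_theta(sub_fit, extreme_adjust)
    totals <- rowSums(resp$scores[keep, items, drop = FALSE])
    list(theta = lookup$theta[totals + 1L],
         se = lookup$se[totals + 1L],
         extreme = lookup$extreme[totals + 1L])
  }
  A <- est_subset(pos)
  B <- est_subset(neg)
  valid <- !(A$extreme | B$extreme)
  t_v <- rep(NA_real_, length(keep))
  t_v[valid] <- (A$theta[valid] - B$theta[valid]) /
    sqrt(A$se[valid]^2 + B$se[valid]^2)
  n_valid <- sum(valid)
  n_sig <- sum(abs(t_v[valid]) > 1.96)
  ci <- as.numeric(stats::binom.test(n_sig, n_valid)$conf.int) * 100
  structure(list(loadings = loadings, positive = pos, negative = neg,
                 t = t_v, n_valid = n_valid, n_significant = n_sig,
                 proportion = 100 * n_sig / n_valid, ci = ci,
                 unidimensional = ci[1] < 5),
            class = "smith_result")
}

#' @export
print.smith_result <- function(x, ...) {
  cat(sprintf("Smith's unidimensionality test: %.1f%% significant t-tests (95%% CI %.1f; %.1f)\n",
              x$proportion, x$ci[1], x$ci[2]))
  cat("Verdict:", if (x$unidimensional) "unidimensional" else
    "unidimensionality questionable", "\n")
  invisible(x)
}

#' Differential item functioning by ANOVA on standardized residuals
#'
#' For every item and person factor, a two-way fixed-effects ANOVA of the
#' standardized residuals on the factor, the class interval (trait level),
#' and their interaction. The factor main effect tests uniform DIF (a
#' constant group shift); the interaction tests non-uniform DIF (a group
#' difference changing along the trait). Type II sums of squares are used
#' for the unbalanced layouts that arise from equal-count intervals.
#' P-values are Bonferroni-adjusted over the item-by-factor family at
#' \code{alpha}.
#'
#' @param z standardized residual matrix from
#'   \code{\link{standardized_residuals}}.
#' @param person_factors data frame of factors for the same (non-extreme)
#'   persons as the rows of \code{z}.
#' @param intervals integer vector of class-interval assignments for those
#'   persons (see \code{\link{item_trait_chisq}}).
#' @param factors names of the columns of \code{person_factors} to test.
#' @param alpha family significance level (default 0.01).
#' @param merge_empty when a factor level is empty within an interval,
#'   merge adjacent intervals (with a message) instead of failing.
#' @return object of class \code{dif_table}: data frame with one row per
#'   item x factor (uniform_F, uniform_p, uniform_p_adj, uniform_flag and
#'   the non-uniform counterparts).
#' @export
dif_anova <- function(z, person_factors, intervals,
                      factors = names(person_factors), alpha = 0.01,
                      merge_empty = TRUE) {
  stopifnot(nrow(person_factors) == nrow(z),
            length(intervals) == nrow(z))
  items <- colnames(z)
  n_tests <- length(items) * length(factors)
  rows <- list()
  for (fac in factors) {
    f <- factor(person_factors[[fac]])
    if (nlevels(f) < 2) stop("factor ", fac, " has fewer than 2 levels")
    g <- intervals
    # merge adjacent intervals until every factor level occurs in each
    repeat {
      tab <- table(f, g)
      empty <- which(colSums(tab == 0) > 0)
      if (!length(empty)) break
      if (!merge_empty)
        stop("factor ", fac, " has an empty level within class interval ",
             colnames(tab)[empty[1]])
      lev <- sort(unique(g))
      if (length(lev) <= 2)
        stop("cannot merge further: factor ", fac,
             " never fills two class intervals")
      e <- lev[min(which(lev %in% as.integer(colnames(tab)[empty])))]
      tgt <- if (e == lev[1]) lev[2] else lev[max(which(lev < e))]
      g[g == e] <- tgt
      message("dif_anova: merged class interval ", e, " into ", tgt,
              " for factor ", fac)
    }
    g <- factor(g)
    for (it in items) {
      y <- z[, it]
      if (stats::sd(y) < 1e-12) {
        warning("constant residuals for item ", it,
                "; reporting no DIF for factor ", fac)
        rows[[length(rows) + 1L]] <- data.frame(
          item = it, factor = fac, uniform_F = 0, uniform_p = 1,
          nonuniform_F = 0, nonuniform_p = 1)
        next
      }
      mod <- stats::lm(y ~ f * g)
      a <- car::Anova(mod, type = 2)
      rows[[length(rows) + 1L]] <- data.frame(
        item = it, factor = fac,
        uniform_F = a["f", "F value"], uniform_p = a["f", "Pr(>F)"],
        nonuniform_F = a["f:g", "F value"], nonuniform_p = a["f:g", "Pr(>F)"])
    }
  }
  out <- do.call(rbind, rows)
  out$uniform_p_adj <- pmin(1, out$uniform_p * n_tests)
  out$nonuniform_p_adj <- pmin(1, out$nonuniform_p * n_tests)
  out$uniform_flag <- out$uniform_p_adj < alpha
  out$nonuniform_flag <- out$nonuniform_p_adj < alpha
  class(out) <- c("dif_table", "data.frame")
  out
}

#' @export
print.dif_table <- function(x, ...) {
  flagged <- x[x$uniform_flag | x$nonuniform_flag, , drop = FALSE]
  cat("DIF table:", nrow(x), "item x factor tests,",
      nrow(flagged), "flagged\n")
  if (nrow(flagged))
    print(data.frame(flagged[, c("item", "factor")],
                     uniform_F = round(flagged$uniform_F, 2),
                     uniform_p_adj = signif(flagged$uniform_p_adj, 3),
                     nonuniform_F = round(flagged$nonuniform_F, 2),
                     nonuniform_p_adj = signif(flagged$nonuniform_p_adj, 3),
                     row.names = NULL))
  invisible(x)
}

#' Resolve real versus artificial DIF by item splitting
#'
#' Apparent DIF in several items can be an artifact of one truly
#' DIF-affected item, because the person estimates that residuals condition
#' on absorb that item's group difference. The flagged item with the highest
#' uniform-DIF F statistic is split into group-specific virtual items: the
#' model is refitted within each group, the group metrics are aligned on the
#' mean location of the unsplit items, and DIF is re-evaluated. Items whose
#' flags vanish after the split showed artificial DIF; the split item's
#' group-specific locations are compared with a normal-theory difference
#' test.
#'
#' @param resp a \code{\link{response_matrix}} with person factors.
#' @param dif_table a \code{\link{dif_anova}} result for the current fit.
#' @param factor the person factor to resolve.
#' @param alpha family significance level (default 0.01).
#' @param G number of class intervals for the re-evaluation (default as in
#'   \code{\link{item_trait_chisq}}).
#' @param extreme_adjust passed to person estimation.
#' @return object of class \code{dif_resolution}: list with \code{split_item},
#'   \code{group_locations} (per-level location and SE),
#'   \code{difference} (estimate, se, z, p), \code{before} and \code{after}
#'   (flagged item sets for \code{factor}), \code{artificial} (items whose
#'   flags vanished), \code{dif_after} (full re-evaluated table). When
#'   nothing is flagged for \code{factor}, returns the input unchanged with
#'   \code{split_item = NA} (resolution is idempotent on clean data).
#' @export
resolve_artificial_dif <- function(resp, dif_table, factor, alpha = 0.01,
                                   G = NULL, extreme_adjust = 0.3) {
  stopifnot(inherits(resp, "response_matrix"))
  tab <- dif_table[dif_table$factor == factor, , drop = FALSE]
  flagged <- tab[tab$uniform_flag | tab$nonuniform_flag, , drop = FALSE]
  if (!nrow(flagged))
    return(structure(list(split_item = NA_character_, before = character(0),
                          after = character(0), artificial = character(0),
                          dif_after = dif_table),
                     class = "dif_resolution"))
  split_item <- flagged$item[which.max(flagged$uniform_F)]
  f <- factor(resp$person_factors[[factor]])
  levs <- levels(f)
  other <- setdiff(resp$item_ids, split_item)
  # group-specific refits, aligned on the mean location of the common items
  fits <- list()
  for (lv in levs) {
    sub <- response_matrix(resp$scores[f == lv, , drop = FALSE],
                           subscale_map = resp$subscale_map,
                           person_factors = resp$person_factors[f == lv, , drop = FALSE],
                           item_ids = resp$item_ids, max_score = resp$max_score)
    fits[[lv]] <- tryCatch(fit_pcm(sub), error = function(e)
      stop("group-specific refit failed for ", factor, " = ", lv, ": ",
           conditionMessage(e), "\n(a split creating null categories needs ",
           "category collapsing first)", call. = FALSE))
    shift <- mean(fits[[lv]]$delta[other])
    fits[[lv]]$beta <- lapply(fits[[lv]]$beta, function(b) b - shift)
    fits[[lv]]$delta <- fits[[lv]]$delta - shift
  }
  group_locations <- data.frame(
    level = levs,
    location = vapply(levs, function(lv) fits[[lv]]$delta[[split_item]], 0),
    se = vapply(levs, function(lv) fits[[lv]]$se_delta[[split_item]], 0),
    row.names = NULL)
  d <- diff(group_locations$location[1:2])
  sed <- sqrt(sum(group_locations$se[1:2]^2))
  difference <- list(estimate = d, se = sed, z = d / sed,
                     p = 2 * stats::pnorm(-abs(d / sed)))
  # resolved model: common items keep the pooled fit, the split item takes
  # group-specific thresholds; residuals recomputed per group
  pooled <- fit_pcm(resp)
  z_rows <- list(); pf_rows <- list(); iv_rows <- list()
  for (lv in levs) {
    gfit <- pooled
    gfit$beta[[split_item]] <- fits[[lv]]$beta[[split_item]]
    gfit$delta[[split_item]] <- fits[[lv]]$delta[[split_item]]
    sub <- response_matrix(resp$scores[f == lv, , drop = FALSE],
                           subscale_map = resp$subscale_map,
                           person_factors = resp$person_factors[f == lv, , drop = FALSE],
                           item_ids = resp$item_ids, max_score = resp$max_score)
    pe <- person_estimates(sub, gfit, extreme_adjust)
    z <- standardized_residuals(sub, gfit, pe)
    keep <- attr(z, "persons")
    z_rows[[lv]] <- z
    pf_rows[[lv]] <- sub$person_factors[keep, , drop = FALSE]
    iv_rows[[lv]] <- pe$theta[keep]
  }
  z_all <- do.call(rbind, z_rows)
  pf_all <- do.call(rbind, pf_rows)
  theta_all <- unlist(iv_rows)
  G <- G %||% default_G(length(theta_all))
  iv <- class_intervals(theta_all, G)
  dif_after <- dif_anova(z_all[, other, drop = FALSE],
                         pf_all, iv, factors = factor, alpha = alpha)
  before <- flagged$item
  after_tab <- dif_after[dif_after$uniform_flag | dif_after$nonuniform_flag, ]
  after <- after_tab$item
  structure(list(split_item = split_item,
                 group_locations = group_locations,
                 difference = difference,
                 before = before, after = after,
                 artificial = setdiff(setdiff(before, split_item), after),
                 dif_after = dif_after),
            class = "dif_resolution")
}

#' @export
print.dif_resolution <- function(x, ...) {
  if (is.na(x$split_item)) {
    cat("No DIF flagged; nothing to resolve\n")
    return(invisible(x))
  }
  cat("Split item:", x$split_item, "\n")
  print(x$group_locations)
  cat(sprintf("Group difference %.3f (SE %.3f, p = %.3g)\n",
              x$difference$estimate, x$difference$se, x$difference$p))
  cat("Artificial DIF resolved for:",
      if (length(x$artificial)) paste(x$artificial, collapse = ", ") else "none",
      "\n")
  invisible(x)
}
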