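test_that("testlet formation conserves scores and ranges", {
  resp <- sim_bat_like(400, seed = 12)
  tl <- form_testlets(resp)
  expect_equal(sort(tl$item_ids), sort(unique(resp$subscale_map)))
  for (s in tl$item_ids) {
    members <- attr(tl, "members")[[s]]
    expect_identical(tl$scores[, s],
                     as.integer(rowSums(resp$scores[, members, drop = FALSE])))
  }
  # testlet totals equal item totals person by person
  expect_identical(rowSums(tl$scores), rowSums(resp$scores))
  expect_equal(unname(tl$max_score["EX"]), 32L)
  # all-zero responses stay all zero
  z <- response_matrix(matrix(0L, 5, 23, dimnames = list(NULL, resp$item_ids)),
                       subscale_map = resp$subscale_map,
                       max_score = resp$max_score)
  expect_true(all(form_testlets(z)$scores == 0))
})

test_that("null testlet categories are collapsed with a log", {
  # 2 tiny subscales where testlet score 1 can never occur
  sc <- cbind(A1 = c(0L, 2L, 2L, 0L), A2 = c(0L, 2L, 0L, 2L),
              B1 = c(0L, 1L, 1L, 0L), B2 = c(1L, 0L, 1L, 0L))
  sc[, "A2"] <- sc[, "A1"]   # A-testlet scores: 0 or 4 only
  resp <- response_matrix(sc, subscale_map = c(A1 = "A", A2 = "A",
                                               B1 = "B", B2 = "B"),
                          max_score = c(2L, 2L, 1L, 1L))
  expect_message(tl <- form_testlets(resp), "collapsed")
  expect_gt(length(attr(tl, "collapse_log")), 0)
  expect_error(form_testlets(resp, collapse = "error"), "null")
  # collapsed testlet is estimable: consecutive categories all observed
  expect_true(all(tl$scores[, "A"] %in% 0:1))
})

test_that("latent structure hits its limits and tracks the generating truth", {
  ids <- sprintf("S%d_%d", rep(1:4, each = 3), rep(1:3, 4))
  map <- stats::setNames(rep(paste0("T", 1:4), each = 3), ids)
  bank <- item_bank(n_items = 12, delta = rep(seq(-0.6, 0.6, length.out = 3), 4),
                    item_ids = ids, subscale_map = map)
  gen <- function(theta_mat, seed) {
    set.seed(seed)
    sc <- matrix(0L, nrow(theta_mat), 12, dimnames = list(NULL, ids))
    for (s in 1:4) {
      for (i in 1:3) {
        id <- ids[3 * (s - 1) + i]
        p <- pcm_probs(theta_mat[, s], bank$beta[[id]])
        cp <- t(apply(p, 1, cumsum))
        sc[, id] <- rowSums(stats::runif(nrow(theta_mat)) > cp[, -ncol(cp)])
      }
    }
    response_matrix(sc, subscale_map = map,
                    max_score = vapply(bank$beta, length, 1L))
  }
  # the limits are asymptotic: small average-correlation noise is amplified
  # by the common-variance ratio, so they are checked at a size where the
  # correlation estimates are tight
  n <- 10000
  # single common factor: disattenuated correlations and ECV near 1
  set.seed(91)
  g <- stats::rnorm(n, 0, 1.3)
  ls1 <- latent_structure(gen(matrix(g, n, 4), seed = 92))
  expect_gt(min(ls1$latent_correlations), 0.95)
  expect_gt(ls1$ecv, 0.95)
  # independent factors: both near 0
  set.seed(93)
  ls0 <- latent_structure(gen(matrix(stats::rnorm(n * 4, 0, 1.3), n, 4), seed = 94))
  expect_lt(abs(ls0$average_latent_correlation), 0.05)
  expect_lt(ls0$ecv, 0.05)
  # correlated factors (0.7): high but sub-unit ECV
  set.seed(95)
  g <- stats::rnorm(n, 0, 1.3)
  th <- g + matrix(stats::rnorm(n * 4, 0, 0.85), n, 4)
  ls7 <- latent_structure(gen(th, seed = 96))
  expect_gt(ls7$ecv, 0.85)
  expect_lte(ls7$ecv, 1)
  expect_true(all(ls7$latent_correlations <= 1))
  expect_gt(min(ls7$reliability), 0.5)
})

test_that("the logit-to-metric map reproduces the printed anchor rows", {
  expect_equal(metric_from_logit(-3.40, -3.40, 2.85), 1.00)
  expect_equal(metric_from_logit(2.85, -3.40, 2.85), 5.00)
  expect_equal(round(metric_from_logit(-2.76, -3.40, 2.85), 2), 1.41)
  expect_error(metric_from_logit(0, 1, 1), "degenerate")
  expect_warning(out <- metric_from_logit(-5, -3.40, 2.85), "clamped")
  expect_equal(out, 1.00)
})

test_that("conversion table is a strictly monotone 49-row grid for 12 items", {
  ct <- conversion_table(fx$fit)
  expect_equal(nrow(ct), 49L)
  expect_equal(ct$raw_mean, seq(1, 5, by = 1 / 12), tolerance = 1e-12)
  expect_true(all(diff(ct$logit) > 0))
  expect_true(all(diff(ct$metric) > 0))
  expect_equal(ct$metric[1], 1)
  expect_equal(ct$metric[49], 5)
  # linearity: metric is affine in the logit across all rows
  slope <- (ct$metric - 1) / (ct$logit - attr(ct, "theta_min"))
  expect_lt(max(abs(slope[-1] - 4 / (attr(ct, "theta_max") - attr(ct, "theta_min")))),
            1e-10)
})

test_that("raw-mean conversion honors the grid contract", {
  ct <- conversion_table(fx$fit)
  expect_equal(apply_conversion(c(1, 5), ct), c(1, 5))
  # round trip through a person's total
  tot <- 20
  expect_equal(apply_conversion(1 + 4 * tot / 48, ct), ct$metric[tot + 1])
  expect_error(apply_conversion(1.05, ct), "not on the conversion grid")
  expect_error(apply_conversion(NA_real_, ct), "complete")
})
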