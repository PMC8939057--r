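test_that("standardized residuals match hand computation", {
  # (x - E)/sqrt(W) at the worked three-category cell
  mom <- pcm_moments(0, c(-1, 1))
  expect_equal(round((2 - mom$E) / sqrt(mom$W), 3), 1.536)
  # per-item means are near zero under a correct model
  expect_true(all(abs(colMeans(fx$z)) < 0.15))
  expect_lt(abs(mean(fx$z)), 0.05)
  # extreme persons are excluded
  expect_equal(nrow(fx$z), sum(!fx$pe$extreme))
})

test_that("fit residuals flag maximal overfit and stay calibrated under the null", {
  # all-zero residuals: maximal overfit, strongly negative
  z0 <- matrix(0, 100, 6, dimnames = list(NULL, paste0("I", 1:6)))
  fr0 <- item_fit_residuals(z0)
  expect_true(all(fr0 < -2.5))
  # null envelope over seeds
  calib <- null_calibration()
  fr_means <- vapply(calib, `[[`, 0, "fr_mean")
  fr_sds <- vapply(calib, `[[`, 0, "fr_sd")
  expect_gt(mean(fr_means), -0.5)
  expect_lt(mean(fr_means), 0.5)
  expect_gt(mean(fr_sds), 0.6)
  expect_lt(mean(fr_sds), 1.6)
})

test_that("an over-discriminating item has the most negative fit residual", {
  hits <- 0
  for (s in 1:5) {
    set.seed(400 + s)
    bank <- item_bank()
    theta <- stats::rnorm(800)
    resp <- sim_pcm(800, bank, seed = 500 + s, theta = theta)
    sc <- resp$scores
    # regenerate item 6 with doubled discrimination (Guttman-like)
    p <- pcm_probs(2 * theta, bank$beta[[6]])
    cp <- t(apply(p, 1, cumsum))
    sc[, 6] <- rowSums(stats::runif(800) > cp[, -ncol(cp)])
    resp2 <- response_matrix(sc, item_ids = resp$item_ids,
                             max_score = resp$max_score)
    fit <- fit_pcm(resp2)
    pe <- person_estimates(resp2, fit)
    fr <- item_fit_residuals(standardized_residuals(resp2, fit, pe))
    if (which.min(fr) == 6) hits <- hits + 1
    expect_lt(fr[6], 0)
  }
  expect_gte(hits, 4)
})

test_that("item-trait chi-square is calibrated and catches a misfitting item", {
  calib <- null_calibration()
  ratios <- vapply(calib, `[[`, 0, "chisq_ratio")
  expect_true(all(ratios > 0.7 & ratios < 1.4))
  # essentially no Bonferroni flags under the null
  expect_lte(sum(vapply(calib, `[[`, 0, "n_chisq_flagged")), 1)
  # a slope-2.5 item is flagged after Bonferroni adjustment
  hits <- 0
  for (s in 1:5) {
    set.seed(600 + s)
    bank <- item_bank()
    theta <- stats::rnorm(800)
    resp <- sim_pcm(800, bank, seed = 700 + s, theta = theta)
    sc <- resp$scores
    p <- pcm_probs(2.5 * theta, bank$beta[[6]])
    cp <- t(apply(p, 1, cumsum))
    sc[, 6] <- rowSums(stats::runif(800) > cp[, -ncol(cp)])
    resp2 <- response_matrix(sc, item_ids = resp$item_ids,
                             max_score = resp$max_score)
    fit <- fit_pcm(resp2)
    pe <- person_estimates(resp2, fit)
    chi <- item_trait_chisq(resp2, fit, pe)
    if (chi$items$significant[6]) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # df bookkeeping
  chi <- item_trait_chisq(fx$resp, fx$fit, fx$pe)
  expect_equal(unique(chi$items$df), chi$G - 1)
  expect_equal(chi$total$df, ncol(fx$resp$scores) * (chi$G - 1))
  expect_error(item_trait_chisq(fx$resp, fx$fit, fx$pe, G = 1), "interval")
})

test_that("person separation index behaves at its limits and under the null", {
  mk <- function(theta, se) structure(
    list(theta = theta, se = se, total = seq_along(theta),
         extreme = rep(FALSE, length(theta))), class = "person_estimates")
  expect_equal(person_separation_index(mk(stats::rnorm(50), rep(1e-9, 50)))$psi,
               1, tolerance = 1e-6)
  th <- rep(c(-1, 1), 25)
  expect_equal(person_separation_index(mk(th, rep(stats::sd(th), 50)))$psi, 0,
               tolerance = 1e-6)
  expect_error(person_separation_index(mk(1, 1)), "2 non-extreme")
  # invariance to a location shift
  pe <- fx$pe
  shifted <- pe
  shifted$theta <- pe$theta + 3
  expect_equal(person_separation_index(shifted)$psi,
               person_separation_index(pe)$psi)
  # simulation envelope with a wide person distribution
  resp <- sim_pcm(800, item_bank(), seed = 41, person_sd = 1.5)
  pe2 <- person_estimates(resp, fit_pcm(resp))
  psi <- person_separation_index(pe2)$psi
  expect_gt(psi, 0.80)
  expect_lt(psi, 0.95)
})

test_that("residual correlations flag dependent pairs against avg + 0.2", {
  rc <- residual_correlations(fx$z)
  expect_true(isSymmetric(rc$matrix))
  expect_equal(unname(diag(rc$matrix)), rep(1, ncol(fx$z)))
  expect_equal(rc$critical, rc$average + 0.2)
  # k = 2: the average is the single off-diagonal; a pair never self-flags
  rc2 <- residual_correlations(fx$z[, 1:2])
  expect_equal(rc2$average, rc2$matrix[1, 2])
  expect_equal(nrow(rc2$flagged), 0L)
  # a shared nuisance factor between two items gets flagged
  set.seed(77)
  bank <- item_bank()
  theta <- stats::rnorm(800)
  nuis <- stats::rnorm(800, 0, 0.8)
  sc <- sim_pcm(800, bank, seed = 78, theta = theta)$scores
  for (i in 3:4) {
    p <- pcm_probs(theta + nuis, bank$beta[[i]])
    cp <- t(apply(p, 1, cumsum))
    sc[, i] <- rowSums(stats::runif(800) > cp[, -ncol(cp)])
  }
  resp <- response_matrix(sc, item_ids = bank$item_ids,
                          max_score = vapply(bank$beta, length, 1L))
  fit <- fit_pcm(resp)
  pe <- person_estimates(resp, fit)
  rc3 <- residual_correlations(standardized_residuals(resp, fit, pe))
  expect_true(any(rc3$flagged$item_a == "I03" & rc3$flagged$item_b == "I04"))
})

test_that("threshold ordering is read off the uncentered thresholds", {
  mkfit <- function(beta) structure(
    list(item_ids = names(beta), beta = beta,
         max_score = vapply(beta, length, 1L)), class = "pcm_fit")
  f <- mkfit(list(A = c(-1, 0, 1), B = c(1, -1) + 0.2, C = 0.5))
  expect_equal(unname(check_threshold_ordering(f)), c(TRUE, FALSE, TRUE))
  # ordered generating thresholds stay ordered after refitting once the
  # sample pins the thresholds down (threshold SEs shrink below the gaps)
  all_ordered <- vapply(1:5, function(s)
    all(check_threshold_ordering(fit_pcm(sim_pcm(2000, item_bank(),
                                                 seed = 1200 + s)))), TRUE)
  expect_gte(sum(all_ordered), 4)
})

test_that("summary report is reproducible and internally consistent", {
  rep1 <- summary_fit(fx$resp, fx$fit, fx$pe, label = "SIM12")
  rep2 <- summary_fit(fx$resp, fx$fit, fx$pe, label = "SIM12")
  expect_identical(rep1$summary, rep2$summary)
  # summary statistics recompute from the per-unit vectors
  fr <- item_fit_residuals(fx$z)
  expect_equal(rep1$summary$item_res_mean, mean(fr), tolerance = 1e-10)
  expect_equal(rep1$summary$item_res_sd, stats::sd(fr), tolerance = 1e-10)
  expect_equal(rep1$summary$chisq,
               sum(rep1$items$chisq), tolerance = 1e-10)
  expect_named(rep1$summary,
               c("analysis", "item_res_mean", "item_res_sd", "person_res_mean",
                 "person_res_sd", "chisq", "chisq_df", "chisq_p", "psi",
                 "unidim_pct", "unidim_ci_low", "unidim_ci_high"))
})
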