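test_that("simulation is seed-reproducible and matches model frequencies", {
  a <- sim_pcm(200, item_bank(), seed = 3)
  b <- sim_pcm(200, item_bank(), seed = 3)
  expect_identical(a$scores, b$scores)
  # law of large numbers: empirical category frequencies at fixed theta
  bank <- item_bank(n_items = 1, delta = 0.2)
  big <- sim_pcm(1e5, bank, seed = 4, theta = 0.5)
  emp <- tabulate(big$scores + 1L, 5) / 1e5
  expect_lt(max(abs(emp - drop(pcm_probs(0.5, bank$beta[[1]])))), 0.01)
  # floor: theta far below every threshold gives all zeros
  expect_true(all(sim_pcm(50, item_bank(), seed = 5, theta = -50)$scores == 0))
  expect_error(sim_pcm(10, item_bank()), "seed")
})

test_that("generating parameters are recovered from simulated data", {
  bank <- item_bank()
  rmse_d <- c(); rmse_t <- c()
  for (s in 1:3) {
    fit <- fit_pcm(sim_pcm(2000, bank, seed = 1100 + s))
    rmse_d <- c(rmse_d, sqrt(mean((fit$delta - bank$delta)^2)))
    rmse_t <- c(rmse_t, sqrt(mean((unlist(fit$tau) - unlist(bank$tau))^2)))
  }
  expect_lt(mean(rmse_d), 0.1)
  expect_lt(mean(rmse_t), 0.25)
})

test_that("the multidimensional generator reproduces the testlet structure", {
  resp <- sim_bat_like(800, seed = 61)
  expect_equal(dim(resp$scores), c(800L, 23L))
  expect_equal(as.integer(table(resp$subscale_map)[c("EX", "MD", "CI", "EI")]),
               c(8L, 5L, 5L, 5L))
  expect_named(resp$person_factors, c("gender", "country", "age", "age_group"))
  # equal 2x2 strata
  expect_true(all(table(resp$person_factors$gender,
                        resp$person_factors$country) == 200))
  # within-subscale residual correlations exceed the critical value,
  # between-subscale ones do not dominate the flags
  fit <- fit_pcm(resp)
  pe <- person_estimates(resp, fit)
  rc <- residual_correlations(standardized_residuals(resp, fit, pe))
  same <- resp$subscale_map[rc$flagged$item_a] == resp$subscale_map[rc$flagged$item_b]
  expect_gt(nrow(rc$flagged), 0)
  expect_gt(mean(same), 0.8)
  # default size mirrors the emulated complete-case count
  expect_equal(nrow(sim_bat_like(seed = 1)$scores), 2978L)
})

test_that("a zero subscale factor reduces to a unidimensional instrument", {
  resp <- sim_bat_like(800, seed = 62, subscale_sd = 0)
  fit <- fit_pcm(resp)
  pe <- person_estimates(resp, fit)
  sm <- smith_unidimensionality(resp, fit, pe)
  expect_true(sm$unidimensional)
})

test_that("injected uniform DIF shifts the expected score as the model says", {
  bank <- item_bank()
  bank_d <- inject_dif(bank, "I03", "gender", "F", 0.5, "uniform")
  expect_length(bank_d$dif, 1)
  expect_identical(inject_dif(bank, "I03", "gender", "F", 0, "uniform")$dif,
                   list())
  # group difference in expected item score at theta = 0 equals the
  # closed-form PCM difference under the shifted thresholds
  n <- 4e4
  pf <- data.frame(gender = rep(c("M", "F"), n / 2))
  resp <- sim_pcm(n, bank_d, seed = 63, theta = 0, person_factors = pf)
  diff_emp <- mean(resp$scores[pf$gender == "M", "I03"]) -
    mean(resp$scores[pf$gender == "F", "I03"])
  diff_true <- pcm_moments(0, bank$beta[["I03"]])$E -
    pcm_moments(0, bank$beta[["I03"]] + 0.5)$E
  expect_lt(abs(diff_emp - diff_true), 0.03)
  expect_error(inject_dif(bank, "I03", "gender", "F", Inf, "uniform"), "finite")
})

test_that("non-uniform DIF is detected as an interaction", {
  hits <- 0
  for (s in 1:5) {
    bank <- inject_dif(item_bank(), "I05", "gender", "F", 0.8, "non-uniform")
    pf <- data.frame(gender = rep(c("M", "F"), 400))
    resp <- sim_pcm(800, bank, seed = 830 + s, person_factors = pf)
    fit <- fit_pcm(resp)
    pe <- person_estimates(resp, fit)
    z <- standardized_residuals(resp, fit, pe)
    keep <- attr(z, "persons")
    iv <- item_trait_chisq(resp, fit, pe)$intervals
    d <- dif_anova(z, resp$person_factors[keep, , drop = FALSE], iv,
                   factors = "gender")
    if (d$nonuniform_flag[d$item == "I05"]) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("stratified subsampling draws exact counts reproducibly", {
  resp <- sim_bat_like(1600, seed = 64)
  subs <- stratified_subsample(resp, k_per_stratum = 200, n_draws = 2, seed = 65)
  expect_length(subs, 2)
  for (s in subs) {
    expect_equal(nrow(s$scores), 800L)
    expect_true(all(table(s$person_factors$gender, s$person_factors$country) == 200))
  }
  subs2 <- stratified_subsample(resp, k_per_stratum = 200, n_draws = 2, seed = 65)
  expect_identical(subs[[1]]$scores, subs2[[1]]$scores)
  # k equal to the stratum size returns the stratum fully
  all_of_it <- stratified_subsample(resp, k_per_stratum = 400, n_draws = 1,
                                    seed = 66)[[1]]
  expect_equal(nrow(all_of_it$scores), 1600L)
  expect_error(stratified_subsample(resp, k_per_stratum = 401, seed = 67),
               "too small")
})
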